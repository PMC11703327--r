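test_that("score fusion applies the double radiologist weight", {
  scores <- matrix(c(4, 5, 3, 3), 1, 4,
                   dimnames = list("img-1", c("radiologist1", "radiologist2",
                                              "radiographer1", "radiographer2")))
  rt <- rater_table(scores, weights = c(2, 2, 1, 1))
  expect_equal(fuse_scores(rt)$score, 4)  # (2*4 + 2*5 + 3 + 3) / 6

  all5 <- rater_table(matrix(5, 3, 4), weights = c(2, 2, 1, 1))
  expect_equal(fuse_scores(all5)$score, rep(5, 3))

  single <- rater_table(matrix(c(3, NA, NA, NA), 1, 4), weights = c(2, 2, 1, 1))
  expect_equal(fuse_scores(single)$score, 3)
})

test_that("equal-weight fusion is the plain mean, with missing cells skipped", {
  set.seed(9)
  s <- matrix(sample(1:5, 40, replace = TRUE), 10, 4)
  s[2, 3] <- NA
  rt <- rater_table(s)
  expect_equal(fuse_scores(rt)$score, rowMeans(s, na.rm = TRUE))
})

test_that("krippendorff alpha is 1 under perfect agreement and matches brute force", {
  perfect <- matrix(rep(c(5, 3, 1, 4, 2), each = 4), 5, 4, byrow = TRUE)
  for (lvl in c("nominal", "ordinal", "interval")) {
    expect_equal(krippendorff_alpha(perfect, level = lvl)$alpha, 1)
  }
  # toy 4-rater x 10-item table with missing cells
  set.seed(14)
  toy <- matrix(sample(1:5, 40, replace = TRUE), 10, 4)
  toy[cbind(c(1, 4, 7), c(2, 4, 1))] <- NA
  for (lvl in c("nominal", "ordinal", "interval")) {
    expect_equal(krippendorff_alpha(toy, level = lvl)$alpha,
                 kripp_brute(toy, level = lvl), tolerance = 1e-12)
  }
})

test_that("alpha handles degenerate and null cases", {
  # all values identical globally: zero expected disagreement -> alpha 1 + note
  same <- matrix(4, 6, 3)
  a <- krippendorff_alpha(same)
  expect_equal(a$alpha, 1)
  expect_match(a$note, "expected disagreement")
  # random independent ratings: alpha near zero
  set.seed(15)
  rnd <- matrix(sample(1:5, 500 * 4, replace = TRUE), 500, 4)
  expect_lt(abs(krippendorff_alpha(rnd, level = "ordinal")$alpha), 0.1)
  expect_error(krippendorff_alpha(matrix(1:5, 5, 1)), "2 raters")
})

test_that("alpha is invariant to item order and deterministic", {
  set.seed(16)
  s <- matrix(sample(1:5, 60, replace = TRUE), 30, 2)
  a1 <- krippendorff_alpha(s, level = "interval")$alpha
  a2 <- krippendorff_alpha(s[sample(30), ], level = "interval")$alpha
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("spearman correlation hits the textbook endpoints and the rank oracle", {
  st <- tibble::tibble(image_id = paste0("i", 1:8), metric = "m",
                       value = 1:8, available = TRUE)
  sc <- tibble::tibble(image_id = paste0("i", 1:8), score = (1:8)^2)
  expect_equal(correlate(st, sc)$rho, 1)
  sc_rev <- tibble::tibble(image_id = paste0("i", 1:8), score = -(1:8))
  expect_equal(correlate(st, sc_rev)$rho, -1)

  # 5-pair toy with a tie, against the average-rank formula
  x <- c(1.2, 3.4, 3.4, 0.5, 2.2)
  y <- c(2, 5, 4, 1, 3)
  st2 <- tibble::tibble(image_id = paste0("i", 1:5), metric = "m",
                        value = x, available = TRUE)
  sc2 <- tibble::tibble(image_id = paste0("i", 1:5), score = y)
  expect_equal(correlate(st2, sc2)$rho, spearman_brute(x, y), tolerance = 1e-12)
})

test_that("correlation is invariant under strictly monotone metric transforms", {
  set.seed(17)
  x <- rnorm(20); y <- x + rnorm(20, sd = 0.5)
  st <- tibble::tibble(image_id = paste0("i", 1:20), metric = "m",
                       value = x, available = TRUE)
  sc <- tibble::tibble(image_id = paste0("i", 1:20), score = y)
  r1 <- correlate(st, sc)$rho
  st$value <- exp(3 * st$value)
  expect_equal(correlate(st, sc)$rho, r1, tolerance = 1e-12)
})

test_that("too few pairs and unavailable rows are handled in correlation", {
  st <- tibble::tibble(image_id = paste0("i", 1:5), metric = "m",
                       value = c(1, 2, 3, 4, 5),
                       available = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  sc <- tibble::tibble(image_id = paste0("i", 1:5), score = 5:1)
  res <- correlate(st, sc)
  expect_false(res$defined)
  expect_equal(res$n, 2)
  expect_false(res$significant)
})

test_that("the median-rank league table ranks |rho| with average ties", {
  cors <- tibble::tibble(metric = c("A", "B", "C"), group = "s1",
                         rho = c(0.9, -0.5, 0.7), p_value = 0.01, n = 10,
                         significant = TRUE, defined = TRUE)
  r <- rank_metrics(cors)
  expect_equal(setNames(r$median_rank, r$metric), c(A = 1, C = 2, B = 3))

  tie <- tibble::tibble(metric = c("A", "B"), group = "s1",
                        rho = c(0.8, -0.8), defined = TRUE)
  rt <- rank_metrics(tie)
  expect_equal(rt$median_rank, c(1.5, 1.5))

  two <- tibble::tibble(metric = rep(c("A", "B"), 2),
                        group = rep(c("s1", "s2"), each = 2),
                        rho = c(0.9, 0.4, 0.3, 0.8), defined = TRUE)
  r2 <- rank_metrics(two)
  expect_equal(setNames(r2$median_rank, r2$metric), c(A = 1.5, B = 1.5))
})

test_that("tidy and glance methods return well-formed tibbles", {
  set.seed(18)
  s <- matrix(sample(1:5, 40, replace = TRUE), 10, 4)
  a <- krippendorff_alpha(s)
  expect_named(tidy(a), c("alpha", "level", "n_raters", "n_items"))
  st <- tibble::tibble(image_id = paste0("i", 1:10), metric = "m",
                       value = rnorm(10), available = TRUE)
  sc <- tibble::tibble(image_id = paste0("i", 1:10), score = rnorm(10))
  cr <- correlate(st, sc)
  expect_s3_class(tidy(cr), "tbl_df")
  g <- glance(cr)
  expect_equal(g$n_metrics, 1)
})
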