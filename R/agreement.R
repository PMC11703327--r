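# Agreement between metric values and observer scores: weighted score
# fusion, Krippendorff's alpha inter-rater reliability, Spearman rank
# correlation per metric (and per sequence/group), and the median-rank
# league table over |rho|.

#' Fuse observer scores across raters
#'
#' Weighted mean per image over non-missing raters:
#' `sum(w_r * s_r) / sum(w_r)`. With a double weight on radiologists
#' relative to radiographers this reproduces the conventional experience-
#' weighted averaging of panel scores. With all-equal weights it is the
#' plain mean. Non-integer fused scores are expected and used as-is in
#' correlation.
#'
#' @param table A [rater_table()].
#' @return Tibble with columns `image_id`, `score`, `n_raters`.
#' @export
fuse_scores <- function(table) {
  stopifnot(inherits(table, "rater_table"))
  s <- table$scores
  w <- matrix(table$weights, nrow(s), ncol(s), byrow = TRUE)
  w[is.na(s)] <- 0
  wsum <- rowSums(w)
  if (any(wsum == 0)) {
    moqam_abort(paste0("images with no scores: ",
                       paste(rownames(s)[wsum == 0], collapse = ", ")),
                "moqam_input_error")
  }
  tibble::tibble(image_id = rownames(s),
                 score = unname(rowSums(w * s, na.rm = TRUE) / wsum),
                 n_raters = unname(rowSums(!is.na(s))))
}

#' Krippendorff's alpha inter-rater reliability
#'
#' Chance-corrected agreement `alpha = 1 - D_observed / D_expected`
#' computed from the coincidence matrix of pairable values, with the
#' distance function of the chosen level of measurement (`ordinal` by
#' default, appropriate for 1-5 Likert data). Missing cells are excluded
#' pairwise; items with fewer than two ratings do not contribute. Alpha
#' ranges from 0 (no agreement) to 1 (perfect agreement); small negative
#' values can occur for systematic disagreement.
#'
#' When every pairable value in the table is identical, expected
#' disagreement is zero and alpha is defined as 1 (perfect agreement, with
#' a note).
#'
#' @param table A [rater_table()] or a numeric matrix (items x raters,
#'   `NA` for missing).
#' @param level Level of measurement: `"ordinal"`, `"nominal"` or
#'   `"interval"`.
#' @return Object of class `moqam_alpha`: list with `alpha`, `level`,
#'   `n_raters`, `n_items` (items with >= 2 ratings), `note`.
#' @export
krippendorff_alpha <- function(table, level = c("ordinal", "nominal", "interval")) {
  level <- match.arg(level)
  s <- if (inherits(table, "rater_table")) table$scores else as.matrix(table)
  if (ncol(s) < 2) {
    moqam_abort("Krippendorff's alpha needs at least 2 raters",
                "moqam_input_error")
  }
  m_u <- rowSums(!is.na(s))
  usable <- m_u >= 2
  if (sum(usable) < 1) {
    moqam_abort("no item has two or more pairable values", "moqam_input_error")
  }
  su <- s[usable, , drop = FALSE]
  vals <- sort(unique(as.vector(su[!is.na(su)])))
  nv <- length(vals)
  # coincidence matrix: o[c,k] = sum over items of (#ordered c-k pairs)/(m_u - 1)
  o <- matrix(0, nv, nv, dimnames = list(vals, vals))
  for (u in seq_len(nrow(su))) {
    r <- su[u, ]; r <- r[!is.na(r)]
    idx <- match(r, vals)
    cnt <- tabulate(idx, nv)
    pair <- outer(cnt, cnt)
    diag(pair) <- diag(pair) - cnt  # a value does not pair with itself
    o <- o + pair / (length(r) - 1)
  }
  n_c <- rowSums(o)
  n <- sum(n_c)
  delta <- switch(level,
    nominal = 1 - diag(nv),
    interval = outer(vals, vals, function(a, b) (a - b)^2),
    ordinal = {
      d <- matrix(0, nv, nv)
      for (a in seq_len(nv)) for (b in seq_len(nv)) {
        if (a != b) {
          g <- min(a, b):max(a, b)
          d[a, b] <- (sum(n_c[g]) - (n_c[a] + n_c[b]) / 2)^2
        }
      }
      d
    })
  d_obs <- sum(o * delta) / n
  d_exp <- sum(outer(n_c, n_c) * delta) / (n * (n - 1))
  note <- NULL
  if (d_exp == 0) {
    alpha <- 1
    note <- "all pairable values identical: zero expected disagreement, alpha defined as 1"
  } else {
    alpha <- 1 - d_obs / d_exp
  }
  structure(list(alpha = alpha, level = level, n_raters = ncol(s),
                 n_items = sum(usable), note = note),
            class = "moqam_alpha")
}

#' @export
print.moqam_alpha <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha (%s): %.4f  [%d raters, %d items]\n",
              x$level, x$alpha, x$n_raters, x$n_items))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @method tidy moqam_alpha
#' @export
tidy.moqam_alpha <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, level = x$level,
                 n_raters = x$n_raters, n_items = x$n_items)
}

#' @method glance moqam_alpha
#' @export
glance.moqam_alpha <- function(x, ...) tidy.moqam_alpha(x)

#' Correlate metric values with fused observer scores
#'
#' Spearman rank correlation (average ranks on ties) between each metric's
#' values and the fused observer score, optionally within groups (e.g. MR
#' sequence). Rows with unavailable metric values are excluded from
#' pairing. Lower-is-better metrics are expected to correlate negatively
#' with observer scores (higher score = better image); signs are
#' preserved, and the league table ranks absolute values.
#'
#' @param study A study tibble from [evaluate_dataset()] (columns
#'   `image_id`, `metric`, `value`, `available`, optionally `direction`).
#' @param scores Fused scores from [fuse_scores()] (columns `image_id`,
#'   `score`).
#' @param group_by Optional name of a grouping column in `study` (e.g.
#'   `"sequence"`); `NULL` for a single group `"all"`.
#' @param alpha_level Two-sided significance level for the `significant`
#'   flag (default 0.05, uncorrected, matching per-cell reporting
#'   practice).
#' @return Tibble of class `moqam_correlations`: `metric`, `group`, `rho`,
#'   `p_value`, `n`, `significant`, `defined`.
#' @export
correlate <- function(study, scores, group_by = NULL, alpha_level = 0.05) {
  stopifnot(is.data.frame(study), is.data.frame(scores))
  df <- dplyr::inner_join(tibble::as_tibble(study),
                          scores[c("image_id", "score")], by = "image_id")
  if (!"available" %in% names(df)) df$available <- TRUE
  df$group <- if (is.null(group_by)) "all" else as.character(df[[group_by]])
  out <- df |>
    dplyr::group_by(.data$metric, .data$group) |>
    dplyr::group_modify(function(d, key) {
      d <- d[d$available & !is.na(d$value) & !is.na(d$score), ]
      n <- nrow(d)
      if (n < 3) {
        return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                              significant = FALSE, defined = FALSE))
      }
      ct <- suppressWarnings(
        stats::cor.test(d$value, d$score, method = "spearman"))
      tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                     significant = ct$p.value < alpha_level, defined = TRUE)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, .data$metric)
  class(out) <- c("moqam_correlations", class(out))
  out
}

#' Median-rank league table of metrics
#'
#' Within each group (sequence), metrics are ranked by descending `|rho|`
#' (rank 1 = strongest correlation, average ranks on ties); the median
#' rank across groups summarizes each metric's overall standing. Metrics
#' with an undefined correlation in a group get no rank there; their
#' median is taken over the groups where they are present.
#'
#' @param correlations A [correlate()] result.
#' @return Tibble of class `moqam_ranks`: `metric`, `median_rank`,
#'   `n_groups`, ordered by `median_rank`.
#' @export
rank_metrics <- function(correlations) {
  stopifnot(is.data.frame(correlations))
  out <- tibble::as_tibble(correlations)
  if (!"group" %in% names(out)) out$group <- "all"
  out <- out |>
    dplyr::filter(!is.na(.data$rho)) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(rank = rank(-abs(.data$rho), ties.method = "average")) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(median_rank = median(.data$rank),
                     n_groups = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$median_rank, .data$metric)
  class(out) <- c("moqam_ranks", class(out))
  out
}

#' @method tidy moqam_correlations
#' @export
tidy.moqam_correlations <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @method glance moqam_correlations
#' @export
glance.moqam_correlations <- function(x, ...) {
  tibble::tibble(n_metrics = dplyr::n_distinct(x$metric),
                 n_groups = dplyr::n_distinct(x$group),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 max_abs_rho = max(abs(x$rho), na.rm = TRUE))
}
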