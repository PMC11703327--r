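# Independent brute-force oracles. These deliberately use literal loops /
# direct formulas, separate from the package's vectorized implementations.

# SSIM: explicit loop over all fully interior Gaussian-weighted windows.
ssim_brute <- function(x, y, L, ws = 11, sigma = 1.5) {
  r <- (ws - 1) / 2
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g1, g1); w <- w / sum(w)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  vals <- c()
  for (i in seq_len(nrow(x) - ws + 1)) {
    for (j in seq_len(ncol(x) - ws + 1)) {
      px <- x[i:(i + ws - 1), j:(j + ws - 1)]
      py <- y[i:(i + ws - 1), j:(j + ws - 1)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2
      vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# root-energy-normalized entropy by explicit pixel loop
entropy_loop <- function(x) {
  e <- 0
  for (v in x) e <- e + v^2
  h <- 0
  for (v in x) {
    yv <- v / sqrt(e)
    if (yv > 0) h <- h - yv * log(yv)
  }
  h
}

# Krippendorff's alpha by direct pair enumeration (no coincidence matrix)
kripp_brute <- function(scores, level = "ordinal") {
  vals <- sort(unique(as.vector(scores[!is.na(scores)])))
  m_u <- rowSums(!is.na(scores))
  units <- which(m_u >= 2)
  # marginal counts of each value over pairable units
  n_c <- sapply(vals, function(v) sum(scores[units, ] == v, na.rm = TRUE))
  n <- sum(n_c)
  dist2 <- function(a, b) {
    if (a == b) return(0)
    switch(level,
           nominal = 1,
           interval = (a - b)^2,
           ordinal = {
             ia <- which(vals == min(a, b)); ib <- which(vals == max(a, b))
             (sum(n_c[ia:ib]) - (n_c[ia] + n_c[ib]) / 2)^2
           })
  }
  d_obs_sum <- 0
  for (u in units) {
    r <- scores[u, ]; r <- r[!is.na(r)]
    for (i in seq_along(r)) {
      for (j in seq_along(r)) {
        if (i != j) d_obs_sum <- d_obs_sum + dist2(r[i], r[j]) / (length(r) - 1)
      }
    }
  }
  d_obs <- d_obs_sum / n
  d_exp_sum <- 0
  for (a in seq_along(vals)) {
    for (b in seq_along(vals)) {
      if (a != b) d_exp_sum <- d_exp_sum + n_c[a] * n_c[b] * dist2(vals[a], vals[b])
    }
  }
  d_exp <- d_exp_sum / (n * (n - 1))
  if (d_exp == 0) 1 else 1 - d_obs / d_exp
}

# average ranks computed by counting, then the Pearson formula on ranks
spearman_brute <- function(x, y) {
  avg_rank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
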