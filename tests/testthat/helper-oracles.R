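# Independent oracles. These deliberately avoid the package's own code
# paths: dense grid search instead of Levenberg-Marquardt, numerical
# quadrature instead of the closed-form integral, explicit outcome
# enumeration instead of distribution tails, and plain voxel loops
# instead of vectorized indexing.

oracle_grid_fit <- function(t, y, iters = 7L) {
  # center the search wide around a crude log-space estimate, then
  # refine a 61 x 61 grid multiplicatively
  ll <- stats::lm(log(y) ~ t)
  c0 <- exp(stats::coef(ll)[[1]])
  lam <- max(-stats::coef(ll)[[2]], 1e-6)
  w <- 3
  for (it in seq_len(iters)) {
    c0g <- exp(seq(log(c0 / w), log(c0 * w), length.out = 61))
    lamg <- exp(seq(log(lam / w), log(lam * w), length.out = 61))
    rss <- matrix(NA_real_, 61, 61)
    for (a in 1:61) {
      for (l in 1:61) {
        rss[a, l] <- sum((y - c0g[a] * exp(-lamg[l] * t))^2)
      }
    }
    idx <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    c0 <- c0g[idx[1]]
    lam <- lamg[idx[2]]
    w <- 1 + (w - 1) / 5
  }
  list(c0 = c0, lambda = lam)
}

oracle_quadrature_rt <- function(c0, lam, a_adm) {
  q <- stats::integrate(function(t) c0 * exp(-lam * t), 0,
                        50 * log(2) / lam, rel.tol = 1e-10)
  q$value * 3600 / a_adm
}

oracle_power_enum <- function(n, p_alt, alpha, p_null) {
  upper_tail <- function(k, p) {
    x <- k:n
    sum(choose(n, x) * p^x * (1 - p)^(n - x))
  }
  k_star <- n + 1L
  for (k in 0:n) {
    tail <- if (k == 0) 1 else upper_tail(k, p_null)
    if (tail <= alpha) { k_star <- k; break }
  }
  if (k_star > n) return(0)
  upper_tail(k_star, p_alt)
}

oracle_pearson_r <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

oracle_fixed_voi_mean <- function(ph, shift_vox) {
  d <- ph$dim
  tot <- 0
  cnt <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        if (ph$mask[i, j, k]) {
          tot <- tot + ph$activity[i, j, k + shift_vox]
          cnt <- cnt + 1L
        }
      }
    }
  }
  tot / cnt
}
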