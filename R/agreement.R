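#' Bland-Altman relative-difference summary
#'
#' Per-pair relative differences between two measurement protocols,
#' expressed in percent of the pair mean:
#' `d_i = (a_i - b_i) / ((a_i + b_i)/2) * 100`, summarized by the mean,
#' the sample standard deviation (n - 1), and the 95% limits of
#' agreement `mean +/- 1.96 * SD`. Signed differences are the default
#' (the reported mean differences of agreement studies carry sign);
#' `signed = FALSE` takes absolute values first.
#'
#' @param a,b Numeric vectors of paired measurements (protocol A / B),
#'   equal length >= 2; every pair mean must be > 0.
#' @param labels Optional pair labels.
#' @param signed Keep the sign of the differences (default `TRUE`).
#' @return An object of class `bland_altman`: list with `differences`
#'   (data frame `label`, `mean_ab`, `diff_pct`), `mean_pct`, `sd_pct`,
#'   `loa_low_pct`, `loa_high_pct`, `n`.
#' @examples
#' ba <- bland_altman(c(10, 30), c(10, 10))
#' ba$mean_pct  # 50
#' @export
bland_altman <- function(a, b, labels = NULL, signed = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    abort_prrt("`a` and `b` must have equal length", "prrtdose_input_error")
  }
  n <- length(a)
  if (n < 2L) {
    abort_prrt("need >= 2 pairs for an SD-based summary",
               "prrtdose_insufficient_data")
  }
  m <- (a + b) / 2
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort_prrt("every pair mean must be > 0", "prrtdose_domain_error")
  }
  d <- (a - b) / m * 100
  if (!signed) d <- abs(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  sd_pct <- stats::sd(d)
  mean_pct <- mean(d)
  structure(list(
    differences = data.frame(label = labels, mean_ab = m, diff_pct = d,
                             stringsAsFactors = FALSE),
    mean_pct = mean_pct, sd_pct = sd_pct,
    loa_low_pct = mean_pct - 1.96 * sd_pct,
    loa_high_pct = mean_pct + 1.96 * sd_pct,
    n = n
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean %.2f%%, SD %.2f%%, LoA [%.2f%%, %.2f%%]\n",
              x$n, x$mean_pct, x$sd_pct, x$loa_low_pct, x$loa_high_pct))
  invisible(x)
}

#' Pearson correlation between two protocols
#'
#' Product-moment correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against Student's t with `n - 2`
#' degrees of freedom (as computed by [stats::cor.test]).
#'
#' @param a,b Paired numeric vectors, length >= 3, each with nonzero
#'   variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_agreement <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    abort_prrt("`a` and `b` must have equal length", "prrtdose_input_error")
  }
  if (length(a) < 3L) {
    abort_prrt("need >= 3 pairs", "prrtdose_insufficient_data")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_prrt("zero variance in one of the series", "prrtdose_degenerate_input")
  }
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Exact power of the one-sided binomial test
#'
#' Rejection region `{X >= k*}` with `k*` the smallest integer such
#' that `P(X >= k* | p_null) <= alpha` (exact binomial tail); the power
#' is `P(X >= k* | p_alt)`. Under the discordance null `p_null = 0`
#' (no management disagreement between protocols), `k* = 1` and the
#' power reduces to `1 - (1 - p_alt)^n`: for n = 24 patients and a true
#' discordance proportion of 10%, the power to detect at least one
#' discordant management at alpha = 0.05 is 92%.
#'
#' @param n Number of trials (patients), integer >= 1.
#' @param p_alt True proportion under the alternative; `p_null <= p_alt <= 1`.
#' @param alpha Significance level, in (0, 1).
#' @param p_null Null proportion, default 0.
#' @return Power, in [0, 1].
#' @examples
#' binomial_power(24, 0.10)  # 0.9202
#' @export
binomial_power <- function(n, p_alt, alpha = 0.05, p_null = 0) {
  stopifnot_scalar_number(n, "n")
  stopifnot_scalar_number(p_alt, "p_alt")
  stopifnot_scalar_number(alpha, "alpha")
  stopifnot_scalar_number(p_null, "p_null")
  if (n < 1 || n != round(n)) {
    abort_prrt("n must be an integer >= 1", "prrtdose_domain_error")
  }
  if (p_null < 0 || p_alt > 1 || p_null > p_alt) {
    abort_prrt("need 0 <= p_null <= p_alt <= 1", "prrtdose_domain_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort_prrt("alpha must be in (0, 1)", "prrtdose_domain_error")
  }
  # P(X >= k | p_null) for k = 0..n+1; find smallest k with tail <= alpha
  k_star <- NA_integer_
  for (k in 0:(n + 1)) {
    tail <- if (k == 0) 1 else stats::pbinom(k - 1, n, p_null, lower.tail = FALSE)
    if (tail <= alpha) { k_star <- k; break }
  }
  if (k_star > n) return(0)
  stats::pbinom(k_star - 1, n, p_alt, lower.tail = FALSE)
}

#' Concordance of management decisions between protocols
#'
#' Counts positions where the final management decisions of the two
#' protocols differ.
#'
#' @param decisions_a,decisions_b Equal-length vectors of decisions
#'   (any comparable values, e.g. `"continue"`/`"withhold"`).
#' @return List with `discordant`, `proportion`, `n`.
#' @examples
#' decision_concordance(rep("continue", 24), rep("continue", 24))
#' @export
decision_concordance <- function(decisions_a, decisions_b) {
  if (length(decisions_a) != length(decisions_b)) {
    abort_prrt("decision lists must have equal length", "prrtdose_input_error")
  }
  n <- length(decisions_a)
  if (n < 1L) abort_prrt("need at least one decision", "prrtdose_input_error")
  disc <- sum(decisions_a != decisions_b)
  list(discordant = disc, proportion = disc / n, n = n)
}
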