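# Small statistical helpers shared across modules.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Uses the exact distribution when both samples are small (n <= 10) and
#' tie-free, and the normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

# Simes combination of per-window significance values into a region-level
# value (csaw-style combined testing).
simes <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  n <- length(p)
  min(1, min(n * sort(p) / seq_len(n)))
}

# z-scores over the finite entries of x; zero-variance tracks get z = 0.
zscore <- function(x) {
  fin <- is.finite(x)
  if (!any(fin)) return(rep(NA_real_, length(x)))
  s <- stats::sd(x[fin])
  z <- rep(NA_real_, length(x))
  z[fin] <- if (is.na(s) || s == 0) 0 else (x[fin] - mean(x[fin])) / s
  z
}
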