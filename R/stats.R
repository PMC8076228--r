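#' Two-group comparison and correlation helpers
#'
#' `compare_groups()` is a two-sample t test (Welch by default, as
#' appropriate for unequal variances between suture sites);
#' `correlate()` returns the Pearson correlation and its square, the
#' R-squared used to report how weakly related two suture measures are.
#'
#' @param a,b Numeric vectors (n >= 2 per group; equal length for
#'   `correlate`).
#' @param var.equal Passed to [stats::t.test()].
#' @return `compare_groups()`: list with `t`, `p_value`, `mean_a`, `mean_b`,
#'   `df`.  `correlate()`: list with `r` and `r_squared`.
#' @export
compare_groups <- function(a, b, var.equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  ht <- t.test(a, b, var.equal = var.equal)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       mean_a = mean(a), mean_b = mean(b), df = unname(ht$parameter))
}

#' @rdname compare_groups
#' @export
correlate <- function(a, b) {
  if (length(a) != length(b)) stop("correlate requires equal-length vectors")
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance: correlation undefined")
  r <- cor(a, b)
  list(r = r, r_squared = r^2)
}
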