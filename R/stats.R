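# Post-hoc inferential layer: pooled two-sample t, JZS Bayes factor with
# Cauchy prior on effect size, Pearson correlation.

#' Two-sample t test with JZS Bayes factor
#'
#' Classic pooled-variance (Student) two-sample t by default — the
#' convention implied by reporting df = n1 + n2 - 2 — with the
#' corresponding JZS Bayes factor in favour of a group difference.  Welch's
#' unequal-variance form is available behind a flag (its Bayes factor is
#' still computed from the pooled-convention effective sample sizes).
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param r_scale Cauchy prior scale for the Bayes factor (default 0.707).
#' @param welch Use Welch's t instead of the pooled form.
#' @param bf Compute the Bayes factor (set `FALSE` to skip).
#' @return A one-row tibble: `t`, `df`, `p`, `bf10`, `mean_x`, `mean_y`.
#' @examples
#' pooled_t(rnorm(20), rnorm(20, 0.5))
#' @export
pooled_t <- function(x, y, r_scale = 0.707, welch = FALSE, bf = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("each sample needs >= 2 values")
  if (!welch) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    if (sp2 == 0) abort("zero pooled variance")
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value,
         bf10 = if (bf) jzs_bf10(unname(ht$statistic), length(x), length(y),
                                 r_scale) else NA_real_,
         mean_x = mean(x), mean_y = mean(y))
}

#' JZS two-sample Bayes factor from a t statistic
#'
#' Default Bayes factor for a two-sample t contrast: a zero-centred Cauchy
#' prior with scale `r_scale` on the standardised effect size, against the
#' point null.  Computed by adaptive numerical integration of the
#' g-representation of the Cauchy prior with effective sample size
#' `N = n1 * n2 / (n1 + n2)` and `df = n1 + n2 - 2`; symmetric in the sign
#' of `t` and strictly increasing in `|t|`.
#'
#' @param t Observed t statistic.
#' @param n1,n2 Group sizes, each >= 2.
#' @param r_scale Cauchy prior scale (default 0.707).
#' @return The Bayes factor BF10 (> 1 favours a difference).
#' @examples
#' jzs_bf10(2.84, 127, 134)  # about 6
#' @export
jzs_bf10 <- function(t, n1, n2, r_scale = 0.707) {
  if (n1 < 2 || n2 < 2) abort("group sizes must be >= 2")
  if (r_scale <= 0) abort("r_scale must be positive")
  if (!is.finite(t)) abort("t must be finite")
  N <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(-0.5 * log1p(N * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) - log_null +
          0.5 * log(r_scale^2 / 2) - lgamma(0.5) -
          1.5 * log(g) - r_scale^2 / (2 * g))
  }
  res <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = 1e-8, abs.tol = 0,
              subdivisions = 500L),
    error = function(e) abort(paste0("Bayes factor integration failed: ",
                                     conditionMessage(e))))
  if (res$message != "OK") {
    abort(paste0("Bayes factor integration did not converge: ", res$message))
  }
  res$value
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Equal-length numeric samples, n >= 3.
#' @return A one-row tibble: `r`, `n`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}
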