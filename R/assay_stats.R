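#' Mann-Whitney U comparison of two samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, the standard
#' nonparametric comparison for migration distances, which are far from
#' normally distributed. The U statistic is computed from joint midranks
#' (tie-corrected). For small tie-free samples (`n1 + n2 <= 12`, at most
#' 924 arrangements) the exact null distribution is enumerated; otherwise
#' the normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative Only `"two_sided"` is supported, matching how the
#'   assay results are reported.
#' @param exact_max Largest combined sample size for the exact path.
#' @return Object of class `mw_test`: list with `U` (statistic of sample
#'   `a`), `p_value`, `method` (`"exact"` or `"normal_approx"`), `stars`
#'   (see [star_label()]), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1, exact
#' @export
mann_whitney <- function(a, b, alternative = "two_sided", exact_max = 12L) {
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  if (!identical(alternative, "two_sided"))
    stop("only the two-sided alternative is supported", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  rk <- rank(c(a, b))  # midranks
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  mu <- n1 * n2 / 2
  if (!ties && n <= exact_max) {
    # enumerate all C(n, n1) rank assignments of sample a
    combos <- utils::combn(n, n1)
    Us <- colSums(combos) - n1 * (n1 + 1) / 2
    dev <- abs(Us - mu)
    p <- mean(dev >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    tab <- table(rk)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu)
      z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity corr.
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(U = U, p_value = p, method = method,
                 stars = star_label(p), n1 = n1, n2 = n2),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d/%d), two-sided p = %.4g %s [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$stars, x$method))
  invisible(x)
}

#' Box-plot summary with 5th/95th-percentile whiskers
#'
#' Summary statistics matching the assay's box-plot convention: box from
#' first to third quartile with the median band, whiskers at the 5th and
#' 95th percentiles, plus the mean and the overall minimum and maximum.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param values Non-empty numeric sample.
#' @return Object of class `box_summary`: list with `median`, `q1`, `q3`,
#'   `p5`, `p95`, `mean`, `min`, `max`.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty sample", call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95),
                       type = 7, names = FALSE)
  structure(list(median = q[3], q1 = q[2], q3 = q[4], p5 = q[1], p95 = q[5],
                 mean = mean(values), min = min(values), max = max(values)),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf("median %g [Q1 %g, Q3 %g], whiskers (p5 %g, p95 %g), mean %g, range [%g, %g]\n",
              x$median, x$q1, x$q3, x$p5, x$p95, x$mean, x$min, x$max))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05, and the
#' empty string otherwise; all boundaries are strict.
#'
#' @param p Probability in `[0, 1]`.
#' @return One of `""`, `"*"`, `"**"`, `"***"`.
#' @export
star_label <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("p must lie in [0, 1]", call. = FALSE)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Pooled-variance two-sample t test
#'
#' Thin wrapper around `stats::t.test(var.equal = TRUE)` for the two-tailed
#' unpaired Student's t test used for sphere-formation rates and similar
#' bar-graph comparisons (the pooled form is the classical Student test).
#'
#' @param a,b Numeric samples.
#' @return List with `t`, `df`, `p_value`, `stars`.
#' @export
two_sample_t <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, stars = star_label(tt$p.value))
}
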