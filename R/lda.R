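#' Limiting-dilution outcome groups
#'
#' Validates a limiting-dilution table: one row per dose group with the
#' cell dose per implantation, the number of implants, and the number of
#' positive (tumor-forming) implants.
#'
#' @param dose Cells per implantation (> 0), one per group.
#' @param n_implants Implants per group.
#' @param n_positive Positive implants per group (`0 <= k <= n`).
#' @return Data frame with columns `dose`, `n_implants`, `n_positive`.
#' @export
lda_groups <- function(dose, n_implants, n_positive) {
  df <- data.frame(dose = dose, n_implants = as.integer(n_implants),
                   n_positive = as.integer(n_positive))
  validate_lda(df)
  df
}

validate_lda <- function(groups) {
  need <- c("dose", "n_implants", "n_positive")
  if (!all(need %in% names(groups)))
    stop("groups must have columns dose, n_implants, n_positive",
         call. = FALSE)
  if (!nrow(groups)) stop("at least one group is required", call. = FALSE)
  with(groups, {
    if (any(dose <= 0)) stop("dose must be positive", call. = FALSE)
    if (any(n_implants < 1)) stop("n_implants must be >= 1", call. = FALSE)
    if (any(n_positive < 0 | n_positive > n_implants))
      stop("n_positive must lie in [0, n_implants]", call. = FALSE)
  })
  invisible(groups)
}

# Log-likelihood of the single-hit Poisson model at frequency f:
# P(positive | dose d) = 1 - exp(-f d).
lda_loglik <- function(f, groups) {
  mu <- f * groups$dose
  k <- groups$n_positive; n <- groups$n_implants
  pos <- ifelse(k > 0, k * log1p(-exp(-mu)), 0)
  sum(pos - (n - k) * mu)
}

# Newton maximization of the cloglog-binomial log-likelihood in
# theta = log f (offset log dose). Returns list(f, loglik, info).
lda_newton <- function(groups, tol = 1e-10, max_iter = 100L) {
  k <- groups$n_positive; n <- groups$n_implants; d <- groups$dose
  p_pool <- sum(k) / sum(n)
  f <- -log(1 - min(p_pool, 0.99)) / mean(d)
  theta <- log(f)
  score_hess <- function(theta) {
    mu <- exp(theta) * d
    q <- exp(-mu)
    s_mu <- k * q / (1 - q) - (n - k)          # dl/dmu per group
    sp_mu <- -k * q / (1 - q)^2                # d s/dmu
    list(score = sum(mu * s_mu),
         hess = sum(mu * (s_mu + mu * sp_mu)))
  }
  for (it in seq_len(max_iter)) {
    sh <- score_hess(theta)
    if (!is.finite(sh$hess) || sh$hess >= 0)
      stop("limiting-dilution likelihood is not concave at the iterate",
           call. = FALSE)
    step <- sh$score / sh$hess
    theta <- theta - step
    if (abs(step) < tol) break
  }
  f <- exp(theta)
  list(f = f, loglik = lda_loglik(f, groups),
       info = -score_hess(theta)$hess)
}

#' Stem-cell frequency from limiting-dilution outcomes
#'
#' Maximum-likelihood estimate of the tumor-initiating (stem) cell
#' frequency `f` under the single-hit Poisson model
#' `P(positive | dose d) = 1 - exp(-f d)`. With a single dose group the
#' estimate has the closed form `f = -log(1 - k/n) / d`; with several
#' groups the complementary log-log binomial likelihood is maximized by
#' Newton iteration (tolerance 1e-10). Degenerate outcomes are flagged: no
#' positive implants gives frequency 0 (`degenerate = "all_negative"`),
#' while all-positive outcomes have no finite MLE and raise an error
#' unless `all_positive_bound = TRUE`, which reports a one-sided bound via
#' the continuity correction `k -> n - 0.5`.
#'
#' @param groups Data frame of dose groups (see [lda_groups()]).
#' @param all_positive_bound Report a continuity-corrected bound when every
#'   implant is positive instead of raising an error.
#' @return Object of class `lda_estimate`: list with `frequency`,
#'   `reciprocal` (cells per stem cell), `log_se` (SE of `log f` from the
#'   observed information; `NA` when degenerate), `ci_reciprocal`
#'   (filled by [wald_ci()]), `degenerate` (`"none"`, `"all_negative"`,
#'   `"all_positive"`), `loglik`, and the input `groups`.
#' @examples
#' estimate_frequency(lda_groups(100, 10, 9))$reciprocal   # 43.4
#' estimate_frequency(lda_groups(100, 10, 4))$reciprocal   # 195.8
#' @export
estimate_frequency <- function(groups, all_positive_bound = FALSE) {
  validate_lda(groups)
  k <- groups$n_positive; n <- groups$n_implants
  degenerate <- "none"
  if (all(k == 0)) {
    est <- list(frequency = 0, reciprocal = Inf, log_se = NA_real_,
                loglik = 0)
    degenerate <- "all_negative"
  } else if (all(k == n)) {
    degenerate <- "all_positive"
    if (!all_positive_bound)
      stop(paste("every implant was positive: the stem-cell frequency has",
                 "no finite MLE (set all_positive_bound = TRUE for a",
                 "continuity-corrected bound)"), call. = FALSE)
    g2 <- groups
    g2$n_positive <- g2$n_implants - 0.5
    fit <- lda_newton_fractional(g2)
    est <- list(frequency = fit$f, reciprocal = 1 / fit$f,
                log_se = 1 / sqrt(fit$info), loglik = fit$loglik)
  } else {
    if (nrow(groups) == 1L) {
      f <- -log(1 - k / n) / groups$dose
      fit <- lda_newton(groups)  # information at the MLE
      est <- list(frequency = f, reciprocal = 1 / f,
                  log_se = 1 / sqrt(fit$info),
                  loglik = lda_loglik(f, groups))
    } else {
      fit <- lda_newton(groups)
      est <- list(frequency = fit$f, reciprocal = 1 / fit$f,
                  log_se = 1 / sqrt(fit$info), loglik = fit$loglik)
    }
  }
  structure(c(est, list(ci_reciprocal = NULL, degenerate = degenerate,
                        groups = groups)),
            class = "lda_estimate")
}

# Newton fit tolerating fractional n_positive (continuity correction).
lda_newton_fractional <- function(groups) {
  groups$n_positive <- groups$n_positive  # numeric ok; reuse machinery
  lda_newton(groups)
}

#' @export
print.lda_estimate <- function(x, ...) {
  if (x$degenerate == "all_negative") {
    cat("Stem-cell frequency: 0 (no positive implants)\n")
  } else {
    cat(sprintf("Stem-cell frequency: %.5g (1 per %.1f cells)%s\n",
                x$frequency, x$reciprocal,
                if (x$degenerate == "all_positive")
                  " [continuity-corrected bound]" else ""))
    if (!is.null(x$ci_reciprocal))
      cat(sprintf("  95%% CI (reciprocal scale): (%.1f-%.1f)\n",
                  x$ci_reciprocal[1], x$ci_reciprocal[2]))
  }
  invisible(x)
}

#' Wald confidence interval for the stem-cell frequency
#'
#' 95% Wald interval for `log f` using the standard error from the
#' observed information of the complementary log-log fit,
#' `f * exp(+/- z * SE(log f))`. For a single dose group this coincides
#' with the delta-method form
#' `SE(log f) = SE(p_hat) / ((1 - p_hat) * d * f)` with
#' `SE(p_hat) = sqrt(p_hat (1 - p_hat) / n)`. The interval is reported on
#' the reciprocal (cells-per-stem-cell) scale as `(upper, lower)` —
#' largest reciprocal first, i.e. `(1 / f_lower, 1 / f_upper)`.
#'
#' @param estimate An [estimate_frequency()] result (non-degenerate).
#' @param conf_level Confidence level (default 0.95).
#' @return The estimate with `ci_reciprocal = c(upper, lower)` and
#'   `ci_frequency = c(lower_f, upper_f)` filled in.
#' @examples
#' est <- estimate_frequency(lda_groups(100, 10, 4))
#' wald_ci(est)$ci_reciprocal  # about (527, 72.7)
#' @export
wald_ci <- function(estimate, conf_level = 0.95) {
  stopifnot(inherits(estimate, "lda_estimate"))
  if (estimate$degenerate != "none")
    stop("no Wald interval for a degenerate estimate", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  f <- estimate$frequency
  half <- z * estimate$log_se
  f_lo <- f * exp(-half); f_hi <- f * exp(half)
  estimate$ci_frequency <- c(f_lo, f_hi)
  estimate$ci_reciprocal <- c(1 / f_lo, 1 / f_hi)
  estimate
}

# Maximized log-likelihood of one arm, handling boundary cases:
# all-negative arms attain their supremum 0 at f = 0; all-positive arms
# approach 0 as f -> Inf.
arm_max_loglik <- function(groups) {
  k <- groups$n_positive; n <- groups$n_implants
  if (all(k == 0) || all(k == n)) return(0)
  lda_newton(groups)$loglik
}

#' Likelihood-ratio comparison of stem-cell frequencies
#'
#' Tests equality of the single-hit frequencies of two arms (for example
#' migratory versus non-migratory implants) with a likelihood-ratio test
#' under the joint complementary log-log model, chi-square with 1 df.
#' Degenerate arms contribute their boundary supremum (log-likelihood 0).
#'
#' @param groups_a,groups_b Dose-group data frames for the two arms.
#' @return List with `lr_statistic`, `p_value`, and the two arm estimates'
#'   frequencies (`f_a`, `f_b`, boundary values for degenerate arms).
#' @export
compare_frequencies <- function(groups_a, groups_b) {
  validate_lda(groups_a); validate_lda(groups_b)
  deg <- function(g) all(g$n_positive == 0) ||
    all(g$n_positive == g$n_implants)
  if (deg(groups_a) && deg(groups_b))
    stop("both arms are degenerate; frequencies are not comparable",
         call. = FALSE)
  l_a <- arm_max_loglik(groups_a)
  l_b <- arm_max_loglik(groups_b)
  joint <- rbind(groups_a[c("dose", "n_implants", "n_positive")],
                 groups_b[c("dose", "n_implants", "n_positive")])
  l_0 <- arm_max_loglik(joint)
  lr <- max(0, 2 * (l_a + l_b - l_0))
  f_of <- function(g) {
    if (all(g$n_positive == 0)) 0
    else if (all(g$n_positive == g$n_implants)) Inf
    else lda_newton(g)$f
  }
  list(lr_statistic = lr,
       p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
       f_a = f_of(groups_a), f_b = f_of(groups_b))
}

#' Read a limiting-dilution outcome table
#'
#' Reads a CSV with columns `dose`, `n_implants`, `n_positive` and
#' optionally `arm` (and any annotation columns, which are kept).
#'
#' @param path CSV path.
#' @return Data frame, validated.
#' @export
read_lda_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_lda(df)
  df
}
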