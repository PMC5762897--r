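#' Significant differentially-expressed genes for one cell line
#'
#' Applies the differential-expression screen used to compare migratory
#' versus non-migratory cells: a gene is significantly up-regulated when
#' `p < p_max` and its fold change exceeds `min_fold` (i.e.
#' `log2fc > log2(min_fold)`), and significantly down-regulated when
#' `p < p_max` and `log2fc < -log2(min_fold)`; all inequalities are
#' strict. P-values are taken as supplied (raw).
#'
#' @param records Data frame for a single cell line with columns `gene`,
#'   `log2fc`, `p_value`.
#' @param p_max Significance cutoff (default 0.01).
#' @param min_fold Fold-change cutoff (default 2).
#' @return List of character vectors `up` and `down`.
#' @export
significant_genes <- function(records, p_max = 0.01, min_fold = 2) {
  need <- c("gene", "log2fc", "p_value")
  if (!all(need %in% names(records)))
    stop("records must have columns gene, log2fc, p_value", call. = FALSE)
  if (anyDuplicated(records$gene))
    stop("duplicate gene within one cell line", call. = FALSE)
  if (any(records$p_value <= 0 | records$p_value > 1))
    stop("p_value must lie in (0, 1]", call. = FALSE)
  lfc <- log2(min_fold)
  sig <- records$p_value < p_max
  list(up = records$gene[sig & records$log2fc > lfc],
       down = records$gene[sig & records$log2fc < -lfc])
}

#' Cross-line overlap with directional concordance
#'
#' Intersects the significant gene sets of two cell lines, keeping only
#' genes regulated in the same direction in both: the concordant
#' up-regulated set is `A.up` intersect `B.up`, the concordant
#' down-regulated set `A.down` intersect `B.down`; genes moving in
#' opposite directions are excluded.
#'
#' @param line_a,line_b Lists with `up` and `down` gene vectors, as
#'   returned by [significant_genes()].
#' @return List of character vectors `up` and `down`.
#' @export
overlap_concordant <- function(line_a, line_b) {
  list(up = intersect(line_a$up, line_b$up),
       down = intersect(line_a$down, line_b$down))
}

#' Median-split Kaplan-Meier comparison with log-rank test
#'
#' Splits subjects into low- and high-expression groups at the median
#' expression (ties go to the low group), estimates the Kaplan-Meier
#' product-limit curve for each group, and compares them with the log-rank
#' test. The hazard ratio is the Mantel-Haenszel observed/expected form
#' `HR = (O_low / E_low) / (O_high / E_high)` (low relative to high), with
#' a log-scale 95% interval `exp(log HR +/- z * sqrt(1/E_low + 1/E_high))`.
#'
#' @param records Data frame with columns `time` (> 0), `event`
#'   (1 = event, 0 = censored), `expression`.
#' @param split Only `"median"` is supported.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return Object of class `km_comparison`: list with `hr`, `hr_ci`,
#'   `logrank_p`, `chisq`, `low_group_worse` (`hr > 1`), per-group `O`
#'   and `E`, `n` per group, and `km_curves` (data frame `group`, `time`,
#'   `n_risk`, `n_event`, `surv`).
#' @export
km_logrank <- function(records, split = "median", conf_level = 0.95) {
  if (!identical(split, "median"))
    stop("only the median split is supported", call. = FALSE)
  need <- c("time", "event", "expression")
  if (!all(need %in% names(records)))
    stop("records must have columns time, event, expression", call. = FALSE)
  if (any(records$time <= 0)) stop("time must be positive", call. = FALSE)
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0 or 1", call. = FALSE)
  med <- stats::median(records$expression)
  grp <- ifelse(records$expression <= med, "low", "high")
  if (length(unique(grp)) < 2L || min(table(grp)) < 2L)
    stop("median split leaves fewer than 2 subjects in a group",
         call. = FALSE)
  if (sum(records$event) < 1L)
    stop("no events observed", call. = FALSE)

  time <- records$time; event <- records$event
  is_low <- grp == "low"
  ev_times <- sort(unique(time[event == 1]))
  O <- c(low = 0, high = 0); E <- c(low = 0, high = 0); V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & is_low); n2 <- sum(at_risk & !is_low)
    nt <- n1 + n2
    d1 <- sum(at_risk & is_low & event == 1 & time == t)
    d2 <- sum(at_risk & !is_low & event == 1 & time == t)
    dt <- d1 + d2
    O <- O + c(d1, d2)
    E <- E + dt * c(n1, n2) / nt
    if (nt > 1)
      V <- V + dt * (n1 / nt) * (n2 / nt) * (nt - dt) / (nt - 1)
  }
  chisq <- if (V > 0) (O[["low"]] - E[["low"]])^2 / V else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  hr <- (O[["low"]] / E[["low"]]) / (O[["high"]] / E[["high"]])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(1 / E[["low"]] + 1 / E[["high"]])
  hr_ci <- exp(log(hr) + c(-1, 1) * z * se_log)

  km_curve <- function(sel) {
    tt <- time[sel]; ee <- event[sel]
    ts <- sort(unique(tt[ee == 1]))
    surv <- 1; out <- NULL
    for (t in ts) {
      n_risk <- sum(tt >= t)
      n_event <- sum(tt == t & ee == 1)
      surv <- surv * (1 - n_event / n_risk)
      out <- rbind(out, data.frame(time = t, n_risk = n_risk,
                                   n_event = n_event, surv = surv))
    }
    out
  }
  curves <- rbind(
    if (!is.null(km_curve(is_low)))
      cbind(group = "low", km_curve(is_low)),
    if (!is.null(km_curve(!is_low)))
      cbind(group = "high", km_curve(!is_low)))

  structure(list(hr = hr, hr_ci = hr_ci, logrank_p = p,
                 chisq = unname(chisq), low_group_worse = hr > 1,
                 O = O, E = E, n = c(low = sum(is_low),
                                     high = sum(!is_low)),
                 median_expression = med, km_curves = curves),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat(sprintf("Median-split KM: HR(low/high) = %.3f (%.3f-%.3f), log-rank p = %.4g %s\n",
              x$hr, x$hr_ci[1], x$hr_ci[2], x$logrank_p,
              star_label(x$logrank_p)))
  invisible(x)
}

#' Survival-concordance filter for candidate genes
#'
#' Keeps a concordant-overlap gene only when its patient-survival
#' association points the same way as its expression change in migratory
#' cells: a down-regulated gene is kept when the low-expression group has
#' significantly worse survival (`low_group_worse` and
#' `logrank_p < alpha`), an up-regulated gene when the high-expression
#' group does. Output is sorted by the absolute mean log2 fold change
#' across the two lines, descending.
#'
#' @param candidates List with `up` and `down` gene vectors (from
#'   [overlap_concordant()]).
#' @param survival_results Data frame with one row per candidate gene:
#'   `gene`, `hr` (low vs high), `logrank_p`, `low_group_worse`.
#' @param fc_table Data frame `gene`, `log2fc_a`, `log2fc_b` with the
#'   per-line fold changes (used for ranking).
#' @param alpha Log-rank significance cutoff (default 0.05).
#' @return Data frame of candidate genes: `gene`, `direction`,
#'   `log2fc_a`, `log2fc_b`, `mean_log2fc`, `survival_hr`, `logrank_p`,
#'   `concordant` (all `TRUE` in the returned set).
#' @export
concordance_filter <- function(candidates, survival_results, fc_table,
                               alpha = 0.05) {
  genes <- c(candidates$up, candidates$down)
  direction <- rep(c("up", "down"),
                   c(length(candidates$up), length(candidates$down)))
  missing_surv <- setdiff(genes, survival_results$gene)
  if (length(missing_surv))
    stop("missing survival results for: ",
         paste(missing_surv, collapse = ", "), call. = FALSE)
  m <- match(genes, survival_results$gene)
  sr <- survival_results[m, , drop = FALSE]
  keep <- sr$logrank_p < alpha &
    ifelse(direction == "down", sr$low_group_worse, !sr$low_group_worse)
  out <- data.frame(gene = genes, direction = direction,
                    survival_hr = sr$hr, logrank_p = sr$logrank_p,
                    concordant = keep)
  fm <- match(out$gene, fc_table$gene)
  out$log2fc_a <- fc_table$log2fc_a[fm]
  out$log2fc_b <- fc_table$log2fc_b[fm]
  out$mean_log2fc <- rowMeans(cbind(out$log2fc_a, out$log2fc_b))
  out <- out[out$concordant, , drop = FALSE]
  out <- out[order(-abs(out$mean_log2fc)), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("gene", "direction", "log2fc_a", "log2fc_b", "mean_log2fc",
          "survival_hr", "logrank_p", "concordant")]
}

#' Simulate a two-group exponential survival cohort
#'
#' Generates subjects whose event times are exponential with a known
#' hazard ratio between a low- and a high-expression group (expression
#' values are drawn so that the median split exactly recovers the groups),
#' with optional administrative censoring. Used to benchmark the
#' Kaplan-Meier / log-rank machinery against a known truth.
#'
#' @param n_per_group Subjects per group.
#' @param hr True hazard ratio of the low-expression group relative to the
#'   high-expression group (`hr > 1` means low expression is worse).
#' @param baseline_rate Event rate of the high-expression group.
#' @param censor_time Administrative censoring time (`Inf` for none).
#' @param seed Integer seed (caller's RNG state is preserved).
#' @return Data frame `subject`, `time`, `event`, `expression`, `group`.
#' @export
simulate_survival_cohort <- function(n_per_group, hr = 2,
                                     baseline_rate = 0.1,
                                     censor_time = Inf, seed = 1L) {
  stopifnot(n_per_group >= 2, hr > 0, baseline_rate > 0)
  with_seed(seed, {
    n <- n_per_group
    t_low <- stats::rexp(n, rate = baseline_rate * hr)
    t_high <- stats::rexp(n, rate = baseline_rate)
    expr_low <- stats::runif(n, 0, 1)
    expr_high <- stats::runif(n, 2, 3)
    tt <- c(t_low, t_high)
    ev <- as.integer(tt <= censor_time)
    tt <- pmin(tt, censor_time)
    data.frame(subject = sprintf("s%03d", seq_len(2 * n)),
               time = tt, event = ev,
               expression = c(expr_low, expr_high),
               group = rep(c("low", "high"), each = n))
  })
}

#' Packaged cross-line fold-change fixture
#'
#' Reads the packaged table of top-ranked genes up- and down-regulated in
#' migratory relative to non-migratory cells in both breast-cancer cell
#' lines (SUM159 and MDA-MB-231), with each line's log2 fold change.
#'
#' @return Data frame `gene`, `direction` (`"up"`/`"down"`),
#'   `log2fc_sum159`, `log2fc_mdamb231`.
#' @export
read_table2_fixture <- function() {
  path <- system.file("extdata", "top_ranked_genes.csv",
                      package = "migratic", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Direction sets from the packaged fold-change fixture
#'
#' Builds per-line `{up, down}` gene sets from the packaged top-ranked
#' gene table (every listed gene is significant in both lines by
#' construction of the table), suitable for [overlap_concordant()].
#'
#' @param fixture Data frame as returned by [read_table2_fixture()].
#' @return List of two lists (`sum159`, `mdamb231`), each with `up` and
#'   `down` gene vectors.
#' @export
table2_sets <- function(fixture = read_table2_fixture()) {
  per_line <- function(lfc) {
    list(up = fixture$gene[lfc > 0], down = fixture$gene[lfc < 0])
  }
  list(sum159 = per_line(fixture$log2fc_sum159),
       mdamb231 = per_line(fixture$log2fc_mdamb231))
}
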