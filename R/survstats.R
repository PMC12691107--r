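#' Kaplan-Meier product-limit fit
#'
#' Right-censored product-limit estimator (ties at a time: events precede
#' censorings). The median is the smallest time at which the survival curve
#' reaches 0.5 or below, undefined (NA) when never attained.
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicators (TRUE/1 = event, FALSE/0 = censored).
#' @return Object of class `km_fit`: step-function grid (`time`, `surv`,
#'   `n_risk`, `n_event`, `n_censor`), `median`, `n` and the underlying
#'   [survival::survfit] object.
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0L) stop("no observations")
  if (length(times) != length(events))
    stop("times and events must have equal length")
  if (any(times < 0, na.rm = TRUE)) stop("times must be >= 0")
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1L]] else NA_real_
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor,
                 median = med, n = length(times), survfit = fit),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n = %d, events = %d, median = %s\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  plot(x$survfit, xlab = "time (days)", ylab = "survival probability", ...)
  invisible(x)
}

#' Log-rank test
#'
#' Standard log-rank chi-square (hypergeometric variance) across k groups,
#' with p from a chi-square distribution on k - 1 degrees of freedom.
#'
#' @param times,events As in [km_fit()].
#' @param group Group label per observation (>= 2 nonempty groups).
#' @return Object of class `sts_test`: `statistic`, `df`, `p`,
#'   `method = "logrank"`, `group_sizes`.
#' @export
logrank <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("log-rank needs >= 2 groups")
  sizes <- table(group)
  if (any(sizes == 0L))
    stop("group(s) with zero observations: ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  events <- as.logical(events)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  p <- stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  structure(list(statistic = unname(sd_$chisq), df = df, p = p,
                 method = "logrank", group_sizes = as.vector(sizes) |>
                   stats::setNames(names(sizes))),
            class = "sts_test")
}

#' @export
print.sts_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g (groups: %s)\n",
              x$method, x$statistic, x$p,
              paste(sprintf("%s n=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Median split of a gene's expression
#'
#' Assigns each sample to `"high"` when its value exceeds the cohort median,
#' else `"low"` (values exactly at the median are low). Used to dichotomize
#' MYC expression for survival comparisons; the cut quantile is configurable.
#'
#' @param m Expression matrix with gene symbols as rownames.
#' @param gene Gene symbol to split on.
#' @param quantile_cut Cut point as a quantile of the cohort (default 0.5).
#' @return Named character vector (`"high"`/`"low"`) per sample.
#' @export
median_split <- function(m, gene, quantile_cut = 0.5) {
  gene <- toupper(gene)
  if (!gene %in% toupper(rownames(m)))
    stop("gene not found in matrix: ", gene)
  v <- as_plain_matrix(m)
  rownames(v) <- toupper(rownames(v))
  x <- v[gene, ]
  cut <- stats::quantile(x, quantile_cut, names = FALSE, type = 7)
  grp <- ifelse(x > cut, "high", "low")
  if (all(grp == "low"))
    message("degenerate split for ", gene, ": no value above the cut")
  stats::setNames(grp, colnames(v))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with average-tie ranks. The exact null
#' distribution is used when the pooled size is at most 12 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Nonempty numeric vectors.
#' @return Object of class `sts_test`: rank-sum `statistic` (Mann-Whitney U
#'   of `x`), `p`, `method = "wilcoxon"`, `group_sizes`, `exact` flag.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                 method = "wilcoxon", exact = exact,
                 group_sizes = c(x = length(x), y = length(y))),
            class = "sts_test")
}
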