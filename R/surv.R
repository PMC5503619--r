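# Kaplan-Meier curves and multi-group log-rank tests. The estimators
# themselves come from the survival package; these wrappers fix the cohort
# conventions (events before censorings at tied times, months as the time
# unit) and the output shape.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate over the pooled event/censoring time grid.
#' Samples censored at an event time are counted at risk for that time
#' (events precede censorings at ties, the standard product-limit
#' convention).
#'
#' @param time positive follow-up times (months).
#' @param event event indicator, 1 = event, 0 = censored.
#' @return A `km_curve` data frame: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (stepwise non-increasing, `S(0) = 1` implicitly).
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time <= 0)) stop("times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Kaplan-Meier curves per group
#'
#' @inheritParams kaplan_meier
#' @param group group labels per sample.
#' @return Named list of `km_curve` data frames, one per group level.
#' @export
km_by_group <- function(time, event, group) {
  stopifnot(length(group) == length(time))
  idx <- split(seq_along(time), group)
  lapply(idx, function(i) kaplan_meier(time[i], event[i]))
}

#' Multi-group log-rank test
#'
#' Standard g-group log-rank test: observed versus expected events per
#' group across the pooled event times; the statistic is referred to a
#' chi-square distribution with g - 1 degrees of freedom.
#'
#' @inheritParams km_by_group
#' @return List: `statistic`, `df`, `p`, `n` (per-group sizes),
#'   `observed`, `expected` (per-group event counts).
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(group) == length(time))
  if (any(time <= 0)) stop("times must be > 0")
  g <- factor(group)
  if (nlevels(g) < 2) stop("log-rank test needs >= 2 groups")
  if (any(table(g) == 0)) stop("every group must be nonempty")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       n = as.numeric(sd$n), observed = as.numeric(sd$obs),
       expected = as.numeric(sd$exp))
}
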