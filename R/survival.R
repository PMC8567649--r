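# Survival endpoints: Kaplan-Meier estimation, log-rank comparison and Cox
# proportional-hazards models, via the survival package behind a thin
# cohort-oriented surface. Times are in months; event = 1 means the event
# (death or progression) was observed, 0 means censored.

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator with Greenwood standard errors. The median is
#' the first event time at which the survival curve drops to 0.5 or below,
#' `NA` if that never happens.
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return List with `curve` (data.frame `time`, `n_risk`, `n_event`,
#'   `surv`, `std_err`), `median`, `n`, `n_events`.
#' @export
km_fit <- function(time, event) {
  if (length(time) < 1) stop("need at least one record")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  s <- summary(fit, censored = FALSE)
  curve <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                      surv = s$surv, std_err = s$std.err)
  med <- if (any(curve$surv <= 0.5)) min(curve$time[curve$surv <= 0.5])
         else NA_real_
  list(curve = curve, median = med, n = length(time), n_events = sum(event))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square with hypergeometric
#' variance, 1 degree of freedom.
#'
#' @param time,event As in [km_fit()].
#' @param group Two-level group labels.
#' @return List with `chisq`, `df`, `p`, and per-group observed/expected
#'   event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) == 0)) stop("both groups must be non-empty")
  if (sum(event) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood with Efron tie handling. Hazard ratios are
#' `exp(coef)` with Wald 95% confidence intervals.
#'
#' @param time,event As in [km_fit()].
#' @param covariates Data.frame of covariates (no constant column).
#' @param ties Tie-handling method, default `"efron"`.
#' @return List with `table` (data.frame `term`, `coef`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p`), `loglik` (at the optimum), and the
#'   underlying `coxph` fit.
#' @export
cox_fit <- function(time, event, covariates, ties = "efron") {
  covariates <- as.data.frame(covariates)
  n_num <- vapply(covariates, function(x)
    length(unique(x[!is.na(x)])), integer(1))
  if (any(n_num < 2)) {
    stop("constant covariate(s): ",
         paste(names(covariates)[n_num < 2], collapse = ", "))
  }
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (sum(df$.event) < ncol(covariates) + 1) {
    stop("too few events for the number of covariates")
  }
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~",
                            paste(names(covariates), collapse = " + "))),
    data = df, ties = ties,
    control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  if (!is.null(fit$info) && isTRUE(fit$fail)) stop("Cox fit failed")
  sm <- summary(fit)
  co <- sm$coefficients
  tab <- data.frame(term = rownames(co), coef = co[, "coef"],
                    se = co[, "se(coef)"], hr = exp(co[, "coef"]),
                    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, loglik = fit$loglik[2], fit = fit)
}

#' Forest-plot table from one or more Cox fits
#'
#' Flattens `cox_fit()` results into the covariate / HR / CI / p layout
#' used for forest plots.
#'
#' @param ... Named results of [cox_fit()].
#' @return Data.frame with columns `model`, `term`, `hr`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
forest_table <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  do.call(rbind, lapply(names(fits), function(nm) {
    cbind(model = nm,
          fits[[nm]]$table[, c("term", "hr", "ci_low", "ci_high", "p")])
  }))
}
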