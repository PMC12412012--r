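# Median-split survival stratification: Kaplan-Meier estimation, the
# two-group log-rank test, and Cox proportional-hazards fits with Wald 95%
# CIs on the hazard-ratio scale. Estimation is delegated to the survival
# package (Breslow tie handling throughout); this file defines the package's
# stable surface and conventions (median tie rule, CI convention).

#' Median dichotomization into high/low groups
#'
#' Samples strictly above the sample median are labeled `"high"`, all
#' others (including exact ties with the median) `"low"`. The tie rule is
#' deterministic and keeps the high group at most half the samples.
#'
#' @param values Numeric vector (e.g. one gene's expression or the
#'   Glyco-MSI score), `n >= 2`.
#' @return Character vector of `"high"`/`"low"`, named like `values`.
#' @export
dichotomize_at_median <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  m <- stats::median(values)
  stats::setNames(ifelse(values > m, "high", "low"), names(values))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative event/censoring times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A list of class `"km_curve"`: `event_times` (sorted distinct
#'   times with at least one event), `at_risk`, `events`, `survival` (the
#'   product-limit estimate just after each event time), plus `n` and
#'   `n_events`. Censored-only times reduce later risk sets but contribute
#'   no factor. Use [km_survival()] to evaluate the step function.
#' @examples
#' km <- km_estimate(c(5, 10, 15), c(1, 0, 1))
#' km$survival  # 2/3 at t = 5, 0 at t = 15
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("times must be non-negative")
  if (length(time) != length(event) || length(time) == 0)
    stop("time and event must be equal-length, non-empty")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 at_risk = fit$n.risk[keep],
                 events = fit$n.event[keep],
                 survival = fit$surv[keep],
                 n = length(time), n_events = sum(event)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `"km_curve"` from [km_estimate()].
#' @param times Times at which to evaluate the survival step function.
#' @return Survival probabilities; 1 before the first event time.
#' @export
km_survival <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  if (length(curve$event_times) == 0) return(rep(1, length(times)))
  f <- stats::stepfun(curve$event_times, c(1, curve$survival), right = FALSE)
  f(times)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events\n",
              x$n, x$n_events))
  print(data.frame(time = x$event_times, at_risk = x$at_risk,
                   events = x$events, survival = x$survival))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance at each distinct
#' event time; the statistic is chi-square with 1 df under the null.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level group labels.
#' @return List of class `"logrank_result"` with `statistic`, `p_value`,
#'   `df`, and per-group `n`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("exactly two non-empty groups required")
  if (sum(event) == 0) stop("no events in the data")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  structure(list(statistic = as.numeric(fit$chisq),
                 p_value = stats::pchisq(fit$chisq, df = 1,
                                         lower.tail = FALSE),
                 df = 1L, n = fit$n, observed = fit$obs,
                 expected = fit$exp),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4f (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow handling of tied event
#' times; hazard ratios with 95% Wald confidence intervals
#' `exp(beta +/- 1.96 se)`.
#'
#' @param data `data.frame` with columns `time`, `event`, and the
#'   covariates.
#' @param covariates Character vector of covariate column names; two-level
#'   character/factor columns are coded 0/1 automatically by the model
#'   matrix.
#' @return A list of class `"cox_result"`: `coefficients` (a `data.frame`
#'   with `term`, `beta`, `hr`, `se`, `ci_low`, `ci_high`, `z`, `p_value`),
#'   `n`, `n_events`, `converged`.
#' @export
cox_fit <- function(data, covariates) {
  if (!all(c("time", "event") %in% names(data)))
    stop("data must contain 'time' and 'event' columns")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariates not in data: ", paste(missing_cov, collapse = ", "))
  if (sum(data$event) == 0) stop("no events in the data")
  for (cv in covariates) {
    v <- data[[cv]]
    if (length(unique(v)) < 2)
      stop("constant covariate: ", cv)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se))) converged <- FALSE
  z <- beta / se
  coefs <- data.frame(term = names(beta), beta = as.numeric(beta),
                      hr = exp(beta), se = as.numeric(se),
                      ci_low = exp(beta - 1.96 * se),
                      ci_high = exp(beta + 1.96 * se),
                      z = as.numeric(z),
                      p_value = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = coefs, n = fit$n, n_events = fit$nevent,
                 converged = converged),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit (Breslow ties): n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Median-split survival analysis of a marker
#'
#' The package's standard stratification: dichotomize a per-sample marker
#' (a gene's expression or the Glyco-MSI score) at its median, then compare
#' the high and low groups by Kaplan-Meier curves, the log-rank test, and a
#' univariable Cox model of the high-vs-low indicator (HR < 1 means lower
#' hazard in the high group).
#'
#' @param time,event Survival outcome, aligned with `values`.
#' @param values Per-sample marker values.
#' @return A list with `groups`, per-group `km` curves, `logrank`, `cox`.
#' @export
median_split_survival <- function(time, event, values) {
  groups <- dichotomize_at_median(values)
  if (length(unique(groups)) < 2)
    stop("median split produced a single group (all values tied)")
  df <- data.frame(time = time, event = event,
                   high = as.integer(groups == "high"))
  list(groups = groups,
       km = list(high = km_estimate(time[groups == "high"],
                                    event[groups == "high"]),
                 low = km_estimate(time[groups == "low"],
                                   event[groups == "low"])),
       logrank = logrank_test(time, event, groups),
       cox = cox_fit(df, "high"))
}
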