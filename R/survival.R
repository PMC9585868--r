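# Kaplan-Meier, log-rank and Cox proportional-hazards analyses of
# disease-free survival, with TSR entered as a categorical (stroma-low vs
# stroma-high) or continuous (per 10 percentage points of stroma)
# covariate. Estimation is delegated to the survival package (survfit,
# survdiff, coxph with Efron tie handling); this module fixes the
# encodings, reference levels and reporting conventions.

#' Administrative censoring at a follow-up horizon
#'
#' Times beyond the horizon are truncated to it and their events set to 0.
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicators (0/1).
#' @param horizon Horizon in months (default 60, five years).
#' @return List with censored `time` and `event`.
#' @export
censor_at_horizon <- function(time, event, horizon = 60) {
  if (horizon <= 0) stop_validation("horizon must be positive")
  over <- time > horizon
  list(time = pmin(time, horizon),
       event = ifelse(over, 0L, as.integer(event)))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (0/1).
#' @return An object of class `tsr_km`: `event_times` (distinct event
#'   times), `survival`, `at_risk`, `n_events`, plus `n`. A fully censored
#'   sample yields empty vectors, i.e. the constant curve S(t) = 1.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop_validation("km_estimate needs n >= 1")
  if (any(time <= 0)) stop_validation("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep],
                 n_events = fit$n.event[keep],
                 n = length(time)),
            class = "tsr_km")
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param km A `tsr_km`.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  if (length(km$event_times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, km$event_times)
  c(1, km$survival)[idx + 1]
}

#' Tidy KM curves by group
#'
#' @param time,event Survival data.
#' @param group Grouping factor.
#' @return data.frame with `group`, `time`, `survival`, `at_risk`,
#'   `n_events` — one row per distinct event time per group, suitable for
#'   plotting or CSV export.
#' @export
km_by_group <- function(time, event, group) {
  group <- as.factor(group)
  do.call(rbind, lapply(levels(group), function(g) {
    sel <- group == g
    km <- km_estimate(time[sel], event[sel])
    if (length(km$event_times) == 0) return(NULL)
    data.frame(group = g, time = km$event_times,
               survival = km$survival, at_risk = km$at_risk,
               n_events = km$n_events, stringsAsFactors = FALSE)
  }))
}

#' k-sample log-rank test
#'
#' Standard log-rank chi-square with k - 1 degrees of freedom; for two
#' groups it equals the square of [logrank_z()].
#'
#' @param time,event Survival data.
#' @param group Grouping factor with >= 2 nonempty levels.
#' @return List with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2)
    stop_validation("log-rank test needs >= 2 nonempty groups")
  if (sum(event) < 1)
    stop_validation("log-rank test undefined with zero events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(chi_square = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Continuous TSR covariate in stroma units
#'
#' Hazard ratios for continuous TSR are reported per 10 percentage points
#' of stroma: the covariate is `(100 - TSR) / 10`, so an HR above 1 means
#' more stroma, shorter survival. `orientation = "tumor"` gives `TSR / 10`
#' instead.
#'
#' @param tsr TSR percents in `[0, 100]`.
#' @param per Unit size in percentage points (default 10).
#' @param orientation `"stroma"` (default) or `"tumor"`.
#' @return Numeric covariate values.
#' @export
continuous_tsr_covariate <- function(tsr, per = 10,
                                     orientation = c("stroma", "tumor")) {
  orientation <- match.arg(orientation)
  if (any(tsr < 0 | tsr > 100, na.rm = TRUE))
    stop_validation("tsr must be in [0, 100]")
  if (orientation == "stroma") (100 - tsr) / per else tsr / per
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron handling of tied event
#' times (via `survival::coxph`). Wald 95 percent confidence intervals use
#' z = 1.96; coefficients with |beta| > 10 are flagged as possible
#' monotone-likelihood (separation) cases and the fit marked
#' non-converged.
#'
#' @param data data.frame containing the covariates (factors must carry
#'   their reference level first).
#' @param time,event Survival data (or names of columns in `data`).
#' @param covariates Character vector of covariate column names.
#' @param ties Tie handling passed to `coxph` ("efron" or "breslow").
#' @return An object of class `tsr_coxfit`: per-term `coefficients`,
#'   `se`, `hr`, `ci_lower`, `ci_upper`, `wald_p`, plus `loglik` (at the
#'   optimum), `loglik_null`, `n`, `n_events`, `converged`, `flags` and
#'   the underlying `fit`.
#' @export
cox_fit <- function(data, time = "time_months", event = "event",
                    covariates, ties = "efron") {
  if (is.character(time)) time <- data[[time]]
  if (is.character(event)) event <- data[[event]]
  stopifnot(length(covariates) >= 1)
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.null(x)) stop_validation("covariate not found: ", cv)
    if (length(unique(x[!is.na(x)])) < 2)
      stop_validation("covariate constant across subjects: ", cv)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  # evaluate Surv() against the supplied vectors
  environment(fml) <- list2env(list(time = time, event = event),
                               parent = environment())
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties, model = TRUE, x = TRUE),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (sum(event) < length(beta))
    flags <- c(flags, "fewer events than parameters")
  separation <- any(abs(beta) > 10, na.rm = TRUE)
  if (separation)
    flags <- c(flags, "possible monotone likelihood (separation)")
  converged <- !separation && !any(is.na(beta)) &&
    !any(grepl("did not converge|infinite", flags, ignore.case = TRUE))
  z <- beta / se
  structure(list(coefficients = beta, se = se, hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 n = fit$n, n_events = fit$nevent,
                 converged = converged, flags = unique(flags),
                 fit = fit),
            class = "tsr_coxfit")
}

#' @export
print.tsr_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d%s\n", x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  df <- data.frame(HR = sprintf("%.2f", x$hr),
                   `95% CI` = sprintf("%.2f-%.2f", x$ci_lower, x$ci_upper),
                   P = format_pvalue(x$wald_p), check.names = FALSE)
  rownames(df) <- names(x$coefficients)
  print(df)
  invisible(x)
}

#' Tidy Cox results in the shape of a univariate/multivariate report
#'
#' @param x A `tsr_coxfit`.
#' @param model Label for the model column.
#' @return data.frame with term, HR, CI bounds, formatted p.
#' @export
cox_report <- function(x, model = "model") {
  data.frame(model = model, term = names(x$coefficients),
             hr = unname(x$hr), ci_lower = unname(x$ci_lower),
             ci_upper = unname(x$ci_upper), p = unname(x$wald_p),
             p_formatted = format_pvalue(unname(x$wald_p)),
             n = x$n, n_events = x$n_events,
             converged = x$converged, stringsAsFactors = FALSE)
}

#' Log-rank vs Cox score test duality check
#'
#' The Cox partial-likelihood score test at beta = 0 for a two-group
#' indicator with Breslow tie handling equals the log-rank chi-square; the
#' agreement is exact when no event times are tied. Useful as a built-in
#' cross-validation of the two routes.
#'
#' @param time,event Survival data.
#' @param group1 Two-group membership indicator.
#' @return List with `logrank_chisq` (from [logrank_z()]),
#'   `cox_score_chisq` (from `coxph`), and their relative difference.
#' @export
score_test_equivalence <- function(time, event, group1) {
  g <- as.integer(as.logical(group1))
  if (sum(event) < 1) {
    return(list(logrank_chisq = 0, cox_score_chisq = 0, rel_diff = 0))
  }
  z2 <- tryCatch(logrank_z(time, event, g == 1)^2,
                 tsr_validation_error = function(e) 0)
  fit <- survival::coxph(survival::Surv(time, event) ~ g,
                         ties = "breslow")
  sc <- unname(summary(fit)$sctest["test"])
  denom <- max(abs(z2), abs(sc))
  list(logrank_chisq = z2, cox_score_chisq = sc,
       rel_diff = if (denom == 0) 0 else abs(z2 - sc) / denom)
}
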