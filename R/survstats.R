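#' Spearman rank correlation
#'
#' Midrank-tie Spearman correlation with a two-sided p-value from the
#' t approximation (the usual large-sample treatment when ties are present).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list `rho`, `p`, `n`; `rho` is `NA` (with a warning) when either
#'   vector is constant.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

as_surv_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time_months", "event") %in% names(records)))
  if (any(!is.finite(records$time_months)) || any(records$time_months < 0))
    stop("survival times must be finite and nonnegative")
  records
}

#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator; the median is the first time at which the
#' survival curve drops to 0.5 or below, reported as `NA` ("not reached")
#' when the curve stays above 0.5 throughout follow-up.
#'
#' @param records data.frame with `time_months` and `event` (0/1).
#' @return list `time`, `surv` (step curve), `median_months` (NA = not
#'   reached), `median_ci` (95% CI bounds, NA where not reached), `n`,
#'   `n_events`.
#' @export
km_estimate <- function(records) {
  records <- as_surv_records(records)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = records, conf.type = "log-log"
  )
  tab <- summary(fit)$table
  list(time = fit$time, surv = fit$surv,
       median_months = unname(tab["median"]),
       median_ci = c(lower = unname(tab["0.95LCL"]),
                     upper = unname(tab["0.95UCL"])),
       n = unname(tab["records"]), n_events = unname(tab["events"]))
}

#' Median follow-up time by inverse Kaplan-Meier estimation
#'
#' The reverse Kaplan-Meier estimator: event and censoring indicators are
#' swapped so censorings are the "events", and the resulting median is the
#' median potential follow-up.
#'
#' @param records data.frame with `time_months` and `event`.
#' @return list `median_months` (NA with a warning when every subject had an
#'   event, leaving the reverse curve without an estimable median) and
#'   `median_ci`.
#' @export
median_followup_inverse_km <- function(records) {
  records <- as_surv_records(records)
  if (all(records$event == 1))
    warning("no censored observations; reverse Kaplan-Meier median is not estimable")
  flipped <- records
  flipped$event <- 1L - records$event
  km_estimate(flipped)[c("median_months", "median_ci")]
}

#' Two-group log-rank test
#'
#' Standard 1-degree-of-freedom log-rank test.
#'
#' @param records data.frame with `time_months` and `event`.
#' @param group vector coercible to a 2-level factor, one value per record.
#' @return list `chi2`, `p`, `n_per_group`.
#' @export
log_rank_test <- function(records, group) {
  records <- as_surv_records(records)
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("log-rank test requires exactly two nonempty groups")
  if (sum(records$event) == 0L)
    stop("log-rank test requires at least one event")
  sd <- survival::survdiff(
    survival::Surv(records$time_months, records$event) ~ g
  )
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chi2 = unname(sd$chisq), p = p, n_per_group = as.vector(table(g)))
}

#' Dichotomize a marker at its median
#'
#' High group = strictly above the sample median; values at the median go to
#' the low group.
#'
#' @param values numeric vector of length >= 2.
#' @return logical vector, `TRUE` = high.
#' @export
dichotomize_at_median <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  med <- stats::median(values)
  out <- values > med
  if (!any(out)) warning("no value above the median; high group is empty")
  out
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit via `survival::coxph` with Efron tie handling
#' (Breslow available), Wald 95% confidence intervals and p-values per
#' covariate. Supports a single covariate (univariable) or several
#' (e.g. a PET burden metric adjusted for infiltration rate and high-risk
#' cytogenetics).
#'
#' @param records data.frame with `time_months`, `event` and the covariates.
#' @param covariates character vector of column names.
#' @param ties "efron" (default) or "breslow".
#' @return list of class `cox_fit_result`: `table` (data.frame with
#'   `covariate`, `coef`, `hr`, `hr_lower`, `hr_upper`, `p`), `loglik`, `n`,
#'   `n_events`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  records <- as_surv_records(records)
  if (!all(covariates %in% names(records)))
    stop("missing covariate column(s): ",
         paste(setdiff(covariates, names(records)), collapse = ", "))
  for (cv in covariates) {
    v <- records[[cv]]
    if (any(is.na(v))) stop("covariate `", cv, "` contains missing values")
    if (length(unique(v)) == 1L)
      stop("covariate `", cv, "` is constant; hazard ratio unidentifiable")
  }
  if (sum(records$event) < 2L) stop("need at least 2 events")
  fml <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = ties)
  if (!is.null(fit$info) || any(!is.finite(stats::coef(fit))))
    stop("Cox model failed to converge")
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- co / se
  tab <- data.frame(covariate = names(co), coef = unname(co),
                    hr = exp(unname(co)),
                    hr_lower = exp(unname(co - 1.96 * se)),
                    hr_upper = exp(unname(co + 1.96 * se)),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, n_events = fit$nevent),
            class = "cox_fit_result")
}

#' Binary outcome at a fixed horizon
#'
#' Classifies each subject for an event-within-horizon analysis: positive if
#' the event occurred at or before the horizon, negative if followed
#' event-free past it. Subjects censored before the horizon cannot be
#' classified and are marked non-evaluable.
#'
#' @param records data.frame with `time_months` and `event`.
#' @param horizon_months horizon; default 24 (2-year outcome).
#' @return list `label` (logical, NA = non-evaluable), `evaluable` (logical).
#' @export
binary_outcome_at_horizon <- function(records, horizon_months = 24) {
  records <- as_surv_records(records)
  if (horizon_months <= 0) stop("`horizon_months` must be positive")
  pos <- records$event == 1 & records$time_months <= horizon_months
  neg <- records$time_months > horizon_months
  evaluable <- pos | neg
  if (!any(evaluable)) stop("no subject is evaluable at the given horizon")
  label <- ifelse(evaluable, pos, NA)
  list(label = label, evaluable = evaluable)
}

# Youden-optimal cut over the empirical ROC: candidate cuts are midpoints
# between consecutive unique marker values (plus the extremes); a subject is
# test-positive when marker >= cut; ties in sensitivity+specificity break
# toward the lower cut value
youden_cut <- function(marker, label) {
  u <- sort(unique(marker))
  cuts <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  npos <- sum(label); nneg <- sum(!label)
  best <- NULL
  for (ct in cuts) {
    sens <- sum(marker >= ct & label) / npos
    spec <- sum(marker < ct & !label) / nneg
    j <- sens + spec
    if (is.null(best) || j > best$j + 1e-12) best <- list(cut = ct, sens = sens,
                                                         spec = spec, j = j)
  }
  best
}

#' ROC analysis with Youden-optimal cut point
#'
#' Empirical ROC of a continuous marker against a binary outcome. AUC with
#' DeLong 95% confidence interval and a two-sided p-value for AUC = 0.5
#' (DeLong variance); the operating point maximizes sensitivity +
#' specificity (the Youden index), with ties broken toward the lower cut.
#'
#' @param marker numeric vector.
#' @param label logical/0-1 vector; both classes must be present.
#' @return list of class `roc_result`: `auc`, `auc_ci`, `p`, `cut`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
roc_youden <- function(marker, label) {
  label <- as.logical(label)
  keep <- !is.na(label)
  marker <- marker[keep]; label <- label[keep]
  if (!any(label) || all(label))
    stop("both outcome classes must be present for ROC analysis")
  r <- pROC::roc(response = label, predictor = marker,
                 direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  # pROC warns that CI/variance are degenerate at AUC exactly 1; the
  # degenerate case is handled explicitly below
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  # DeLong variance degenerates (0 or NA) for tiny or perfectly separated
  # samples; report the p-value accordingly rather than dividing by zero
  p <- if (!is.finite(v)) NA_real_
  else if (v <= 0) ifelse(auc == 0.5, 1, 0)
  else 2 * stats::pnorm(-abs(auc - 0.5) / sqrt(v))
  cutres <- youden_cut(marker, label)
  structure(list(auc = auc, auc_ci = c(lower = ci[1], upper = ci[2]), p = p,
                 cut = cutres$cut, sensitivity = cutres$sens,
                 specificity = cutres$spec,
                 n_pos = sum(label), n_neg = sum(!label)),
            class = "roc_result")
}

#' ROC for survival at a horizon (binary or IPCW mode)
#'
#' `mode = "binary"` excludes subjects censored before the horizon and runs
#' [roc_youden()] on the rest. `mode = "ipcw"` keeps all subjects and
#' computes an inverse-probability-of-censoring weighted AUC (cumulative
#' cases / dynamic controls at the horizon, weights from the reverse
#' Kaplan-Meier censoring curve); no CI is attached in this mode.
#'
#' @param records data.frame with `time_months`, `event`, and the marker.
#' @param marker_col marker column name.
#' @param horizon_months horizon (default 24).
#' @param mode "binary" (default) or "ipcw".
#' @return a `roc_result` (binary mode) or list `auc`, `n_cases`,
#'   `n_controls` (ipcw mode).
#' @export
roc_at_horizon <- function(records, marker_col, horizon_months = 24,
                           mode = c("binary", "ipcw")) {
  mode <- match.arg(mode)
  records <- as_surv_records(records)
  marker <- records[[marker_col]]
  if (mode == "binary") {
    bo <- binary_outcome_at_horizon(records, horizon_months)
    return(roc_youden(marker[bo$evaluable], bo$label[bo$evaluable]))
  }
  # IPCW: censoring survival G from the reverse KM curve
  flipped <- records; flipped$event <- 1L - records$event
  gfit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                            data = flipped)
  G <- stats::stepfun(gfit$time, c(1, gfit$surv))
  cases <- which(records$event == 1 & records$time_months <= horizon_months)
  controls <- which(records$time_months > horizon_months)
  if (length(cases) == 0L || length(controls) == 0L)
    stop("both cases and controls are required at the horizon")
  wc <- 1 / pmax(G(records$time_months[cases]), 1e-10)
  wk <- rep(1 / pmax(G(horizon_months), 1e-10), length(controls))
  num <- 0; den <- 0
  for (i in seq_along(cases)) {
    mi <- marker[cases[i]]
    conc <- sum(wk * ((marker[controls] < mi) + 0.5 * (marker[controls] == mi)))
    num <- num + wc[i] * conc
    den <- den + wc[i] * sum(wk)
  }
  list(auc = num / den, n_cases = length(cases), n_controls = length(controls))
}

#' International Staging System (ISS) stage
#'
#' Stage I: beta2-microglobulin < 3.5 mg/L and albumin >= 3.5 g/dL.
#' Stage III: beta2-microglobulin > 5.5 mg/L. Stage II: everything else.
#'
#' @param b2m_mg_l serum beta2-microglobulin (mg/L), nonnegative.
#' @param albumin_g_dl serum albumin (g/dL), nonnegative.
#' @return integer stage 1, 2 or 3 (vectorised).
#' @export
iss_stage <- function(b2m_mg_l, albumin_g_dl) {
  if (any(b2m_mg_l < 0) || any(albumin_g_dl < 0))
    stop("inputs must be nonnegative")
  ifelse(b2m_mg_l > 5.5, 3L,
         ifelse(b2m_mg_l < 3.5 & albumin_g_dl >= 3.5, 1L, 2L))
}

#' Revised ISS (R-ISS) stage
#'
#' Stage I: ISS I with neither high-risk cytogenetics (del(17p), t(4;14) or
#' t(14;16)) nor elevated LDH. Stage III: ISS III with high-risk
#' cytogenetics or elevated LDH. Stage II: all other combinations.
#'
#' @param iss integer ISS stage (1..3).
#' @param high_risk logical, high-risk chromosomal abnormality present.
#' @param ldh_high logical, LDH above the upper limit of normal.
#' @return integer stage 1, 2 or 3 (vectorised).
#' @export
r_iss_stage <- function(iss, high_risk, ldh_high) {
  if (any(!iss %in% 1:3)) stop("`iss` must be 1, 2 or 3")
  ifelse(iss == 1L & !high_risk & !ldh_high, 1L,
         ifelse(iss == 3L & (high_risk | ldh_high), 3L, 2L))
}
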