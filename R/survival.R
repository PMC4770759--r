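#' Censor follow-up at allogeneic transplant
#'
#' Patients with a recorded stem-cell-infusion date are censored on that
#' day: `os_time` becomes `hsct_time` and `os_event` 0. Avoids confounding
#' of the chemotherapy-response signal by transplant outcomes.
#'
#' @param clinical data.frame with `os_time`, `os_event`, and an optional
#'   `hsct_time` column (NA where no transplant).
#' @return The clinical table with censoring applied.
#' @export
apply_hsct_censoring <- function(clinical) {
  if (is.null(clinical$hsct_time)) return(clinical)
  h <- clinical$hsct_time
  has <- !is.na(h)
  if (any(has & h > clinical$os_time))
    stop("hsct_time exceeds os_time for: ",
         paste(clinical$sample_id[has & h > clinical$os_time], collapse = ", "))
  clinical$os_time[has] <- h[has]
  clinical$os_event[has] <- 0L
  clinical
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per group, with the median survival time defined
#' as the first time the curve drops to 0.5 or below ("not reached" when it
#' never does).
#'
#' @param times,events numeric vectors (months, 0/1 indicator).
#' @param groups group labels (single group when omitted).
#' @return List with `curves` (data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`) and `medians` (data.frame: `group`, `median` months
#'   or NA, `reached` flag; serialize NA as the token "not reached").
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(times))
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  groups <- as.factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(groups)[1], length(sm$time))
         else sub("^groups=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv,
                       stringsAsFactors = FALSE)
  med <- vapply(split(curves, curves$group), function(d) {
    i <- which(d$surv <= 0.5)
    if (length(i) == 0) NA_real_ else d$time[min(i)]
  }, numeric(1))
  list(curves = curves,
       medians = data.frame(group = names(med), median = unname(med),
                            reached = !is.na(med), stringsAsFactors = FALSE))
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank chi-square comparing survival between
#' groups.
#'
#' @param times,events,groups as in [km_estimate()]; >= 2 groups and >= 1
#'   event required.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("log-rank needs >= 2 groups")
  if (sum(events) < 1) stop("log-rank undefined with zero events")
  d <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(d$n) - 1
  list(chisq = unname(d$chisq), df = df,
       p = stats::pchisq(d$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie approximation.
#' Supports a single covariate (the univariate screen) or several (the
#' multivariate adjusted model). P-values and confidence intervals are
#' Wald-based: `CI = exp(coef +/- 1.96 se)`.
#'
#' @param clinical data.frame containing `os_time`, `os_event`, and every
#'   covariate named; no missing covariate values are allowed among the
#'   included rows.
#' @param covariates character vector of column names to enter the model.
#' @return A data.frame of class `cox_fit`: `term`, `coef`, `hr`, `ci_low`,
#'   `ci_high`, `se`, `z`, `p`, with the model log-likelihood in attribute
#'   `loglik`.
#' @export
cox_fit <- function(clinical, covariates) {
  stopifnot(length(covariates) >= 1)
  miss <- setdiff(c("os_time", "os_event", covariates), names(clinical))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  d <- clinical[, c("os_time", "os_event", covariates), drop = FALSE]
  if (anyNA(d))
    stop("missing covariate or survival values among included samples")
  if (sum(d$os_event) < 2) stop("fewer than 2 events; cannot fit")
  fml <- stats::as.formula(paste(
    "survival::Surv(os_time, os_event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite|Loglik converged", conditionMessage(w)))
        stop("Cox fit failed (separation or non-convergence): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)$coefficients
  out <- data.frame(term = rownames(s),
                    coef = s[, "coef"],
                    hr = exp(s[, "coef"]),
                    ci_low = exp(s[, "coef"] - 1.96 * s[, "se(coef)"]),
                    ci_high = exp(s[, "coef"] + 1.96 * s[, "se(coef)"]),
                    se = s[, "se(coef)"], z = s[, "z"],
                    p = s[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "loglik") <- fit$loglik[2]
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Write Kaplan-Meier curves as step-function CSV
#'
#' @param km output of [km_estimate()].
#' @param path output path. Medians are appended as comment lines with the
#'   "not reached" token where the curve never crosses 0.5.
#' @export
write_km_csv <- function(km, path) {
  utils::write.csv(km$curves, path, row.names = FALSE, quote = FALSE)
  meds <- sprintf("# median %s: %s", km$medians$group,
                  ifelse(km$medians$reached,
                         format(km$medians$median), "not reached"))
  cat(meds, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
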