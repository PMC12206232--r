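#' Logistic incidence model for a binary outcome
#'
#' Orchestrates a standard logistic fit of a binary outcome (e.g. diagnosis
#' registered before or after baseline) on an mLOY variable plus adjustment
#' covariates, reporting odds ratios with Wald confidence intervals.  The
#' mLOY variable may be the continuous percent or a categorical flag
#' (detectable/high).  The exact formula used is attached for audit.
#'
#' @param table cohort data.frame.
#' @param outcome name of the binary outcome column.
#' @param mloy_var name of the mLOY column (numeric or logical/factor).
#' @param covariates character vector of adjustment column names.
#' @param conf_level CI level.
#' @return data.frame: `term`, `estimate` (log-odds), `or`, `ci_low`,
#'   `ci_high`, `p_value`; attributes `"formula"` and `"converged"`.
#'   Non-convergence is reported via warning and the attribute, never
#'   silently dropped.
#' @export
fit_incidence_model <- function(table, outcome = "diagnosed",
                                mloy_var = "mloy_percent",
                                covariates = character(0), conf_level = 0.95) {
  fml <- as.formula(paste(outcome, "~",
                          paste(c(mloy_var, covariates), collapse = " + ")))
  fit <- glm(fml, data = table, family = stats::binomial())
  if (!fit$converged) warning("logistic model did not converge")
  coefs <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = rownames(coefs), estimate = coefs[, 1],
                    or = exp(coefs[, 1]),
                    ci_low = exp(coefs[, 1] - z * coefs[, 2]),
                    ci_high = exp(coefs[, 1] + z * coefs[, 2]),
                    p_value = coefs[, 4], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "formula") <- deparse(fml)
  attr(out, "converged") <- fit$converged
  out
}

#' Cox proportional-hazards model for time-to-event outcomes
#'
#' Orchestrates `survival::coxph` (Efron tie handling by default) for an
#' event outcome over follow-up time, reporting hazard ratios with
#' confidence intervals.
#'
#' @param table cohort data.frame with event and time columns.
#' @param time,event names of the follow-up time and event-indicator
#'   columns.
#' @param mloy_var,covariates as in [fit_incidence_model()].
#' @param ties tie-handling method passed to `coxph`.
#' @param conf_level CI level.
#' @return data.frame: `term`, `estimate` (log-hazard), `hr`, `ci_low`,
#'   `ci_high`, `p_value`; attribute `"formula"`.
#' @export
fit_survival_model <- function(table, time = "time", event = "event",
                               mloy_var = "mloy_percent",
                               covariates = character(0), ties = "efron",
                               conf_level = 0.95) {
  fml <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                           paste(c(mloy_var, covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = table, ties = ties)
  coefs <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = rownames(coefs), estimate = coefs[, "coef"],
                    hr = exp(coefs[, "coef"]),
                    ci_low = exp(coefs[, "coef"] - z * coefs[, "se(coef)"]),
                    ci_high = exp(coefs[, "coef"] + z * coefs[, "se(coef)"]),
                    p_value = coefs[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "formula") <- deparse(fml)
  attr(out, "ties") <- ties
  out
}

#' Linear model for lung-function outcomes
#'
#' FVC or DLCO regressed on an mLOY variable (continuous percent or the
#' high-level flag) with optional adjustment covariates.  Collinear terms
#' dropped by `lm` are reported via warning.
#'
#' @param table cohort data.frame.
#' @param outcome outcome column name (e.g. `"fvc"` or `"dlco"`).
#' @param mloy_var,covariates as in [fit_incidence_model()].
#' @param conf_level CI level.
#' @return data.frame: `term`, `estimate`, `ci_low`, `ci_high`, `p_value`;
#'   attribute `"formula"`.
#' @export
fit_lungfunction_model <- function(table, outcome = "fvc",
                                   mloy_var = "mloy_percent",
                                   covariates = character(0),
                                   conf_level = 0.95) {
  fml <- as.formula(paste(outcome, "~",
                          paste(c(mloy_var, covariates), collapse = " + ")))
  fit <- lm(fml, data = table)
  if (any(is.na(coef(fit))))
    warning("collinear terms dropped: ",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  coefs <- summary(fit)$coefficients
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  out <- data.frame(term = rownames(coefs), estimate = coefs[, 1],
                    ci_low = coefs[, 1] - tq * coefs[, 2],
                    ci_high = coefs[, 1] + tq * coefs[, 2],
                    p_value = coefs[, 4], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "formula") <- deparse(fml)
  out
}

#' Median imputation of missing exposure values
#'
#' Replaces missing entries of each named numeric column by the median of
#' its observed values; the per-column imputation mask is retained in
#' attribute `"imputed"` (a logical matrix).
#'
#' @param table data.frame.
#' @param columns columns to impute (default: all numeric columns with any
#'   missing value).
#' @return `table` with imputed values and the `"imputed"` attribute.
#' @export
impute_missing_exposures <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, function(x)
      is.numeric(x) && anyNA(x), logical(1))]
  mask <- matrix(FALSE, nrow(table), length(columns),
                 dimnames = list(NULL, columns))
  for (cl in columns) {
    x <- table[[cl]]
    if (!is.numeric(x)) stop(sprintf("column '%s' is not numeric", cl))
    if (all(is.na(x))) stop(sprintf("column '%s' is entirely missing", cl))
    mask[, cl] <- is.na(x)
    x[is.na(x)] <- median(x, na.rm = TRUE)
    table[[cl]] <- x
  }
  attr(table, "imputed") <- mask
  table
}
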