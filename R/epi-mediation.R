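#' Bootstrap mediation analysis (exposure -> mediator -> outcome)
#'
#' Product-of-paths mediation with a counterfactual contrast: a linear model
#' predicts the mediator from the exposure (plus covariates), and an outcome
#' model (logistic for binary outcomes, linear otherwise) includes exposure,
#' mediator and covariates.  The average causal mediation effect (ACME) is
#' the mean over subjects of the outcome-model contrast when the mediator is
#' shifted from its predicted value under the control exposure to its
#' predicted value under the treated exposure (exposure held at treated);
#' the average direct effect (ADE) is the analogous contrast in exposure at
#' the control mediator value.  For linear-linear models the ACME reduces
#' exactly to the product of the two path coefficients.  Confidence
#' intervals are percentile bootstrap over subjects, deterministic given
#' `seed`.
#'
#' @param table data.frame.
#' @param exposure,mediator,outcome column names; the exposure must be
#'   binary (logical, 0/1, or matching `treat`/`control`).
#' @param covariates covariate column names used in both models.
#' @param treat,control exposure values contrasted (defaults for
#'   logical/0-1 exposures).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @param conf_level CI level.
#' @return list of class `MediationResult`: `acme`, `ade`, `total_effect`,
#'   `proportion_mediated`, `ci` (matrix of percentile intervals), `n_boot`,
#'   `seed`, `outcome_family`.
#' @export
mediation_bootstrap <- function(table, exposure, mediator, outcome,
                                covariates = character(0), treat = NULL,
                                control = NULL, n_boot = 1000, seed,
                                conf_level = 0.95) {
  x <- table[[exposure]]
  if (is.logical(x)) { treat <- treat %||% TRUE; control <- control %||% FALSE }
  else if (is.numeric(x) && all(x %in% 0:1)) {
    treat <- treat %||% 1; control <- control %||% 0
  }
  if (is.null(treat) || is.null(control))
    stop("non-binary exposure: specify `treat` and `control` values")
  y <- table[[outcome]]
  fam <- if (is.logical(y) || (is.numeric(y) && all(y %in% 0:1)))
    "binomial" else "gaussian"

  point <- function(dat) {
    rhs_m <- paste(c(exposure, covariates), collapse = " + ")
    rhs_y <- paste(c(exposure, mediator, covariates), collapse = " + ")
    mfit <- lm(as.formula(paste(mediator, "~", rhs_m)), data = dat)
    yfit <- glm(as.formula(paste(outcome, "~", rhs_y)), data = dat,
                family = if (fam == "binomial") stats::binomial()
                         else stats::gaussian())
    d_t <- dat; d_t[[exposure]] <- rep(treat, nrow(dat))
    d_c <- dat; d_c[[exposure]] <- rep(control, nrow(dat))
    m1 <- predict(mfit, newdata = d_t)
    m0 <- predict(mfit, newdata = d_c)
    dy_t1 <- d_t; dy_t1[[mediator]] <- m1
    dy_t0 <- d_t; dy_t0[[mediator]] <- m0
    dy_c0 <- d_c; dy_c0[[mediator]] <- m0
    p_t1 <- predict(yfit, newdata = dy_t1, type = "response")
    p_t0 <- predict(yfit, newdata = dy_t0, type = "response")
    p_c0 <- predict(yfit, newdata = dy_c0, type = "response")
    acme <- mean(p_t1 - p_t0)
    ade <- mean(p_t0 - p_c0)
    total <- acme + ade
    c(acme = acme, ade = ade, total = total,
      prop = if (abs(total) > 0) acme / total else NA_real_)
  }
  est <- point(table)
  boots <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(nrow(table), replace = TRUE)
      tryCatch(point(table[ix, , drop = FALSE]),
               error = function(e) rep(NA_real_, 4))
    }, numeric(4)))
  })
  alpha <- (1 - conf_level) / 2
  ci <- apply(boots, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  structure(list(acme = unname(est["acme"]), ade = unname(est["ade"]),
                 total_effect = unname(est["total"]),
                 proportion_mediated = unname(est["prop"]),
                 ci = ci, n_boot = n_boot, seed = seed,
                 outcome_family = fam),
            class = "MediationResult")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.MediationResult <- function(x, ...) {
  cat(sprintf("ACME %.4g [%.4g, %.4g]; ADE %.4g [%.4g, %.4g]\n",
              x$acme, x$ci[1, "acme"], x$ci[2, "acme"],
              x$ade, x$ci[1, "ade"], x$ci[2, "ade"]))
  cat(sprintf("proportion mediated %.3f (%s outcome model, %d bootstraps)\n",
              x$proportion_mediated, x$outcome_family, x$n_boot))
  invisible(x)
}
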