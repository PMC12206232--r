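#' Simulate a prospective cohort with mLOY-dependent outcomes
#'
#' Generates a population-cohort analogue: subjects aged 40-70 at entry, a
#' stated fraction female, smoking status (never/previous/current), and for
#' men an age- and smoking-dependent percent of blood cells with Y loss
#' (`mloy_percent`, identically 0 for women).  Time to event is drawn from an
#' exponential proportional-hazards model whose linear predictor includes
#' `log(hr_per_percent) * mloy_percent` plus any `covariate_effects`;
#' administrative censoring is applied at `max_followup` years.  When
#' `or_per_percent` is supplied, a binary diagnosis outcome is additionally
#' generated from a logistic model with the analogous per-percent odds
#' ratio, for testing incidence models.
#'
#' The built-in smoking -> mLOY -> outcome chain (smokers get higher mean
#' mLOY via `smoking_mloy_shift`) provides a known mediation structure for
#' [mediation_bootstrap()].
#'
#' @param n number of subjects.
#' @param frac_female fraction of women.
#' @param mloy_mean function(age, smoking) giving the mean mLOY percent for
#'   men; the default rises with age (~0.4 percent per year above 50) and is
#'   shifted by `smoking_mloy_shift` for ever-smokers, echoing the
#'   age-dependence of population data.
#' @param mloy_sd Gaussian sd of mLOY percent around its mean (truncated to
#'   `[0, 100]`).
#' @param smoking_mloy_shift added to mean mLOY percent for previous (half
#'   weight) and current (full weight) smokers.
#' @param hr_per_percent hazard ratio per percent mLOY (> 0).
#' @param baseline_hazard events/year at linear predictor zero (>= 0).
#' @param covariate_effects named list of log-hazard effects applied to both
#'   outcomes; recognised names: `age` (per year, centred at 60), `previous`,
#'   `current`, `female`.
#' @param max_followup administrative censoring horizon, years (> 0).
#' @param or_per_percent optional odds ratio per percent mLOY for the binary
#'   diagnosis outcome; `baseline_logit` is its intercept.
#' @param baseline_logit intercept of the diagnosis model (default -5, a
#'   rare outcome).
#' @param seed integer seed.
#' @return data.frame: `subject_id`, `sex`, `age`, `smoking`,
#'   `mloy_percent`, `event`, `time`, and `diagnosed` when `or_per_percent`
#'   is given.
#' @export
gen_epi_cohort <- function(n, frac_female = 0.5,
                           mloy_mean = function(age, smoking)
                             pmax(0, (age - 50) * 0.4),
                           mloy_sd = 5, smoking_mloy_shift = 3,
                           hr_per_percent = 1.013,
                           baseline_hazard = 0.002,
                           covariate_effects = list(age = 0.08,
                                                    previous = 0.3,
                                                    current = 0.7,
                                                    female = -0.5),
                           max_followup = 15, or_per_percent = NULL,
                           baseline_logit = -5, seed) {
  stopifnot(n >= 1, hr_per_percent > 0, baseline_hazard >= 0)
  if (max_followup <= 0) stop("follow-up horizon must be positive")
  stop_if_not_scalar_prob(frac_female, "frac_female")
  with_seed(seed, {
    sex <- ifelse(runif(n) < frac_female, "F", "M")
    age <- runif(n, 40, 70)
    smoking <- sample(c("never", "previous", "current"), n, replace = TRUE,
                      prob = c(0.55, 0.35, 0.10))
    smoke_w <- c(never = 0, previous = 0.5, current = 1)[smoking]
    mloy <- rnorm(n, mloy_mean(age, smoking) + smoking_mloy_shift * smoke_w,
                  mloy_sd)
    mloy <- pmin(100, pmax(0, mloy))
    mloy[sex == "F"] <- 0
    eff <- function(nm) if (is.null(covariate_effects[[nm]])) 0 else
      covariate_effects[[nm]]
    lp <- log(hr_per_percent) * mloy + eff("age") * (age - 60) +
      eff("previous") * (smoking == "previous") +
      eff("current") * (smoking == "current") + eff("female") * (sex == "F")
    if (baseline_hazard > 0) {
      t_event <- rexp(n, rate = baseline_hazard * exp(lp))
    } else {
      t_event <- rep(Inf, n)
    }
    event <- t_event <= max_followup
    time <- pmin(t_event, max_followup)
    out <- data.frame(subject_id = sprintf("P%06d", seq_len(n)), sex = sex,
                      age = age, smoking = smoking, mloy_percent = mloy,
                      event = event, time = time, stringsAsFactors = FALSE)
    if (!is.null(or_per_percent)) {
      stopifnot(or_per_percent > 0)
      lp2 <- baseline_logit + log(or_per_percent) * mloy +
        eff("age") * (age - 60) + eff("previous") * (smoking == "previous") +
        eff("current") * (smoking == "current") + eff("female") * (sex == "F")
      out$diagnosed <- runif(n) < plogis(lp2)
    }
    out
  })
}
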