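#' Male-excess attribution to the mLOY subgroup
#'
#' Decomposes the male excess of an outcome (relative to the female rate)
#' across men with and without mLOY.  With stratified event rates and group
#' sizes, the expected excess events in stratum g are
#' `excess_g = (rate_g - rate_female) * n_g`, and the share of the total
#' male excess occurring in the mLOY stratum is
#' `share_mloy = excess_mloy / (excess_mloy + excess_no_mloy)`.
#' The statistic is invariant to rescaling all rates by a common factor.
#' Negative stratum excesses are allowed and propagated with an annotation;
#' when the total excess is not positive, the share is undefined (`NA`) with
#' annotation.
#'
#' @param rate_female,rate_male_no_mloy,rate_male_mloy event rates (events
#'   per subject) in women, men without mLOY, and men with mLOY; all >= 0.
#' @param n_male_no_mloy,n_male_mloy group sizes (> 0).
#' @return list of class `ExcessAttribution` with the inputs,
#'   `excess_mloy`, `excess_no_mloy`, `excess_total`, `share_mloy`, and
#'   `note` ("" when unremarkable).
#' @examples
#' # equal male rates: the share reduces to the mLOY group's population share
#' excess_attribution(0.001, 0.004, 0.004, 8000, 2000)$share_mloy  # 0.2
#' @export
excess_attribution <- function(rate_female, rate_male_no_mloy, rate_male_mloy,
                               n_male_no_mloy, n_male_mloy) {
  rates <- c(rate_female, rate_male_no_mloy, rate_male_mloy)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative")
  if (n_male_no_mloy <= 0 || n_male_mloy <= 0)
    stop("group sizes must be positive")
  excess_mloy <- (rate_male_mloy - rate_female) * n_male_mloy
  excess_no <- (rate_male_no_mloy - rate_female) * n_male_no_mloy
  total <- excess_mloy + excess_no
  note <- ""
  if (excess_mloy < 0 || excess_no < 0)
    note <- "negative stratum excess: a male stratum has a lower rate than women"
  share <- if (total > 0) excess_mloy / total else NA_real_
  if (total <= 0)
    note <- paste0(note, if (nzchar(note)) "; ",
                   "total male excess is not positive: share undefined")
  structure(list(rate_female = rate_female,
                 rate_male_no_mloy = rate_male_no_mloy,
                 rate_male_mloy = rate_male_mloy,
                 n_male_no_mloy = n_male_no_mloy, n_male_mloy = n_male_mloy,
                 excess_mloy = excess_mloy, excess_no_mloy = excess_no,
                 excess_total = total, share_mloy = share, note = note),
            class = "ExcessAttribution")
}

#' @export
print.ExcessAttribution <- function(x, ...) {
  cat(sprintf("Excess events: %.2f in mLOY men, %.2f in other men (total %.2f)\n",
              x$excess_mloy, x$excess_no_mloy, x$excess_total))
  cat(sprintf("Share of male excess in the mLOY group: %s\n",
              if (is.na(x$share_mloy)) "undefined"
              else sprintf("%.1f%%", 100 * x$share_mloy)))
  if (nzchar(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Excess attribution from a subject-level cohort table
#'
#' Convenience wrapper computing the stratified rates and group sizes from a
#' cohort table and delegating to [excess_attribution()].
#'
#' @param table data.frame with `sex` ("M"/"F"), a logical outcome column,
#'   and a logical mLOY indicator column for men.
#' @param outcome outcome column name.
#' @param mloy_flag mLOY indicator column name (e.g. `"detectable"`).
#' @return an `ExcessAttribution`.
#' @export
excess_attribution_from_table <- function(table, outcome = "event",
                                          mloy_flag = "detectable") {
  y <- table[[outcome]]; male <- table$sex == "M"
  flag <- table[[mloy_flag]]
  excess_attribution(rate_female = mean(y[!male]),
                     rate_male_no_mloy = mean(y[male & !flag]),
                     rate_male_mloy = mean(y[male & flag]),
                     n_male_no_mloy = sum(male & !flag),
                     n_male_mloy = sum(male & flag))
}
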