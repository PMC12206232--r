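#' Median log-R ratio over X and Y probes
#'
#' The per-subject summaries mLRRX and mLRRY: medians of the log-R ratio
#' (LRR) over X-chromosome and Y-chromosome probes.  mLRRY below 0 indicates
#' mosaic loss of Y; both are inspected jointly to spot sex-chromosome
#' aneuploidies.  Even-length medians are the mean of the two middle order
#' statistics; the result is invariant to probe order and to duplication of
#' the whole probe set.
#'
#' @param profile data.frame with columns `chrom` and `lrr` (one subject's
#'   probes).
#' @return named numeric vector `c(mlrrx = , mlrry = )`.
#' @export
compute_mlrr <- function(profile) {
  stopifnot(all(c("chrom", "lrr") %in% names(profile)))
  if (any(!is.finite(profile$lrr))) stop("lrr values must be finite")
  x <- profile$lrr[profile$chrom == "X"]
  y <- profile$lrr[profile$chrom == "Y"]
  if (length(x) < 1L || length(y) < 1L)
    stop("profile must contain at least one X and one Y probe")
  c(mlrrx = median(x), mlrry = median(y))
}

#' Derivative log-ratio spread (DLRS)
#'
#' Per-sample array noise metric: the standard deviation of successive LRR
#' differences along a chromosome, divided by sqrt(2).  For i.i.d. probe
#' noise of sd sigma the DLRS converges to sigma, while being insensitive to
#' slow copy-number waves.  Used for genotyping-quality QC.
#'
#' @param profile data.frame with `chrom` and `lrr` in probe order.
#' @param chromosome chromosome whose probes are used (default "1").
#' @return numeric DLRS value.
#' @export
compute_dlrs <- function(profile, chromosome = "1") {
  v <- profile$lrr[profile$chrom == chromosome]
  if (length(v) < 3L)
    stop(sprintf("need >= 3 probes on chromosome %s for DLRS", chromosome))
  sd(diff(v)) / sqrt(2)
}

#' Flag samples with outlying DLRS
#'
#' Marks `qc_pass = FALSE` for estimates whose chromosome-1 DLRS exceeds
#' `Q3 + 1.5 * IQR` of the cohort DLRS distribution (quantiles by linear
#' interpolation, type 7).  A degenerate all-identical distribution yields a
#' cutoff equal to that value and flags nothing.
#'
#' @param estimates data.frame with a finite `dlrs_chr1` column (>= 4 rows).
#' @return `estimates` with a logical `qc_pass` column updated (existing
#'   `FALSE` values are preserved), plus attribute `"dlrs_cutoff"`.
#' @export
qc_filter_dlrs <- function(estimates) {
  d <- estimates$dlrs_chr1
  if (sum(is.finite(d)) < 4L) stop("need >= 4 finite DLRS values")
  q <- quantile(d, c(0.25, 0.75), na.rm = TRUE, type = 7)
  cutoff <- unname(q[2] + 1.5 * (q[2] - q[1]))
  pass <- d <= cutoff
  estimates$qc_pass <- if (is.null(estimates$qc_pass)) pass
                       else estimates$qc_pass & pass
  attr(estimates, "dlrs_cutoff") <- cutoff
  estimates
}

#' Flag sex-chromosome aneuploidies from (mLRRX, mLRRY)
#'
#' Subjects whose median intensities indicate karyotypes other than mosaic Y
#' loss are excluded from mLOY scoring: elevated mLRRX suggests 47,XXY;
#' elevated mLRRY suggests 47,XYY; strongly depressed mLRRX suggests a
#' genetic female (or no-Y sample).  Bounds default to +/- 0.3 in median-LRR
#' space and are configurable.
#'
#' @param mlrrx,mlrry finite numeric vectors (recycled to common length).
#' @param bounds named list: `x_gain`, `y_gain`, `female` (lower bound on
#'   mLRRX).
#' @return character vector: "none", "XXY-like", "XYY-like" or "other".
#' @export
flag_sex_aneuploidy <- function(mlrrx, mlrry,
                                bounds = list(x_gain = 0.3, y_gain = 0.3,
                                              female = -0.3)) {
  stopifnot(all(is.finite(mlrrx)), all(is.finite(mlrry)))
  n <- max(length(mlrrx), length(mlrry))
  mlrrx <- rep_len(mlrrx, n); mlrry <- rep_len(mlrry, n)
  flag <- rep("none", n)
  flag[mlrry > bounds$y_gain] <- "XYY-like"
  flag[mlrrx > bounds$x_gain] <- "XXY-like"   # X gain takes precedence
  flag[mlrrx < bounds$female] <- "other"
  flag
}

#' Batch-adjust mLRRY values
#'
#' Subtracts from each subject's mLRRY the median mLRRY of its genotyping
#' batch, computed over eligible subjects only (QC-passing, no aneuploidy
#' flag) so that outliers and aneuploidies do not drag the batch centre.  A
#' batch with no eligible subjects falls back to the grand median (and is
#' reported via the `"fallback_batches"` attribute).
#'
#' @param estimates data.frame with `mlrry`, `batch_id` and (optionally)
#'   `qc_pass`, `aneuploidy_flag` columns.
#' @return `estimates` with an `mlrry_adjusted` column.
#' @export
batch_adjust <- function(estimates) {
  stopifnot(all(c("mlrry", "batch_id") %in% names(estimates)))
  eligible <- rep(TRUE, nrow(estimates))
  if (!is.null(estimates$qc_pass)) eligible <- eligible & estimates$qc_pass
  if (!is.null(estimates$aneuploidy_flag))
    eligible <- eligible & estimates$aneuploidy_flag == "none"
  grand <- median(estimates$mlrry[eligible])
  if (!is.finite(grand)) grand <- median(estimates$mlrry)
  med <- tapply(estimates$mlrry[eligible], estimates$batch_id[eligible],
                median)
  centres <- as.vector(med[as.character(estimates$batch_id)])
  fallback <- unique(estimates$batch_id[is.na(centres)])
  centres[is.na(centres)] <- grand
  estimates$mlrry_adjusted <- estimates$mlrry - centres
  attr(estimates, "fallback_batches") <- fallback
  estimates
}

#' Transform mLRRY to percent of cells with Y loss
#'
#' Under the ideal single-copy model a fraction `f` of Y-less cells gives a
#' Y log-R ratio of `log2(1 - f)`, so `percent = 100 * (1 -
#' 2^(mlrry/slope))`.  The optional `response_slope` calibrates array signal
#' compression (observed LRR = slope x ideal).  Values above 100 are
#' impossible; slightly negative values arise from noise and are preserved
#' (never clamped), since clamping would bias downstream noise-threshold
#' estimation.
#'
#' @param mlrry_adjusted numeric vector of (batch-adjusted) mLRRY values.
#' @param response_slope positive calibration slope (default 1).
#' @return percent of cells with Y loss.
#' @examples
#' mlrr_to_percent(c(0, -1))       # 0 and 50 percent
#' @export
mlrr_to_percent <- function(mlrry_adjusted, response_slope = 1) {
  stopifnot(response_slope > 0)
  100 * (1 - 2^(mlrry_adjusted / response_slope))
}

#' Derive the mLOY detection threshold from experimental noise
#'
#' Estimates the spread of mLRRY under no loss and places the detection
#' threshold at the lower limit of the `confidence` (default 99%) two-sided
#' interval of that noise: in mLRRY space `-z_{(1+conf)/2} * noise_sd`,
#' mapped to percent by [mlrr_to_percent()].  The noise sd is the robust
#' estimate `1.4826 * MAD about 0` of the reference values; when no
#' LOY-free truth is available (`mirror = TRUE`, the default) only values
#' `>= 0` are used, mirrored about 0 - the right half of the mLRRY
#' distribution is noise-dominated because loss only pushes values left.
#'
#' @param reference_mlrry numeric vector of (adjusted) mLRRY values from
#'   subjects presumed LOY-free, or a full cohort when `mirror = TRUE`
#'   (>= 100 values required).
#' @param confidence confidence level in (0, 1), default 0.99.
#' @param mirror use the mirrored right half (see above).
#' @param response_slope passed to [mlrr_to_percent()].
#' @return list of class `DetectionThreshold`: `threshold_percent`,
#'   `threshold_mlrry`, `noise_sd`, `confidence`, `n_reference`, `mirror`.
#' @export
derive_detection_threshold <- function(reference_mlrry, confidence = 0.99,
                                       mirror = TRUE, response_slope = 1) {
  stop_if_not_scalar_prob(confidence, "confidence")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  v <- reference_mlrry[is.finite(reference_mlrry)]
  if (length(v) < 100L)
    stop("need >= 100 reference mLRRY values to estimate noise")
  if (mirror) v <- c(v[v >= 0], -v[v >= 0])
  noise_sd <- 1.4826 * median(abs(v))        # MAD about 0
  z <- qnorm((1 + confidence) / 2)
  bound <- -z * noise_sd
  structure(list(threshold_percent = mlrr_to_percent(bound, response_slope),
                 threshold_mlrry = bound, noise_sd = noise_sd,
                 confidence = confidence, n_reference = length(reference_mlrry),
                 mirror = mirror),
            class = "DetectionThreshold")
}

#' @export
print.DetectionThreshold <- function(x, ...) {
  cat(sprintf(paste0("mLOY detection threshold: %.2f%% ",
                     "(noise sd %.4f, %.0f%% confidence, n = %d%s)\n"),
              x$threshold_percent, x$noise_sd, 100 * x$confidence,
              x$n_reference, if (x$mirror) ", mirrored reference" else ""))
  invisible(x)
}

#' Categorical mLOY scoring
#'
#' `detectable`: percent LOY at or above the noise-derived detection
#' threshold ("at least" is inclusive; set `strict = TRUE` for a strict
#' inequality).  `high`: percent LOY at or above `high_cutoff` (default
#' 40%), the level at which lung-function deficits become apparent.
#'
#' @param percent_loy numeric vector.
#' @param threshold a `DetectionThreshold` or a bare percent value.
#' @param high_cutoff high-mLOY cutoff in percent.
#' @param strict use `>` instead of `>=` at both boundaries.
#' @return data.frame with logical columns `detectable` and `high`.
#' @export
categorize_mloy <- function(percent_loy, threshold, high_cutoff = 40,
                            strict = FALSE) {
  thr <- if (inherits(threshold, "DetectionThreshold"))
    threshold$threshold_percent else threshold
  cmp <- if (strict) `>` else `>=`
  data.frame(detectable = cmp(percent_loy, thr),
             high = cmp(percent_loy, high_cutoff))
}

#' Per-subject mLOY estimation from array intensities
#'
#' Full pipeline over a probe-level table: per-subject mLRRX/mLRRY and
#' chromosome-1 DLRS, DLRS-outlier QC, sex-aneuploidy flagging, batch
#' adjustment of mLRRY, transformation to percent LOY, noise-threshold
#' derivation from the cohort itself (mirrored right half), and categorical
#' scoring.  Subjects failing QC or flagged for aneuploidy are retained in
#' the output with `detectable = FALSE`.
#'
#' @param profiles data.frame with columns `subject_id`, `chrom`, `lrr` and
#'   optionally `batch_id` (single batch assumed if absent).
#' @param confidence detection-threshold confidence level.
#' @param high_cutoff high-mLOY percent cutoff.
#' @param response_slope array response slope (see [mlrr_to_percent()]).
#' @param threshold optional pre-computed `DetectionThreshold` (or bare
#'   percent); when `NULL` the threshold is derived from this cohort
#'   (requires >= 100 eligible subjects).
#' @param aneuploidy_bounds passed to [flag_sex_aneuploidy()].
#' @param dlrs_chromosome chromosome used for DLRS QC.
#' @param adjust_batches subtract batch medians from mLRRY before the
#'   percent transformation (default `TRUE`; batch centring assumes most
#'   subjects have little or no loss, as in population cohorts).
#' @return data.frame of per-subject estimates (`mlrrx`, `mlrry`,
#'   `dlrs_chr1`, `qc_pass`, `aneuploidy_flag`, `mlrry_adjusted`,
#'   `percent_loy`, `detectable`, `high`) with the `DetectionThreshold` in
#'   attribute `"threshold"` and the DLRS cutoff in `"dlrs_cutoff"`.
#' @export
estimate_mloy_array <- function(profiles, confidence = 0.99, high_cutoff = 40,
                                response_slope = 1, threshold = NULL,
                                aneuploidy_bounds = list(x_gain = 0.3,
                                                         y_gain = 0.3,
                                                         female = -0.3),
                                dlrs_chromosome = "1", adjust_batches = TRUE) {
  stopifnot(all(c("subject_id", "chrom", "lrr") %in% names(profiles)))
  if (is.null(profiles$batch_id)) profiles$batch_id <- "B01"
  sid <- factor(profiles$subject_id, levels = unique(profiles$subject_id))
  is_x <- profiles$chrom == "X"; is_y <- profiles$chrom == "Y"
  is_d <- profiles$chrom == dlrs_chromosome
  ng <- nlevels(sid)
  mlrrx <- grouped_median(profiles$lrr[is_x], as.integer(sid)[is_x], ng)
  mlrry <- grouped_median(profiles$lrr[is_y], as.integer(sid)[is_y], ng)
  dlrs <- grouped_dlrs(profiles$lrr[is_d], as.integer(sid)[is_d], ng)
  subj <- levels(sid)
  names(mlrrx) <- names(mlrry) <- names(dlrs) <- subj
  if (anyNA(mlrrx) || anyNA(mlrry))
    stop("every subject needs at least one X and one Y probe")
  est <- data.frame(
    subject_id = subj,
    batch_id = profiles$batch_id[match(subj, profiles$subject_id)],
    mlrrx = as.numeric(mlrrx[subj]), mlrry = as.numeric(mlrry[subj]),
    dlrs_chr1 = as.numeric(dlrs[subj]), stringsAsFactors = FALSE)
  est$aneuploidy_flag <- flag_sex_aneuploidy(est$mlrrx, est$mlrry,
                                             aneuploidy_bounds)
  est <- qc_filter_dlrs(est)
  dlrs_cutoff <- attr(est, "dlrs_cutoff")
  if (adjust_batches) est <- batch_adjust(est)
  else est$mlrry_adjusted <- est$mlrry
  est$percent_loy <- mlrr_to_percent(est$mlrry_adjusted, response_slope)
  thr <- threshold
  if (is.null(thr)) {
    ref <- est$mlrry_adjusted[est$qc_pass & est$aneuploidy_flag == "none"]
    thr <- derive_detection_threshold(ref, confidence = confidence,
                                      response_slope = response_slope)
  }
  cat_ <- categorize_mloy(est$percent_loy, thr, high_cutoff)
  est$detectable <- cat_$detectable & est$qc_pass &
    est$aneuploidy_flag == "none"
  est$high <- cat_$high
  attr(est, "threshold") <- thr
  attr(est, "dlrs_cutoff") <- dlrs_cutoff
  est
}
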