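#' Poisson inversion of a positive-partition fraction
#'
#' In digital PCR the template concentration is recovered from the fraction
#' of positive partitions: if copies land in partitions as Poisson(lambda),
#' the void probability is `exp(-lambda)`, so
#' `lambda = -ln(1 - positives/n_partitions)` mean copies per partition.
#' A fully saturated plate carries no concentration information and is an
#' error.
#'
#' @param positives positive partition count(s).
#' @param n_partitions total partitions (> 0).
#' @return lambda, mean copies per partition.
#' @export
poisson_lambda <- function(positives, n_partitions) {
  stopifnot(n_partitions > 0)
  if (any(positives < 0) || any(positives > n_partitions))
    stop("positives must lie in [0, n_partitions]")
  if (any(positives == n_partitions))
    stop("saturated plate: all partitions positive, lambda unbounded")
  -log(1 - positives / n_partitions)
}

#' mLOY percent from Y/X target concentrations
#'
#' The copy-ratio formula `(1 - [Y]/[X]) * 100%` applied to the estimated
#' concentrations (lambda, copies per partition; partition volume cancels in
#' the ratio) of a Y-chromosome target and its X-chromosome homologue, e.g.
#' AMELY/AMELX.  Negative values can arise from sampling noise and are
#' returned as-is (with a warning annotation via attribute `"negative"`);
#' use `floor_zero = TRUE` to clamp for categorical use.
#'
#' @param lambda_y,lambda_x concentrations from [poisson_lambda()];
#'   `lambda_x` must be > 0.
#' @param floor_zero clamp negative estimates to 0.
#' @return mLOY percent.
#' @export
compute_mloy_dpcr <- function(lambda_y, lambda_x, floor_zero = FALSE) {
  if (any(lambda_x <= 0)) stop("lambda_x must be positive (undefined ratio)")
  if (any(lambda_y < 0)) stop("lambda_y must be non-negative")
  pct <- (1 - lambda_y / lambda_x) * 100
  neg <- pct < 0
  if (floor_zero) pct[neg] <- 0
  if (any(neg)) attr(pct, "negative") <- which(neg)
  pct
}

#' Bootstrap confidence interval for a dPCR mLOY estimate
#'
#' Percentile bootstrap: positive counts of both channels are resampled as
#' Binomial(n_partitions, observed fraction), pushed through
#' [poisson_lambda()] and [compute_mloy_dpcr()].  Deterministic given
#' `seed`.
#'
#' @param plate one-row data.frame with `n_partitions`, `positives_y`,
#'   `positives_x`.
#' @param confidence interval level (default 0.95).
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @return named vector `c(ci_low = , ci_high = )` in percent.
#' @export
mloy_ci <- function(plate, confidence = 0.95, n_boot = 1000, seed) {
  stopifnot(nrow(plate) == 1L)
  n <- plate$n_partitions
  poisson_lambda(c(plate$positives_y, plate$positives_x), n)  # validates
  with_seed(seed, {
    by <- rbinom(n_boot, n, plate$positives_y / n)
    bx <- rbinom(n_boot, n, plate$positives_x / n)
    ok <- by < n & bx < n & bx > 0
    pct <- compute_mloy_dpcr(poisson_lambda(by[ok], n),
                             poisson_lambda(bx[ok], n))
    q <- quantile(pct, c((1 - confidence) / 2, (1 + confidence) / 2),
                  names = FALSE)
    c(ci_low = q[1], ci_high = q[2])
  })
}

#' High-mLOY categorization for dPCR estimates
#'
#' @param mloy_percent numeric vector.
#' @param cutoff percent cutoff (default 40); `high = mloy_percent >= cutoff`
#'   (boundary convention shared with the array module; `strict = TRUE` for
#'   `>`).
#' @param strict use a strict inequality.
#' @return logical vector.
#' @export
categorize_dpcr <- function(mloy_percent, cutoff = 40, strict = FALSE) {
  if (strict) mloy_percent > cutoff else mloy_percent >= cutoff
}

#' Estimate mLOY from digital PCR plates
#'
#' Applies the Poisson inversion and copy-ratio formula per sample, with a
#' bootstrap confidence interval and categorical scoring.
#'
#' @param plates data.frame with columns `sample_id`, `n_partitions`,
#'   `positives_y`, `positives_x` (one row per sample).
#' @param cutoff high-mLOY percent cutoff.
#' @param confidence CI level.
#' @param n_boot bootstrap draws per sample.
#' @param seed integer seed.
#' @param floor_zero clamp negative percent estimates to 0.
#' @return data.frame: `sample_id`, `lambda_y`, `lambda_x`, `mloy_percent`,
#'   `ci_low`, `ci_high`, `high`.
#' @export
estimate_mloy_dpcr <- function(plates, cutoff = 40, confidence = 0.95,
                               n_boot = 1000, seed, floor_zero = FALSE) {
  lam_y <- poisson_lambda(plates$positives_y, plates$n_partitions)
  lam_x <- poisson_lambda(plates$positives_x, plates$n_partitions)
  pct <- compute_mloy_dpcr(lam_y, lam_x, floor_zero = floor_zero)
  ci <- t(vapply(seq_len(nrow(plates)), function(i)
    mloy_ci(plates[i, , drop = FALSE], confidence, n_boot,
            seed = child_seed(seed, i)),
    numeric(2)))
  out <- data.frame(sample_id = plates$sample_id, lambda_y = lam_y,
                    lambda_x = lam_x, mloy_percent = as.numeric(pct),
                    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                    high = categorize_dpcr(as.numeric(pct), cutoff),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
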