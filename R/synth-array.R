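#' Simulate a SNP-array intensity cohort with known mLOY fractions
#'
#' Generates per-probe log-R ratios (LRR) for `n` male subjects.  For a
#' subject whose true fraction of Y-less cells is `f`, probes on chromosome Y
#' are centred on the ideal single-copy signal `log2(1 - f)`; probes on X and
#' on autosomes are centred on 0.  Every probe additionally receives the
#' subject's batch offset (drawn once per batch from `N(0, batch_sd)`) and
#' i.i.d. Gaussian probe noise `N(0, noise_sd)`.  An optional multiplicative
#' `response_slope` models array signal compression (ideal Y signal becomes
#' `slope * log2(1 - f)`); the default of 1 keeps the model exactly
#' invertible by [mlrr_to_percent()].
#'
#' @param n number of subjects (>= 1).
#' @param loy_dist true LOY fractions: a single number, a vector of length
#'   `n`, or a function of `n` returning fractions in `[0, 1)`.  Default is a
#'   Beta(0.5, 8) draw, a right-skewed distribution in which most subjects
#'   have little or no loss, as seen in population cohorts.
#' @param noise_sd per-probe Gaussian noise, log2-ratio units.
#' @param n_batches number of genotyping batches; subjects are assigned
#'   uniformly at random.
#' @param batch_sd standard deviation of per-batch LRR offsets.
#' @param probes_per_chrom probes simulated per chromosome (>= 2).
#' @param chromosomes chromosome labels to simulate; must include "X" and
#'   "Y", and "1" is required downstream for DLRS QC.  Subsets of
#'   `c(1:22, "X", "Y")` only.
#' @param response_slope multiplicative response applied to the ideal Y
#'   signal (see above).
#' @param seed integer seed; identical seeds and parameters give identical
#'   output.
#' @return list with `profiles` (data.frame: `subject_id`, `batch_id`,
#'   `probe_id`, `chrom`, `lrr`) and `truth` (data.frame: `subject_id`,
#'   `true_loy_fraction`, `batch_id`, `age`).
#' @examples
#' sim <- gen_array_cohort(5, loy_dist = 0.2, noise_sd = 0, seed = 1)
#' est <- estimate_mloy_array(sim$profiles, threshold = 8.28,
#'                            adjust_batches = FALSE)
#' est$percent_loy                     # all exactly 20
#' @export
gen_array_cohort <- function(n, loy_dist = function(n) stats::rbeta(n, 0.5, 8),
                             noise_sd = 0.05, n_batches = 1, batch_sd = 0,
                             probes_per_chrom = 50,
                             chromosomes = c("1", "X", "Y"),
                             response_slope = 1, seed) {
  stopifnot(n >= 1, noise_sd >= 0, batch_sd >= 0, probes_per_chrom >= 2,
            n_batches >= 1, response_slope > 0)
  chromosomes <- as.character(chromosomes)
  if (!all(chromosomes %in% c(as.character(1:22), "X", "Y")))
    stop("chromosome labels must be drawn from {1..22, X, Y}")
  if (!all(c("X", "Y") %in% chromosomes))
    stop("chromosomes must include both X and Y")
  with_seed(seed, {
    f <- if (is.function(loy_dist)) loy_dist(n)
         else rep_len(as.numeric(loy_dist), n)
    if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
      stop("true LOY fractions must be finite and in [0, 1]")
    if (any(f >= 1))
      stop("true LOY fraction 1 gives a -Inf log-R signal; use f < 1")
    subj <- sprintf("S%04d", seq_len(n))
    batch <- sprintf("B%02d", sample.int(n_batches, n, replace = TRUE))
    offsets <- setNames(rnorm(n_batches, 0, batch_sd),
                        sprintf("B%02d", seq_len(n_batches)))
    age <- runif(n, 40, 70)

    n_chr <- length(chromosomes)
    p <- probes_per_chrom
    ## ideal per-(subject, chrom) centre: log2(1-f)*slope on Y, 0 elsewhere
    centre <- matrix(0, nrow = n, ncol = n_chr,
                     dimnames = list(subj, chromosomes))
    centre[, "Y"] <- response_slope * log2(1 - f)
    lrr <- rep(as.vector(t(centre)), each = p) +            # subject-major
      rep(offsets[batch], each = n_chr * p)
    if (noise_sd > 0) lrr <- lrr + rnorm(length(lrr), 0, noise_sd)
    ## probe ids name physical array probes, so the panel repeats per subject
    probe_panel <- paste0("chr", rep(chromosomes, each = p), "_p",
                          seq_len(p))
    profiles <- data.frame(
      subject_id = rep(subj, each = n_chr * p),
      batch_id = rep(batch, each = n_chr * p),
      probe_id = rep(probe_panel, times = n),
      chrom = rep(rep(chromosomes, each = p), times = n),
      lrr = lrr,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(subject_id = subj, true_loy_fraction = f,
                        batch_id = batch, age = age,
                        stringsAsFactors = FALSE)
    list(profiles = profiles, truth = truth)
  })
}
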