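#' Simulate a digital PCR plate for a Y/X copy-ratio assay
#'
#' Models the standard dPCR partition process: template molecules distribute
#' over `n_partitions` partitions as Poisson with mean `lambda =
#' mean_copies_per_partition` copies per partition for the X-chromosome
#' target; a partition is positive when it holds at least one copy.  A true
#' fraction `true_f` of cells lacking the Y chromosome reduces the Y-target
#' concentration to `lambda * (1 - true_f)`, so
#' positive counts are drawn as
#' `Binomial(n_partitions, 1 - exp(-lambda))` (X channel) and
#' `Binomial(n_partitions, 1 - exp(-lambda * (1 - true_f)))` (Y channel).
#'
#' @param true_f true mLOY fraction in `[0, 1]`.
#' @param n_partitions number of partitions (>= 100); 26000 mimics a 26k
#'   nanoplate.
#' @param mean_copies_per_partition Poisson mean copies per partition for the
#'   X target (> 0).
#' @param seed integer seed.
#' @param sample_id identifier carried into the output.
#' @return one-row data.frame of class `PartitionPlate`: `sample_id`,
#'   `n_partitions`, `positives_y`, `positives_x`, `true_f`.
#' @examples
#' plate <- gen_dpcr_run(0.4, n_partitions = 26000,
#'                       mean_copies_per_partition = 1, seed = 3)
#' estimate_mloy_dpcr(plate, seed = 3)
#' @export
gen_dpcr_run <- function(true_f, n_partitions = 26000,
                         mean_copies_per_partition = 1, seed,
                         sample_id = "sample1") {
  stop_if_not_scalar_prob(true_f, "true_f")
  stopifnot(n_partitions >= 100)
  if (!is.numeric(mean_copies_per_partition) ||
      mean_copies_per_partition <= 0 || !is.finite(mean_copies_per_partition))
    stop("mean_copies_per_partition must be a positive finite number")
  lam <- mean_copies_per_partition
  with_seed(seed, {
    px <- 1 - exp(-lam)
    py <- 1 - exp(-lam * (1 - true_f))
    out <- data.frame(sample_id = sample_id,
                      n_partitions = as.integer(n_partitions),
                      positives_y = rbinom(1, n_partitions, py),
                      positives_x = rbinom(1, n_partitions, px),
                      true_f = true_f,
                      stringsAsFactors = FALSE)
    class(out) <- c("PartitionPlate", class(out))
    out
  })
}
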