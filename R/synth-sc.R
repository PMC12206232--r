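#' Simulate a droplet scRNA-seq case/control cohort with LOY structure
#'
#' Emulates the pooled design used to study Y loss in diseased vs control
#' lungs: several male donors per condition, each contributing cells from a
#' mixture of cell types.  Each cell is assigned a type, a donor, and
#' (before any counts are drawn) an all-or-none LOY state with probability
#' given by its condition x type entry of `loy_frac`.  Counts are Poisson
#' with per-gene rates equal to a type-specific expression profile scaled to
#' the cell's target depth; LOY cells have every MSY-gene rate set to zero,
#' and LOY cells of `profib_types` have `profib_genes` rates multiplied by
#' `exp(profib_effect)`.  The Poisson choice makes the LOY-calling null
#' exactly computable: a non-LOY cell yields zero MSY counts with
#' probability `exp(-msy_lambda)`, returned per cell in the truth table.
#'
#' The gene panel consists of the marker genes of `marker_table`, the MSY
#' genes of `msy_gene_means`, a small mitochondrial block, and `n_background`
#' background genes; markers are up-regulated `marker_strength`-fold in the
#' cell types they define (and in their parent-level types).
#'
#' @param n_donors_per_condition named integer vector, e.g.
#'   `c(IPF = 4, control = 3)`; names must be among IPF/control/nonIPF.
#' @param cells_per_donor cells per donor.
#' @param celltype_props named probability vector over cell-type labels.
#' @param loy_frac either a single proportion or a data.frame with columns
#'   `condition`, `cell_type`, `loy_frac` (unknown labels are an error).
#' @param msy_gene_means named non-negative vector: expected MSY counts per
#'   gene in a cell at reference depth; at least one positive.
#' @param profib_effect natural-log fold change applied to `profib_genes` in
#'   LOY cells of `profib_types` (0 disables).
#' @param profib_genes,profib_types genes and cell types carrying the
#'   LOY-coupled profibrotic up-regulation.
#' @param profib_base baseline expected counts (at reference depth) of each
#'   profibrotic gene, about 0.2% of the library by default.  Relative
#'   (library-size normalized) fold changes only track rate fold changes
#'   when the perturbed genes are a small share of the library; a large
#'   share produces an intrinsic composition bias of about
#'   `-log2(1 + share * (fold - 1))` in every gene's apparent fold change.
#' @param depth_dist function of `n` returning target depths; default
#'   lognormal with median 8000 and sdlog 0.4, a typical 10x depth profile.
#' @param marker_strength fold up-regulation of a type's own markers.
#' @param mito_mean expected total mitochondrial counts at reference depth
#'   (the default gives a mitochondrial fraction of roughly 2-4%).
#' @param n_background number of background genes; the default of 2000 with
#'   heavy-tailed means yields roughly 900-1400 expressed genes per cell at
#'   the default depths, inside the standard QC window.
#' @param marker_table marker map (see [default_marker_table()]).
#' @param seed integer seed.
#' @return list with `dataset` (a [cell_dataset()]) and `truth` (data.frame:
#'   `cell_id`, `donor_id`, `condition`, `cell_type`, `is_loy`,
#'   `target_depth`, `msy_lambda`).
#' @export
gen_sc_cohort <- function(n_donors_per_condition = c(IPF = 4, control = 3),
                          cells_per_donor = 500,
                          celltype_props = c(macrophage = 0.30, T_cell = 0.25,
                                             fibroblast = 0.20,
                                             epithelial = 0.15,
                                             endothelial = 0.10),
                          loy_frac = 0.1,
                          msy_gene_means = default_msy_means(),
                          profib_effect = 0,
                          profib_genes = c("FN1", "SPP1"),
                          profib_types = "macrophage", profib_base = 40,
                          depth_dist = function(n) rlnorm(n, log(8000), 0.4),
                          marker_strength = 4,
                          mito_mean = 400, n_background = 2000,
                          marker_table = default_marker_table(), seed) {
  conds <- names(n_donors_per_condition)
  if (is.null(conds) || !all(conds %in% c("IPF", "control", "nonIPF")))
    stop("n_donors_per_condition must be named with IPF/control/nonIPF")
  stopifnot(cells_per_donor >= 1, all(n_donors_per_condition >= 1))
  if (abs(sum(celltype_props) - 1) > 1e-8 || any(celltype_props < 0))
    stop("celltype_props must be a probability vector")
  types <- names(celltype_props)
  if (!is.numeric(msy_gene_means) || is.null(names(msy_gene_means)) ||
      any(msy_gene_means < 0) || !any(msy_gene_means > 0))
    stop("msy_gene_means must be a named non-negative vector, not all zero")
  loy_lookup <- make_loy_lookup(loy_frac, conds, types)

  with_seed(seed, {
    panel <- build_gene_panel(marker_table, msy_gene_means, mito_mean,
                              n_background, profib_genes, profib_base)
    genes <- panel$genes; base_mu <- panel$base_mu
    ## per-type expression profiles: markers of a type (and of its parents)
    ## multiplied by marker_strength
    profiles <- sapply(types, function(tp) {
      mu <- base_mu
      mk <- type_marker_genes(marker_table, tp)
      mu[genes %in% mk] <- mu[genes %in% mk] * marker_strength
      mu
    })
    rownames(profiles) <- genes

    donors <- unlist(lapply(conds, function(cd)
      sprintf("%s_D%02d", cd, seq_len(n_donors_per_condition[[cd]]))))
    donor_cond <- sub("_D[0-9]+$", "", donors)
    n_cells <- length(donors) * cells_per_donor
    cell_donor <- rep(donors, each = cells_per_donor)
    cell_cond <- rep(donor_cond, each = cells_per_donor)
    cell_type <- sample(types, n_cells, replace = TRUE, prob = celltype_props)
    ## LOY state is assigned before any counts are drawn (all-or-none loss)
    p_loy <- loy_lookup(cell_cond, cell_type)
    is_loy <- runif(n_cells) < p_loy
    depth <- depth_dist(n_cells)
    if (any(depth <= 0)) stop("depth_dist must return positive depths")

    is_msy <- genes %in% names(msy_gene_means)
    rate <- profiles[, cell_type, drop = FALSE]
    scale <- depth / colSums(rate)           # reference profile mass -> depth
    msy_lambda <- colSums(rate[is_msy, , drop = FALSE]) * scale
    rate <- rate * rep(scale, each = nrow(rate))
    if (any(is_loy)) {
      rate[is_msy, is_loy] <- 0
      boosted <- is_loy & cell_type %in% profib_types
      if (profib_effect != 0 && any(boosted)) {
        pg <- genes %in% profib_genes
        rate[pg, boosted] <- rate[pg, boosted] * exp(profib_effect)
      }
    }
    counts <- matrix(rpois(length(rate), as.vector(rate)),
                     nrow = length(genes),
                     dimnames = list(genes, sprintf("C%06d", seq_len(n_cells))))
    cells <- data.frame(cell_id = colnames(counts), donor_id = cell_donor,
                        sex = "M", condition = cell_cond,
                        cell_type = cell_type, stringsAsFactors = FALSE)
    dataset <- cell_dataset(counts, cells,
                            msy_genes = names(msy_gene_means))
    truth <- data.frame(cell_id = colnames(counts), donor_id = cell_donor,
                        condition = cell_cond, cell_type = cell_type,
                        is_loy = is_loy, target_depth = depth,
                        msy_lambda = msy_lambda, stringsAsFactors = FALSE)
    list(dataset = dataset, truth = truth)
  })
}

#' Default per-gene MSY expression means for simulation
#'
#' Expected counts per MSY gene in a cell at the reference depth; totals
#' about 15 transcripts, dominated by RPS4Y1/DDX3Y/EIF1AY as in blood and
#' lung single-cell data, which keeps the false LOY-call (dropout) rate of a
#' wild-type cell well below 1e-4 at typical depths.
#'
#' @return named numeric vector.
#' @export
default_msy_means <- function() {
  c(RPS4Y1 = 6, DDX3Y = 3, EIF1AY = 2, UTY = 1, KDM5D = 1, USP9Y = 0.8,
    TMSB4Y = 0.7, ZFY = 0.5, NLGN4Y = 0.2, TXLNGY = 0.5, PRKY = 0.3)
}

## condition x type LOY-fraction lookup, validating labels
make_loy_lookup <- function(loy_frac, conds, types) {
  if (is.numeric(loy_frac) && length(loy_frac) == 1L) {
    stop_if_not_scalar_prob(loy_frac, "loy_frac")
    return(function(cond, type) rep(loy_frac, length(cond)))
  }
  if (!is.data.frame(loy_frac) ||
      !all(c("condition", "cell_type", "loy_frac") %in% names(loy_frac)))
    stop("loy_frac must be a number or data.frame(condition, cell_type, loy_frac)")
  if (!all(loy_frac$cell_type %in% types))
    stop("unknown cell-type label in loy_frac table")
  if (!all(loy_frac$condition %in% conds))
    stop("unknown condition label in loy_frac table")
  if (any(loy_frac$loy_frac < 0 | loy_frac$loy_frac > 1))
    stop("loy_frac values must be in [0, 1]")
  key <- paste(loy_frac$condition, loy_frac$cell_type)
  val <- setNames(loy_frac$loy_frac, key)
  function(cond, type) {
    out <- val[paste(cond, type)]
    out[is.na(out)] <- 0
    unname(out)
  }
}

## gene panel: markers + MSY + mito + background, with base means
build_gene_panel <- function(marker_table, msy_gene_means, mito_mean,
                             n_background, profib_genes = character(0),
                             profib_base = 40) {
  marker_genes <- unique(marker_table$gene)
  mito_genes <- paste0("MT-", c("CO1", "CO2", "CO3", "ND1", "ND2", "ND4",
                                "CYB", "ATP6"))
  bg_genes <- sprintf("BG%04d", seq_len(n_background))
  genes <- unique(c(marker_genes, names(msy_gene_means), mito_genes, bg_genes))
  base_mu <- setNames(numeric(length(genes)), genes)
  ## background means: heavy-tailed (many near-silent genes, a few abundant)
  ## so that per-cell expressed-gene counts land in the QC window at typical
  ## depths and the expression-bin structure used by module scoring is
  ## non-trivial
  base_mu[bg_genes] <- stats::rgamma(n_background, shape = 0.35, rate = 0.04)
  base_mu[mito_genes] <- mito_mean / length(mito_genes)
  base_mu[names(msy_gene_means)] <- msy_gene_means
  base_mu[marker_genes] <- pmax(base_mu[marker_genes], 8)
  ## profibrotic genes: moderately expressed so their up-regulation does
  ## not perturb the library composition (see profib_base docs)
  base_mu[intersect(profib_genes, genes)] <-
    pmax(base_mu[intersect(profib_genes, genes)], profib_base)
  list(genes = genes, base_mu = base_mu)
}

## markers defining a type: its own genes plus its parents' genes
type_marker_genes <- function(marker_table, type) {
  out <- character(0)
  lbl <- type
  while (length(lbl) == 1L && !is.na(lbl) && lbl %in% marker_table$label) {
    rows <- marker_table[marker_table$label == lbl, , drop = FALSE]
    out <- c(out, rows$gene)
    lbl <- rows$parent[1]
    if (is.null(lbl) || identical(lbl, "") || is.na(lbl)) break
  }
  unique(out)
}
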