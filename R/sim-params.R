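#' Parameters for a synthetic pool-seq study
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults describe the study design this scan is built for: three pooled
#' populations (a hyposalinity- and a hypersalinity-selected pool plus an
#' unselected control) of 46 diploid individuals each, sequenced to a mean
#' depth of about 35x, on a toy multi-scaffold genome of 1,000 one-kb tiles
#' with 5,000 SNPs, low background divergence and a small number of planted
#' high-divergence sweep regions targeting the hyposalinity pool.
#'
#' @param n_scaffolds number of scaffolds in the toy genome.
#' @param scaffold_length length of each scaffold in bp.
#' @param n_snps total number of segregating sites simulated.
#' @param pool_size diploid individuals per pool (46 as in the pooling design
#'   this emulates).
#' @param mean_depth mean sequencing depth per site per pool (reads).
#' @param background_divergence Balding-Nichols divergence `F` in `[0, 1)`
#'   shared by all populations at background loci.
#' @param n_outlier_loci number of planted outlier (swept) loci.
#' @param outlier_divergence floor on the true allele-frequency displacement
#'   planted between the treatment and control pools at outlier loci; must
#'   exceed `background_divergence` and be below 1.
#' @param ssr_fraction fraction of the genome covered by the simple-sequence
#'   repeat (SSR) mask.
#' @param n_genes number of gene models to place (must leave room for one
#'   host gene per outlier region).
#' @param gene_flank_bp flank recorded in the truth table for gene-level
#'   bookkeeping (bp).
#' @param n_terms size of the annotation term vocabulary.
#' @param de_overlap_fraction fraction of outlier-containing genes that are
#'   also placed on the differential-expression (DE) list.
#' @param n_outlier_regions number of linked sweep regions the outlier loci
#'   are clustered into; defaults to one region per five loci. Each region
#'   fits inside a single 1-kb tile, mimicking the linked footprint of a
#'   selective sweep.
#' @param outlier_pool name of the pool the planted sweeps act on.
#' @param seed integer master seed; all outputs derive named substreams from
#'   it, so identical parameters give bit-identical outputs.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(n_scaffolds = 2, scaffold_length = 2e4, n_snps = 100,
#'                 n_outlier_loci = 10, n_genes = 10, seed = 1)
#' p$pool_size
#' @export
sim_params <- function(n_scaffolds = 10,
                       scaffold_length = 1e5,
                       n_snps = 5000,
                       pool_size = 46,
                       mean_depth = 35,
                       background_divergence = 0.05,
                       n_outlier_loci = 50,
                       outlier_divergence = 0.6,
                       ssr_fraction = 0.05,
                       n_genes = 200,
                       gene_flank_bp = 5000,
                       n_terms = 20,
                       de_overlap_fraction = 1,
                       n_outlier_regions = NULL,
                       outlier_pool = "hypo",
                       seed = 1L) {
  chk_count <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x))
      stop("invalid sim_params: `", name, "` must be a single integer >= ",
           min, call. = FALSE)
  }
  chk_count(n_scaffolds, "n_scaffolds")
  chk_count(scaffold_length, "scaffold_length", min = 2000)
  chk_count(n_snps, "n_snps")
  chk_count(pool_size, "pool_size")
  chk_count(n_genes, "n_genes")
  chk_count(n_terms, "n_terms")
  chk_count(gene_flank_bp, "gene_flank_bp", min = 0)
  chk_count(n_outlier_loci, "n_outlier_loci", min = 0)
  chk_count(seed, "seed", min = 0)
  if (seed > 2^31 - 1000)
    stop("invalid sim_params: `seed` too large for substream derivation",
         call. = FALSE)
  if (!is.finite(mean_depth) || mean_depth < 1)
    stop("invalid sim_params: `mean_depth` must be >= 1", call. = FALSE)
  if (background_divergence < 0 || background_divergence >= 1)
    stop("invalid sim_params: `background_divergence` must be in [0, 1)",
         call. = FALSE)
  if (n_outlier_loci > n_snps)
    stop("invalid sim_params: `n_outlier_loci` cannot exceed `n_snps`",
         call. = FALSE)
  if (n_outlier_loci > 0 &&
      (outlier_divergence <= background_divergence || outlier_divergence >= 1))
    stop("invalid sim_params: need background_divergence < outlier_divergence < 1",
         call. = FALSE)
  if (ssr_fraction < 0 || ssr_fraction >= 1)
    stop("invalid sim_params: `ssr_fraction` must be in [0, 1)", call. = FALSE)
  if (de_overlap_fraction < 0 || de_overlap_fraction > 1)
    stop("invalid sim_params: `de_overlap_fraction` must be in [0, 1]",
         call. = FALSE)
  if (n_snps > n_scaffolds * scaffold_length / 2)
    stop("invalid sim_params: too many SNPs for the genome size", call. = FALSE)
  if (is.null(n_outlier_regions))
    n_outlier_regions <- if (n_outlier_loci > 0) ceiling(n_outlier_loci / 5) else 0
  if (n_outlier_loci > 0) {
    chk_count(n_outlier_regions, "n_outlier_regions")
    if (n_outlier_regions > n_outlier_loci)
      stop("invalid sim_params: more outlier regions than loci", call. = FALSE)
    if (ceiling(n_outlier_loci / n_outlier_regions) > 80)
      stop("invalid sim_params: too many outlier loci per 1-kb region",
           call. = FALSE)
    if (n_genes < n_outlier_regions)
      stop("invalid sim_params: `n_genes` must cover one host gene per outlier region",
           call. = FALSE)
    if (n_outlier_regions > n_scaffolds * (scaffold_length %/% 1000 - 2))
      stop("invalid sim_params: genome too small for the outlier regions",
           call. = FALSE)
  } else {
    n_outlier_regions <- 0
  }
  if (!is.character(outlier_pool) || length(outlier_pool) != 1 ||
      !outlier_pool %in% c("hypo", "hyper"))
    stop("invalid sim_params: `outlier_pool` must be \"hypo\" or \"hyper\"",
         call. = FALSE)
  structure(list(
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_length = as.integer(scaffold_length),
    n_snps = as.integer(n_snps),
    pool_size = as.integer(pool_size),
    mean_depth = mean_depth,
    background_divergence = background_divergence,
    n_outlier_loci = as.integer(n_outlier_loci),
    outlier_divergence = outlier_divergence,
    ssr_fraction = ssr_fraction,
    n_genes = as.integer(n_genes),
    gene_flank_bp = as.integer(gene_flank_bp),
    n_terms = as.integer(n_terms),
    de_overlap_fraction = de_overlap_fraction,
    n_outlier_regions = as.integer(n_outlier_regions),
    outlier_pool = outlier_pool,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic pool-seq study parameters\n")
  cat(sprintf("  genome: %d scaffolds x %d bp, %d SNPs\n",
              x$n_scaffolds, x$scaffold_length, x$n_snps))
  cat(sprintf("  pools: %d diploids each, mean depth %gx\n",
              x$pool_size, x$mean_depth))
  cat(sprintf("  divergence: background F = %g, %d planted loci (floor %g) in %d regions on '%s'\n",
              x$background_divergence, x$n_outlier_loci,
              x$outlier_divergence, x$n_outlier_regions, x$outlier_pool))
  cat(sprintf("  annotation: %d genes, %d terms, SSR fraction %g, DE overlap %g\n",
              x$n_genes, x$n_terms, x$ssr_fraction, x$de_overlap_fraction))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Named RNG substreams: any single output is reproducible in isolation from
# the master seed. Offsets are fixed constants, never data-dependent.
.sim_substream <- function(params, stream) {
  offsets <- c(frequencies = 11L, reads = 23L, annotation = 37L,
               phenotypes = 53L, qualities = 71L)
  set.seed(params$seed + offsets[[stream]])
}
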