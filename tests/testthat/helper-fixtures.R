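# In-code fixtures shared across the suite.

# Build a pooled site table from parallel vectors of per-pool counts.
# `counts` is a named list: counts$p1 = list(ref = ..., alt = ...), etc.
make_sites <- function(scaffold, pos, counts, ref = "A", alt = "C",
                       base_quality = 30) {
  n <- length(pos)
  out <- data.frame(scaffold = rep_len(scaffold, n), pos = pos,
                    ref = rep_len(ref, n), alt = rep_len(alt, n))
  for (pool in names(counts)) {
    out[[paste0("ref_", pool)]] <- as.integer(counts[[pool]]$ref)
    out[[paste0("alt_", pool)]] <- as.integer(counts[[pool]]$alt)
  }
  out$base_quality <- rep_len(base_quality, n)
  attr(out, "pools") <- names(counts)
  out
}

# Minimal gene-model container matching read_gene_models() output.
toy_models <- function(genes, exons) {
  g <- GenomicRanges::GRanges(genes$scaffold,
                              IRanges::IRanges(genes$start, genes$end))
  g$gene_id <- genes$gene_id
  e <- GenomicRanges::GRanges(exons$scaffold,
                              IRanges::IRanges(exons$start, exons$end))
  e$gene_id <- exons$gene_id
  list(genes = g, exons = e)
}

# The worked five-record filter fixture: one site per failing rule
# (min depth, het depth, max depth, SSR) plus one clean site.
filter_fixture <- function() {
  sites <- make_sites(
    "scaffold1", pos = c(100, 200, 300, 400, 500),
    counts = list(p1 = list(ref = c(1, 1, 80, 10, 7),
                            alt = c(0, 1, 0, 0, 3))))
  mask <- GenomicRanges::GRanges("scaffold1", IRanges::IRanges(390, 410))
  list(sites = sites, mask = mask)
}

# A small random site table for property-style checks.
random_sites <- function(n, pools = c("a", "b"), seed) {
  set.seed(seed)
  counts <- lapply(setNames(pools, pools), function(p)
    list(ref = rpois(n, 12), alt = rpois(n, 4)))
  make_sites("scaffold1", pos = sort(sample.int(50000, n)), counts = counts,
             base_quality = sample(10:40, n, replace = TRUE))
}

tiny_params <- function(...) {
  defaults <- list(n_scaffolds = 3, scaffold_length = 2e4, n_snps = 300,
                   n_outlier_loci = 10, n_outlier_regions = 2, n_genes = 12,
                   seed = 7)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}
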