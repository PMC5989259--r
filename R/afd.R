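#' Allele frequency from pooled read counts
#'
#' The pooled estimate of the alternate-allele frequency is the alternate
#' read count over the total depth.
#'
#' @param ref_count,alt_count non-negative read counts (vectorised).
#' @return `alt_count / (ref_count + alt_count)`.
#' @examples
#' pool_allele_frequency(30, 10)  # 0.25
#' @export
pool_allele_frequency <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0))
    stop("read counts must be non-negative")
  tot <- ref_count + alt_count
  if (any(tot < 1))
    stop("undefined frequency: zero total depth (site should have been filtered)")
  alt_count / tot
}

#' Allele frequency from genotype counts
#'
#' For individually genotyped samples (e.g. HRM validation panels) the
#' alternate-allele frequency is the alternate allele dose over the
#' chromosome count.
#'
#' @param n_ref_hom,n_het,n_alt_hom genotype class counts (vectorised).
#' @return `(2 * n_alt_hom + n_het) / (2 * (n_ref_hom + n_het + n_alt_hom))`.
#' @examples
#' genotype_allele_frequency(10, 20, 10)  # 0.5
#' @export
genotype_allele_frequency <- function(n_ref_hom, n_het, n_alt_hom) {
  if (any(n_ref_hom < 0 | n_het < 0 | n_alt_hom < 0))
    stop("genotype counts must be non-negative")
  tot <- n_ref_hom + n_het + n_alt_hom
  if (any(tot < 1)) stop("no genotyped individuals")
  (2 * n_alt_hom + n_het) / (2 * tot)
}

#' Allele-frequency-difference scan between two pools
#'
#' Computes per-site alternate-allele frequencies for the two pools and
#' their absolute difference (AFD), and flags sites whose AFD strictly
#' exceeds the threshold (the selection rule is "above 0.6", read as a
#' strict inequality). AFD is invariant to allele labelling and to swapping
#' the two pools.
#'
#' @param sites a (filtered) pooled site table.
#' @param pool_a,pool_b pool names present in the table.
#' @param threshold AFD selection threshold (default 0.6).
#' @return A `data.frame` sorted by scaffold then position: `scaffold`,
#'   `pos`, `freq_a`, `freq_b`, `afd`, `pass`.
#' @export
scan_afd <- function(sites, pool_a, pool_b, threshold = 0.6) {
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]")
  pools <- .site_pools(sites)
  for (p in c(pool_a, pool_b))
    if (!p %in% pools)
      stop("pool '", p, "' not present in the site table (pools: ",
           paste(pools, collapse = ", "), ")")
  freq_a <- pool_allele_frequency(sites[[paste0("ref_", pool_a)]],
                                  sites[[paste0("alt_", pool_a)]])
  freq_b <- pool_allele_frequency(sites[[paste0("ref_", pool_b)]],
                                  sites[[paste0("alt_", pool_b)]])
  out <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                    freq_a = freq_a, freq_b = freq_b,
                    afd = abs(freq_a - freq_b))
  # guard the strict comparison against floating-point noise so a count
  # ratio exactly at the threshold (e.g. |8/10 - 2/10| vs 0.6) never passes
  out$pass <- out$afd > threshold + 1e-9
  out <- out[order(out$scaffold, out$pos), ]
  rownames(out) <- NULL
  attr(out, "pools") <- c(pool_a, pool_b)
  attr(out, "threshold") <- threshold
  out
}

#' Genes carrying differentiated SNPs
#'
#' Maps the passing SNPs of an AFD scan to gene models: a gene is selected
#' when its span (optionally extended by `flank_bp` on both sides) contains
#' a passing SNP. With `nearest = TRUE` each passing SNP that hits no gene
#' is instead assigned to the nearest gene on its scaffold (the assignment
#' mode suggested by intergenic SNPs being reported with a gene).
#'
#' @param afd an AFD table from [scan_afd()] (or any table with `scaffold`,
#'   `pos`, `pass`).
#' @param models gene models from [read_gene_models()].
#' @param flank_bp flank added to each gene span (default 0).
#' @param nearest also assign gene-free passing SNPs to their nearest gene.
#' @return A list: `gene_ids` (sorted unique), `n_intergenic` (passing SNPs
#'   hitting no gene span even after flanking), and `snp_gene` (per passing
#'   SNP, the assigned gene or NA).
#' @export
afd_genes <- function(afd, models, flank_bp = 0, nearest = FALSE) {
  snps <- afd[afd$pass, , drop = FALSE]
  if (nrow(snps) == 0)
    return(list(gene_ids = character(0), n_intergenic = 0L,
                snp_gene = character(0)))
  snp_gr <- GRanges(snps$scaffold, IRanges(snps$pos, width = 1))
  spans <- models$genes
  ext <- GenomicRanges::trim(suppressWarnings(spans + flank_bp))
  ov <- suppressWarnings(findOverlaps(snp_gr, ext, ignore.strand = TRUE))
  assigned <- rep(NA_character_, length(snp_gr))
  assigned[queryHits(ov)] <- spans$gene_id[subjectHits(ov)]
  n_intergenic <- sum(is.na(assigned))
  if (nearest && n_intergenic > 0) {
    idx <- which(is.na(assigned))
    near <- GenomicRanges::nearest(snp_gr[idx], spans, ignore.strand = TRUE)
    assigned[idx[!is.na(near)]] <- spans$gene_id[near[!is.na(near)]]
  }
  gene_ids <- sort(unique(spans$gene_id[subjectHits(ov)]))
  if (nearest)
    gene_ids <- sort(unique(assigned[!is.na(assigned)]))
  list(gene_ids = gene_ids, n_intergenic = n_intergenic,
       snp_gene = assigned)
}
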