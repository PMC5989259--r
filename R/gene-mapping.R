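#' Genes overlapping outlier windows (with flanks)
#'
#' A gene is selected when its span intersects any outlier window extended
#' by `flank_bp` upstream and downstream. Intersection follows half-open
#' semantics at the window boundary: a gene starting exactly where the
#' extended window ends (the first base after it) does not overlap. Flanks
#' are clipped at scaffold bounds.
#'
#' @param windows either a window table from [select_top_windows()] (its
#'   `is_outlier` rows are used; `start` is 0-based) or a `GRanges` of
#'   windows.
#' @param models gene models from [read_gene_models()].
#' @param flank_bp flank added to each window on both sides (default 5000).
#' @return Sorted unique gene IDs.
#' @export
genes_overlapping_windows <- function(windows, models, flank_bp = 5000) {
  if (flank_bp < 0) stop("`flank_bp` must be >= 0")
  if (inherits(windows, "GRanges")) {
    win_gr <- windows
  } else {
    w <- windows
    if ("is_outlier" %in% names(w)) w <- w[w$is_outlier, , drop = FALSE]
    if (nrow(w) == 0) return(character(0))
    win_gr <- GRanges(w$scaffold, IRanges(w$start + 1L, w$end))
  }
  if (length(win_gr) == 0) return(character(0))
  gene_scaffolds <- unique(as.character(seqnames(models$genes)))
  win_scaffolds <- unique(as.character(seqnames(win_gr)))
  if (length(intersect(win_scaffolds, gene_scaffolds)) == 0)
    stop("scaffold names of windows and gene models do not match: windows ",
         "use [", paste(head(win_scaffolds, 5), collapse = ", "),
         "], gene models use [",
         paste(head(gene_scaffolds, 5), collapse = ", "), "]")
  ext <- GenomicRanges::trim(suppressWarnings(win_gr + flank_bp))
  ov <- suppressWarnings(findOverlaps(ext, models$genes, ignore.strand = TRUE))
  sort(unique(models$genes$gene_id[subjectHits(ov)]))
}

#' Classify SNP positions as CDS, intron or intergenic
#'
#' A position is `CDS` when it falls inside any exon interval of any gene,
#' `Intron` when it lies within a gene span but in no exon, and
#' `Intergenic` otherwise. When overlapping genes disagree, CDS takes
#' precedence over Intron. Strand is ignored.
#'
#' @param scaffold,pos vectors of SNP coordinates (1-based).
#' @param models gene models from [read_gene_models()].
#' @return A character vector of area labels, one per SNP.
#' @export
classify_snp_area <- function(scaffold, pos, models) {
  gr <- GRanges(scaffold, IRanges(pos, width = 1))
  in_exon <- overlapsAny_int(gr, models$exons)
  in_gene <- overlapsAny_int(gr, models$genes)
  ifelse(in_exon, "CDS", ifelse(in_gene, "Intron", "Intergenic"))
}
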