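#' Merge AFD- and F_ST-derived gene sets with provenance
#'
#' The DNA-level differentiated gene set for one comparison is the union of
#' the AFD-selected and the F_ST-window-selected genes, with each gene
#' tagged by the evidence stream(s) that selected it.
#'
#' @param afd_genes,fst_genes character vectors of gene IDs from the same
#'   comparison.
#' @param label set label (e.g. the comparison name).
#' @return A `data.frame` with `gene_id` and `provenance`
#'   (`"AFD"`, `"FST"` or `"AFD,FST"`), sorted by gene ID; the label is in
#'   `attr(, "label")`.
#' @export
merge_differentiated <- function(afd_genes, fst_genes, label = "differentiated") {
  afd_genes <- unique(afd_genes)
  fst_genes <- unique(fst_genes)
  ids <- sort(union(afd_genes, fst_genes))
  prov <- vapply(ids, function(g)
    paste(c("AFD"[g %in% afd_genes], "FST"[g %in% fst_genes]),
          collapse = ","), "")
  out <- data.frame(gene_id = ids, provenance = unname(prov))
  attr(out, "label") <- label
  out
}

#' Three-way Venn decomposition of evidence streams
#'
#' Decomposes the AFD, F_ST and differential-expression (DE) gene sets into
#' the seven disjoint Venn regions and defines the candidate set as the
#' genes supported at both the DNA and the expression level:
#' `(AFD union FST) intersect DE`.
#'
#' @param afd_genes,fst_genes,de_genes character vectors of gene IDs in one
#'   consistent namespace.
#' @return A list with `counts` (named 7-vector of region cardinalities),
#'   `regions` (the membership of each region), and `candidates`.
#' @export
venn3 <- function(afd_genes, fst_genes, de_genes) {
  a <- unique(afd_genes); f <- unique(fst_genes); d <- unique(de_genes)
  all_ids <- union(union(a, f), d)
  in_a <- all_ids %in% a; in_f <- all_ids %in% f; in_d <- all_ids %in% d
  region <- paste0(ifelse(in_a, "A", ""), ifelse(in_f, "F", ""),
                   ifelse(in_d, "D", ""))
  labels <- c(A = "afd_only", F = "fst_only", D = "de_only",
              AF = "afd_fst", AD = "afd_de", FD = "fst_de",
              AFD = "afd_fst_de")
  regions <- lapply(names(labels), function(code)
    sort(all_ids[region == code]))
  names(regions) <- unname(labels)
  counts <- vapply(regions, length, 1L)
  candidates <- sort(intersect(union(a, f), d))
  list(counts = counts, regions = regions, candidates = candidates)
}

#' Hypergeometric term enrichment with BH correction
#'
#' For each annotation term, tests over-representation of the candidate
#' genes with the one-sided hypergeometric tail `P(X >= k)` (population =
#' background size, successes = term size in the background, draws =
#' candidate set size), then adjusts across terms by Benjamini-Hochberg.
#' This is the generic enrichment machinery used with externally supplied
#' GO/COG/KEGG-style gene-to-term tables.
#'
#' @param candidates candidate gene IDs; must all be in `background`.
#' @param background the gene universe (IDs).
#' @param term_map `data.frame` with columns `gene_id` and `term`; rows
#'   whose gene is outside the background are ignored, and every term kept
#'   must annotate at least one background gene.
#' @return A `data.frame` sorted by adjusted then raw p: `term`,
#'   `term_size`, `overlap`, `expected`, `p`, `p_adj`.
#' @export
enrich_terms <- function(candidates, background, term_map) {
  candidates <- unique(candidates)
  background <- unique(background)
  extra <- setdiff(candidates, background)
  if (length(extra) > 0)
    stop("candidate gene(s) absent from the background: ",
         paste(head(extra, 5), collapse = ", "))
  if (!all(c("gene_id", "term") %in% names(term_map)))
    stop("`term_map` needs columns `gene_id` and `term`")
  term_map <- unique(term_map[term_map$gene_id %in% background,
                              c("gene_id", "term")])
  if (nrow(term_map) == 0) stop("no term annotations on the background")
  N <- length(background)
  n_draw <- length(candidates)
  terms <- sort(unique(term_map$term))
  term_size <- vapply(terms, function(tm)
    sum(term_map$term == tm), 1L)
  overlap <- vapply(terms, function(tm)
    sum(term_map$gene_id[term_map$term == tm] %in% candidates), 1L)
  p <- phyper(overlap - 1, term_size, N - term_size, n_draw,
              lower.tail = FALSE)
  out <- data.frame(term = terms, term_size = term_size, overlap = overlap,
                    expected = n_draw * term_size / N, p = p,
                    p_adj = p.adjust(p, method = "BH"))
  out <- out[order(out$p_adj, out$p, out$term), ]
  rownames(out) <- NULL
  out
}
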