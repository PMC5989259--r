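#' @title Synthetic pool-seq study generation
#' @description Internal Balding-Nichols draw: population allele frequencies
#'   around an ancestral frequency `p` with divergence `f`. `f = 0` is the
#'   degenerate point mass at `p`.
#' @noRd
.bn_draw <- function(p, f) {
  if (f == 0) return(p)
  shape <- (1 - f) / f
  rbeta(length(p), p * shape, (1 - p) * shape)
}

#' Simulate true population allele frequencies with planted sweeps
#'
#' Draws the truth table for a three-population pooled study (two selected
#' pools, `hypo` and `hyper`, plus a `control`). Background loci get an
#' ancestral frequency uniform on (0.05, 0.95) and independent
#' Balding-Nichols draws at `background_divergence` for every population.
#' Planted outlier loci model a directional sweep in the designated treatment
#' pool: a low-frequency standing variant (unselected frequency uniform on
#' (0.02, 0.12), mirrored to the other allele with probability 1/2) is driven
#' to a frequency displaced from the control by at least
#' `outlier_divergence`, with the displacement drawn on
#' `(outlier_divergence, 1)` tilted toward fixation (Beta(2, 1) tilt). The
#' planted loci are clustered into `n_outlier_regions` linked regions, each
#' inside a single 1-kb tile, mimicking a sweep's linked footprint.
#'
#' @param params a [sim_params()] object.
#' @return A `data.frame` (the truth table) with one row per locus:
#'   `scaffold`, `pos` (1-based), `ref`, `alt` (bases), `p_anc`, `p_hypo`,
#'   `p_hyper`, `p_control` (true alternate-allele frequencies) and
#'   `is_outlier`. The planted regions are attached as
#'   `attr(, "outlier_regions")` (scaffold and 0-based window start), and the
#'   parameters as `attr(, "params")`.
#' @examples
#' truth <- simulate_population_frequencies(
#'   sim_params(n_scaffolds = 2, scaffold_length = 1e4, n_snps = 50,
#'              n_outlier_loci = 5, n_outlier_regions = 1, n_genes = 5))
#' sum(truth$is_outlier)
#' @export
simulate_population_frequencies <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  .sim_substream(params, "frequencies")
  scaffolds <- sprintf("scaffold%d", seq_len(params$n_scaffolds))
  n_win <- params$scaffold_length %/% 1000L

  # planted sweep regions, one per 1-kb tile
  n_reg <- params$n_outlier_regions
  reg <- NULL
  out_scaffold <- character(0); out_pos <- integer(0); out_region <- integer(0)
  if (n_reg > 0) {
    grid <- expand.grid(scaffold = scaffolds, win = seq_len(n_win) - 1L,
                        stringsAsFactors = FALSE)
    pick <- sample.int(nrow(grid), n_reg)
    reg <- data.frame(region = seq_len(n_reg),
                      scaffold = grid$scaffold[pick],
                      win_start = grid$win[pick] * 1000L)
    per_reg <- diff(floor(seq(0, params$n_outlier_loci, length.out = n_reg + 1)))
    for (r in seq_len(n_reg)) {
      k <- per_reg[r]
      if (k == 0) next
      pos <- sort(sample((reg$win_start[r] + 151L):(reg$win_start[r] + 850L), k))
      out_scaffold <- c(out_scaffold, rep(reg$scaffold[r], k))
      out_pos <- c(out_pos, pos)
      out_region <- c(out_region, rep(r, k))
    }
  }

  # background loci anywhere else on the genome
  n_bg <- params$n_snps - params$n_outlier_loci
  genome_size <- params$n_scaffolds * params$scaffold_length
  taken <- paste(out_scaffold, out_pos)
  lin <- integer(0)
  while (length(lin) < n_bg) {
    cand <- sample.int(genome_size, n_bg - length(lin))
    sc <- scaffolds[(cand - 1L) %/% params$scaffold_length + 1L]
    po <- (cand - 1L) %% params$scaffold_length + 1L
    keep <- !(paste(sc, po) %in% taken) & !duplicated(cand)
    cand <- cand[keep]
    taken <- c(taken, paste(sc[keep], po[keep]))
    lin <- c(lin, cand)
  }
  bg_scaffold <- scaffolds[(lin - 1L) %/% params$scaffold_length + 1L]
  bg_pos <- (lin - 1L) %% params$scaffold_length + 1L

  # background frequencies: independent Balding-Nichols per population
  f_bg <- params$background_divergence
  p_anc_bg <- runif(n_bg, 0.05, 0.95)
  bg <- data.frame(scaffold = bg_scaffold, pos = as.integer(bg_pos),
                   p_anc = p_anc_bg,
                   p_hypo = .bn_draw(p_anc_bg, f_bg),
                   p_hyper = .bn_draw(p_anc_bg, f_bg),
                   p_control = .bn_draw(p_anc_bg, f_bg),
                   is_outlier = FALSE)

  # planted sweep frequencies
  if (params$n_outlier_loci > 0) {
    k <- params$n_outlier_loci
    f_out <- params$outlier_divergence
    delta <- f_out + (1 - f_out) * rbeta(k, 2, 1)
    p_low <- runif(k, 0.02, 0.12)
    p_hi <- pmin(p_low + delta, 0.995)
    flip <- runif(k) < 0.5
    p_ctrl <- ifelse(flip, 1 - p_low, p_low)
    p_treat <- ifelse(flip, 1 - p_hi, p_hi)
    p_other <- .bn_draw(p_ctrl, f_bg)
    ot <- data.frame(scaffold = out_scaffold, pos = out_pos,
                     p_anc = p_ctrl,
                     p_hypo = if (params$outlier_pool == "hypo") p_treat else p_other,
                     p_hyper = if (params$outlier_pool == "hyper") p_treat else p_other,
                     p_control = p_ctrl,
                     is_outlier = TRUE)
    truth <- rbind(bg, ot)
  } else {
    truth <- bg
  }

  # biallelic site labels
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(truth), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  truth$ref <- ref
  truth$alt <- unname(alt)
  truth <- truth[order(truth$scaffold, truth$pos),
                 c("scaffold", "pos", "ref", "alt", "p_anc",
                   "p_hypo", "p_hyper", "p_control", "is_outlier")]
  rownames(truth) <- NULL
  attr(truth, "outlier_regions") <- reg
  attr(truth, "params") <- params
  truth
}

#' Simulate pooled sequencing reads over a truth table
#'
#' Two-stage sampling per site and pool: the pool's sample allele frequency is
#' drawn binomially from `2 * pool_size` chromosome draws at the true
#' population frequency (pooling 46 diploids adds variance beyond read
#' sampling), then the alternate read count is drawn binomially from the
#' site's depth at that sample frequency. Depth is zero-truncated Poisson
#' with mean `mean_depth`. Site base qualities are phred-score placeholders.
#'
#' @param truth a truth table from [simulate_population_frequencies()].
#' @param params the matching [sim_params()].
#' @param mask optional SSR mask (`GRanges`); if supplied, an `in_ssr`
#'   column is added.
#' @return A pooled site table: `scaffold`, `pos`, `ref`, `alt`,
#'   `ref_<pool>`/`alt_<pool>` read counts for pools `hypo`, `hyper`,
#'   `control`, and `base_quality`. Pool names are attached as
#'   `attr(, "pools")`.
#' @export
simulate_pool_reads <- function(truth, params, mask = NULL) {
  stopifnot(inherits(params, "sim_params"))
  pcols <- c("p_hypo", "p_hyper", "p_control")
  if (!all(c("scaffold", "pos", pcols) %in% names(truth)))
    stop("`truth` must come from simulate_population_frequencies()")
  if (any(unlist(truth[pcols]) < 0 | unlist(truth[pcols]) > 1))
    stop("truth frequencies must be in [0, 1]")
  .sim_substream(params, "reads")
  n <- nrow(truth)
  sites <- truth[c("scaffold", "pos", "ref", "alt")]
  p0 <- ppois(0, params$mean_depth)
  for (pool in c("hypo", "hyper", "control")) {
    depth <- qpois(p0 + runif(n) * (1 - p0), params$mean_depth)  # truncated at 1
    ac <- rbinom(n, 2L * params$pool_size, truth[[paste0("p_", pool)]]) /
      (2 * params$pool_size)
    alt_n <- rbinom(n, depth, ac)
    sites[[paste0("ref_", pool)]] <- as.integer(depth - alt_n)
    sites[[paste0("alt_", pool)]] <- as.integer(alt_n)
  }
  sites$base_quality <- sample(28:40, n, replace = TRUE)
  if (!is.null(mask)) {
    gr <- GRanges(sites$scaffold, IRanges(sites$pos, width = 1))
    sites$in_ssr <- overlapsAny_int(gr, mask)
  }
  attr(sites, "pools") <- c("hypo", "hyper", "control")
  sites
}

# single overlap-query call site; querying across disjoint seqlevel sets
# (e.g. a gene-free scaffold) is legitimate here, so the Seqinfo merge
# warning is silenced
overlapsAny_int <- function(query, subject) {
  length_hits <- rep(FALSE, length(query))
  ov <- suppressWarnings(findOverlaps(query, subject))
  length_hits[unique(queryHits(ov))] <- TRUE
  length_hits
}

#' Simulate gene models, term annotation, SSR mask and DE list
#'
#' Places non-overlapping multi-exon gene models on the toy genome, one host
#' gene spanning each planted sweep region (a sweep footprint sitting inside
#' a gene is the configuration the scan is designed to detect), assigns 1-3
#' annotation terms per gene from a vocabulary of `n_terms`, lays down a
#' random SSR interval mask covering about `ssr_fraction` of the genome
#' (kept clear of the planted regions so the mask filter does not erase the
#' positive control), and draws a differential-expression gene list
#' containing `de_overlap_fraction` of the outlier-containing genes plus 10%
#' of the remaining genes as expression-only noise.
#'
#' @param truth truth table from [simulate_population_frequencies()].
#' @param params the matching [sim_params()].
#' @return A list with `genes` (1-based inclusive spans), `exons`,
#'   `term_map`, `de_genes`, `mask` (a `GRanges`), and `gene_truth`
#'   (per-gene `contains_outlier` / `is_de` flags).
#' @export
simulate_annotation <- function(truth, params) {
  stopifnot(inherits(params, "sim_params"))
  .sim_substream(params, "annotation")
  scaffolds <- sprintf("scaffold%d", seq_len(params$n_scaffolds))
  L <- params$scaffold_length
  reg <- attr(truth, "outlier_regions")

  gene_list <- list()
  if (!is.null(reg) && nrow(reg) > 0) {
    for (r in seq_len(nrow(reg))) {
      s <- max(1L, reg$win_start[r] + 1L - 200L)
      e <- min(L, reg$win_start[r] + 1200L)
      gene_list[[length(gene_list) + 1L]] <-
        data.frame(scaffold = reg$scaffold[r], start = s, end = e)
    }
  }
  host <- if (length(gene_list)) do.call(rbind, gene_list) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0))

  # remaining genes on a 3-kb slot grid, skipping slots touching host genes
  n_other <- params$n_genes - nrow(host)
  slot_w <- 3000L
  slots <- expand.grid(scaffold = scaffolds,
                       slot = seq_len(L %/% slot_w) - 1L,
                       stringsAsFactors = FALSE)
  slots$start <- slots$slot * slot_w + 1L
  slots$end <- slots$start + slot_w - 1L
  if (nrow(host) > 0) {
    s_gr <- GRanges(slots$scaffold, IRanges(slots$start, slots$end))
    h_gr <- GRanges(host$scaffold, IRanges(host$start, host$end))
    slots <- slots[!overlapsAny_int(s_gr, h_gr), ]
  }
  if (n_other > nrow(slots))
    stop("genes cannot be placed without overlap: increase genome size ",
         "or reduce `n_genes`")
  if (n_other > 0) {
    pick <- slots[sample.int(nrow(slots), n_other), ]
    len <- sample(800:2000, n_other, replace = TRUE)
    off <- vapply(slot_w - len - 1L, function(m) sample.int(m, 1), 1L)
    other <- data.frame(scaffold = pick$scaffold,
                        start = pick$start + off,
                        end = pick$start + off + len - 1L)
    genes <- rbind(host, other)
  } else {
    genes <- host
  }
  genes <- genes[order(genes$scaffold, genes$start), ]
  genes$gene_id <- sprintf("gene_%05d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes <- genes[c("gene_id", "scaffold", "start", "end", "strand")]
  rownames(genes) <- NULL

  # 2-4 exons per gene: odd-numbered equal chunks of the span are exonic
  exon_list <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    n_ex <- sample(2:4, 1)
    cuts <- round(seq(genes$start[i], genes$end[i] + 1L,
                      length.out = 2L * n_ex))
    exon_list[[i]] <- data.frame(
      gene_id = genes$gene_id[i], scaffold = genes$scaffold[i],
      start = cuts[seq(1, 2 * n_ex - 1, by = 2)],
      end = cuts[seq(2, 2 * n_ex, by = 2)] - 1L)
  }
  exons <- do.call(rbind, exon_list)
  rownames(exons) <- NULL

  # term annotation
  terms <- sprintf("T%03d", seq_len(params$n_terms))
  term_map <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    data.frame(gene_id = genes$gene_id[i],
               term = sample(terms, sample(1:3, 1)))
  }))
  rownames(term_map) <- NULL

  # SSR mask, clear of the planted regions
  mask_iv <- data.frame(scaffold = character(0), start = integer(0),
                        end = integer(0))
  if (params$ssr_fraction > 0) {
    for (sc in scaffolds) {
      keep_s <- keep_e <- numeric(0)
      if (!is.null(reg) && nrow(reg) > 0) {
        ri <- reg$scaffold == sc
        keep_s <- reg$win_start[ri] + 1L
        keep_e <- reg$win_start[ri] + 1000L
      }
      target <- params$ssr_fraction * L
      covered <- 0; tries <- 0
      cur_s <- cur_e <- numeric(0)
      while (covered < target && tries < 10000) {
        tries <- tries + 1
        w <- sample(200:800, 1)
        s <- sample.int(L - w, 1); e <- s + w - 1L
        clash <- any(s <= cur_e & e >= cur_s) || any(s <= keep_e & e >= keep_s)
        if (!clash) {
          cur_s <- c(cur_s, s); cur_e <- c(cur_e, e)
          covered <- covered + w
        }
      }
      if (length(cur_s) > 0)
        mask_iv <- rbind(mask_iv, data.frame(
          scaffold = sc, start = as.integer(sort(cur_s)),
          end = as.integer(cur_e[order(cur_s)])))
    }
    mask_iv <- mask_iv[order(mask_iv$scaffold, mask_iv$start), ]
    rownames(mask_iv) <- NULL
  }
  mask <- GRanges(mask_iv$scaffold, IRanges(mask_iv$start, mask_iv$end))

  # per-gene truth: outlier content and DE membership
  out_pos <- truth[truth$is_outlier, c("scaffold", "pos")]
  if (nrow(out_pos) > 0) {
    g_gr <- GRanges(genes$scaffold, IRanges(genes$start, genes$end))
    o_gr <- GRanges(out_pos$scaffold, IRanges(out_pos$pos, width = 1))
    contains <- overlapsAny_int(g_gr, o_gr)
  } else {
    contains <- rep(FALSE, nrow(genes))
  }
  out_genes <- genes$gene_id[contains]
  n_de_out <- round(params$de_overlap_fraction * length(out_genes))
  de_out <- if (n_de_out > 0) sample(out_genes, n_de_out) else character(0)
  non_out <- setdiff(genes$gene_id, out_genes)
  de_bg <- if (length(non_out) > 0)
    sample(non_out, round(0.1 * length(non_out))) else character(0)
  de_genes <- sort(c(de_out, de_bg))
  gene_truth <- data.frame(gene_id = genes$gene_id,
                           contains_outlier = contains,
                           is_de = genes$gene_id %in% de_genes)

  list(genes = genes, exons = exons, term_map = term_map,
       de_genes = de_genes, mask = mask, gene_truth = gene_truth)
}

#' Simulate larval phenotype count tables
#'
#' Emulates the four larval assays used to demonstrate phenotypic
#' differentiation between salinity-adapted and control groups: larval
#' production (D-stage larvae per incubated egg), survival (survivors per
#' starting D-larva), growth (relative shell-height gain) and adhesion
#' (adherent per eye-spot larva). For the count-based traits each replicate
#' draws a true rate from a normal around the group mean (clamped to [0, 1])
#' and then a binomial numerator at that rate; for growth, replicate mean
#' shell heights before and after treatment are drawn so that the relative
#' gain matches the group mean on average.
#'
#' @param group_means traits-by-groups numeric matrix of true rates; rows
#'   must be named with the four traits. Defaults emulate a study in which
#'   the control group outperforms both selected groups under common-garden
#'   conditions.
#' @param group_sds matching matrix (or scalar) of between-replicate SDs.
#' @param n_per_group replicates per group.
#' @param seed integer seed.
#' @param denominators named counts of starting individuals per replicate
#'   for the count-based traits.
#' @return A long `data.frame`: `trait`, `group`, `replicate`, `numerator`,
#'   `denominator`. For `growth` the numerator/denominator are mean shell
#'   heights (micrometres) after/before treatment.
#' @export
simulate_phenotypes <- function(group_means = NULL, group_sds = 0.04,
                                n_per_group = 3, seed = 1L,
                                denominators = c(production = 400,
                                                 survival = 300,
                                                 adhesive = 200)) {
  traits <- c("production", "survival", "growth", "adhesive")
  if (is.null(group_means)) {
    group_means <- rbind(production = c(hypo = 0.40, control = 0.55, hyper = 0.45),
                         survival = c(hypo = 0.60, control = 0.70, hyper = 0.50),
                         growth = c(hypo = 0.35, control = 0.50, hyper = 0.40),
                         adhesive = c(hypo = 0.45, control = 0.60, hyper = 0.50))
  }
  group_means <- as.matrix(group_means)
  if (is.null(rownames(group_means)) || !setequal(rownames(group_means), traits))
    stop("`group_means` must have one row per trait: ",
         paste(traits, collapse = ", "))
  group_means <- group_means[traits, , drop = FALSE]
  if (length(group_sds) == 1)
    group_sds <- matrix(group_sds, nrow = nrow(group_means),
                        ncol = ncol(group_means),
                        dimnames = dimnames(group_means))
  group_sds <- as.matrix(group_sds)[traits, , drop = FALSE]
  if (any(group_means < 0 | group_means > 1))
    stop("trait rate means must be in [0, 1]")
  if (n_per_group < 1) stop("`n_per_group` must be >= 1")
  set.seed(seed)
  groups <- colnames(group_means)
  rows <- list()
  for (tr in traits) {
    for (g in groups) {
      for (r in seq_len(n_per_group)) {
        true_rate <- min(1, max(0, rnorm(1, group_means[tr, g],
                                         group_sds[tr, g])))
        if (tr == "growth") {
          before <- round(rnorm(1, 70, 2 / sqrt(30)), 2)
          after <- round(before * (1 + true_rate), 2)
          num <- after; den <- before
        } else {
          den <- denominators[[tr]]
          num <- rbinom(1, den, true_rate)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, group = g, replicate = r,
          numerator = num, denominator = den)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate and write a complete synthetic pool-seq study
#'
#' Runs the whole generator (truth, annotation, pooled reads, phenotypes) and
#' writes every study input to `dir` in plain-text formats: a sync-style
#' pooled count table (with a trailing per-site base-quality column), a VCF
#' with per-pool AD fields, GFF3 gene models, a BED SSR mask, a gene-to-term
#' table, a DE gene list, phenotype tables, and the truth tables used as the
#' validation oracle. Identical parameters (including the seed) give
#' byte-identical files.
#'
#' @param params a [sim_params()] object.
#' @param dir output directory (created if missing).
#' @param write_vcf also write the VCF representation (default `TRUE`).
#' @return Invisibly, a list with the generated objects (`truth`, `sites`,
#'   `annotation`) and a named vector of file `paths`.
#' @export
simulate_poolseq_study <- function(params, dir, write_vcf = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- simulate_population_frequencies(params)
  annot <- simulate_annotation(truth, params)
  sites <- simulate_pool_reads(truth, params, mask = annot$mask)
  pheno <- simulate_phenotypes(seed = params$seed + 53L)

  paths <- c(
    sync = file.path(dir, "pools.sync"),
    vcf = file.path(dir, "pools.vcf"),
    gff = file.path(dir, "genes.gff3"),
    mask = file.path(dir, "ssr_mask.bed"),
    terms = file.path(dir, "gene_terms.tsv"),
    de = file.path(dir, "de_genes.txt"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"))

  write_sync(sites, paths[["sync"]])
  if (write_vcf) write_pool_vcf(sites, paths[["vcf"]]) else
    paths <- paths[names(paths) != "vcf"]
  write_gene_models(annot$genes, annot$exons, paths[["gff"]])
  rtracklayer::export(annot$mask, paths[["mask"]], format = "BED")
  write.table(annot$term_map, paths[["terms"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(annot$de_genes, paths[["de"]])
  write.table(pheno, paths[["phenotypes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- truth
  attr(tr, "outlier_regions") <- NULL; attr(tr, "params") <- NULL
  write.table(tr, paths[["truth_sites"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(annot$gene_truth, paths[["truth_genes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(truth = truth, sites = sites, annotation = annot,
                 phenotypes = pheno, paths = paths))
}
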