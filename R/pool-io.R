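#' Write a pooled site table in sync format
#'
#' The sync dialect is tab-delimited: scaffold, 1-based position, reference
#' base, then one `A:T:C:G:N:del` count column per pool. As an extension this
#' writer appends a final numeric column with the per-site base quality
#' (phred), which [read_sync()] detects automatically; omit it with
#' `quality = FALSE` for strict six-field-per-pool sync.
#'
#' @param sites a pooled site table (see [simulate_pool_reads()] or
#'   [read_pool_sites()]): columns `scaffold`, `pos`, `ref`, `alt` and
#'   `ref_<pool>` / `alt_<pool>` counts, pools in `attr(, "pools")`.
#' @param path output file.
#' @param quality append the base-quality column (default `TRUE` when the
#'   table has one).
#' @return `path`, invisibly.
#' @export
write_sync <- function(sites, path, quality = "base_quality" %in% names(sites)) {
  pools <- .site_pools(sites)
  base_order <- c("A", "T", "C", "G")
  ref_slot <- match(sites$ref, base_order)
  alt_slot <- match(sites$alt, base_order)
  cols <- list(sites$scaffold, sites$pos, sites$ref)
  for (pool in pools) {
    counts <- matrix(0L, nrow = nrow(sites), ncol = 6)
    idx <- seq_len(nrow(sites))
    counts[cbind(idx, ref_slot)] <- sites[[paste0("ref_", pool)]]
    counts[cbind(idx, alt_slot)] <- counts[cbind(idx, alt_slot)] +
      sites[[paste0("alt_", pool)]]
    cols[[length(cols) + 1L]] <-
      apply(counts, 1, paste, collapse = ":")
  }
  if (quality) cols[[length(cols) + 1L]] <- sites$base_quality
  tab <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.site_pools <- function(sites) {
  pools <- attr(sites, "pools")
  if (is.null(pools))
    pools <- sub("^ref_", "", grep("^ref_", names(sites), value = TRUE))
  if (length(pools) == 0) stop("no pool count columns found")
  missing <- setdiff(c(paste0("ref_", pools), paste0("alt_", pools)),
                     names(sites))
  if (length(missing) > 0)
    stop("unknown pool column(s): ", paste(missing, collapse = ", "))
  pools
}

#' Read a pooled site table from sync format
#'
#' Parses the sync dialect written by [write_sync()]. The alternate allele at
#' each site is the non-reference base with the highest summed count across
#' pools; sites where more than one non-reference base carries reads are
#' multi-allelic and are dropped, with the dropped count reported in
#' `attr(, "n_multiallelic")` and a message. A trailing numeric column, if
#' present, is taken as the per-site base quality.
#'
#' @param path sync file.
#' @param pools pool names, in file column order.
#' @return A site table with columns `scaffold`, `pos`, `ref`, `alt`,
#'   per-pool `ref_`/`alt_` counts and `base_quality` (NA when the file has
#'   no quality column).
#' @export
read_sync <- function(path, pools = c("hypo", "hyper", "control")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty sync file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- 3L + length(pools)
  has_qual <- all(nf == want + 1L)
  if (!has_qual && !all(nf == want)) {
    bad <- which(nf != want & nf != want + 1L)[1]
    stop("malformed sync line ", bad, ": expected ", want, " or ", want + 1,
         " fields, found ", nf[bad])
  }
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  scaffold <- m[, 1]
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos))
    stop("malformed sync line ", which(is.na(pos))[1],
         ": position is not an integer")
  ref <- m[, 3]
  base_order <- c("A", "T", "C", "G")
  n <- length(lines)
  counts <- array(0L, dim = c(n, 6, length(pools)))
  for (j in seq_along(pools)) {
    sp <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    if (any(lengths(sp) != 6))
      stop("malformed sync line ", which(lengths(sp) != 6)[1],
           ": pool column '", pools[j], "' is not A:T:C:G:N:del")
    v <- suppressWarnings(as.integer(unlist(sp)))
    if (anyNA(v))
      stop("malformed sync file: non-integer count in pool '", pools[j], "'")
    counts[, , j] <- matrix(v, ncol = 6, byrow = TRUE)
  }
  tot <- apply(counts[, 1:4, , drop = FALSE], c(1, 2), sum)
  ref_slot <- match(ref, base_order)
  if (anyNA(ref_slot))
    stop("malformed sync line ", which(is.na(ref_slot))[1],
         ": reference base must be one of A/T/C/G")
  nonref <- tot
  nonref[cbind(seq_len(n), ref_slot)] <- 0L
  n_seg <- rowSums(nonref > 0)
  multi <- n_seg > 1
  alt_slot <- max.col(nonref, ties.method = "first")
  no_alt <- n_seg == 0
  alt_slot[no_alt] <- ifelse(ref_slot[no_alt] == 1L, 2L, 1L)
  out <- data.frame(scaffold = scaffold, pos = pos, ref = ref,
                    alt = base_order[alt_slot])
  for (j in seq_along(pools)) {
    out[[paste0("ref_", pools[j])]] <-
      counts[cbind(seq_len(n), ref_slot, j)]
    out[[paste0("alt_", pools[j])]] <-
      counts[cbind(seq_len(n), alt_slot, j)]
  }
  out$base_quality <- if (has_qual)
    suppressWarnings(as.numeric(m[, ncol(m)])) else NA_real_
  if (any(multi)) {
    message("read_sync: dropped ", sum(multi), " multi-allelic site(s)")
    out <- out[!multi, ]
    rownames(out) <- NULL
  }
  attr(out, "pools") <- pools
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' Write a pooled site table as a minimal VCF
#'
#' One sample column per pool, genotype-free, with the per-pool read counts
#' in the `AD` (allelic depth) FORMAT field and the site base quality in
#' QUAL. The output is VCF 4.2 and is read back by [read_pool_sites()] via
#' the vcfR parser.
#'
#' @inheritParams write_sync
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(sites, path) {
  pools <- .site_pools(sites)
  qual <- if ("base_quality" %in% names(sites) &&
              !all(is.na(sites$base_quality)))
    sites$base_quality else rep(".", nrow(sites))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pooldiff",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pools), collapse = "\t"))
  sample_cols <- lapply(pools, function(pool)
    paste0(sites[[paste0("ref_", pool)]], ",", sites[[paste0("alt_", pool)]]))
  body <- do.call(paste, c(list(sites$scaffold, sites$pos, ".", sites$ref,
                                sites$alt, qual, "PASS", ".", "AD"),
                           sample_cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

.read_pool_vcf <- function(path, pools = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(pools)) pools <- colnames(ad)
  missing <- setdiff(pools, colnames(ad))
  if (length(missing) > 0)
    stop("unknown pool column(s) in VCF: ", paste(missing, collapse = ", "))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  out <- data.frame(scaffold = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"])
  for (pool in pools) {
    parts <- strsplit(ad[, pool], ",", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad & !multi))
      stop("malformed AD field at VCF record ", which(bad & !multi)[1])
    parts[bad] <- list(c(NA, NA))
    mat <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
    out[[paste0("ref_", pool)]] <- mat[, 1]
    out[[paste0("alt_", pool)]] <- mat[, 2]
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  out$base_quality <- qual
  if (any(multi)) {
    message("read_pool_sites: dropped ", sum(multi),
            " multi-allelic VCF record(s)")
    out <- out[!multi, ]
    rownames(out) <- NULL
  }
  attr(out, "pools") <- pools
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' Read pooled variant calls (sync or VCF)
#'
#' Single entry point for pooled variant tables. Biallelic normalisation is
#' applied on read: sites with more than one segregating non-reference
#' allele are dropped and counted (`attr(, "n_multiallelic")`). Positions are
#' 1-based throughout.
#'
#' @param path input file.
#' @param format `"sync"` or `"vcf"`.
#' @param pools pool names; for sync these name the count columns in order,
#'   for VCF they select sample columns (default: all samples).
#' @return A pooled site table (see [read_sync()]).
#' @export
read_pool_sites <- function(path, format = c("sync", "vcf"),
                            pools = c("hypo", "hyper", "control")) {
  format <- match.arg(format)
  switch(format,
         sync = read_sync(path, pools = pools),
         vcf = .read_pool_vcf(path, pools = pools))
}

#' SNP filter thresholds for pooled variant tables
#'
#' The four filtering rules applied to pooled SNP calls before any scan: a
#' minimum sequencing depth (2 reads, 3 when the pool shows both alleles,
#' i.e. a heterozygous signal), a maximum depth of `max_depth_factor` times
#' the pool's average depth, a minimum base quality, and exclusion of sites
#' inside the simple-sequence-repeat mask.
#'
#' @param min_depth minimum per-pool depth (reads).
#' @param min_depth_het minimum per-pool depth at sites where that pool has
#'   reads for both alleles; must be `>= min_depth`.
#' @param max_depth_factor maximum depth as a multiple of the pool's mean
#'   depth (computed per pool over the pre-filter sites).
#' @param min_base_quality minimum phred base quality; sites with unknown
#'   (NA) quality pass.
#' @param exclude_ssr drop sites inside the SSR mask.
#' @return A validated `filter_params` list.
#' @export
filter_params <- function(min_depth = 2, min_depth_het = 3,
                          max_depth_factor = 3, min_base_quality = 20,
                          exclude_ssr = TRUE) {
  if (min_depth < 1) stop("invalid filter_params: min_depth must be >= 1")
  if (min_depth_het < min_depth)
    stop("invalid filter_params: min_depth_het must be >= min_depth")
  if (max_depth_factor <= 1)
    stop("invalid filter_params: max_depth_factor must be > 1")
  if (min_base_quality < 0)
    stop("invalid filter_params: min_base_quality must be >= 0")
  structure(list(min_depth = min_depth, min_depth_het = min_depth_het,
                 max_depth_factor = max_depth_factor,
                 min_base_quality = min_base_quality,
                 exclude_ssr = isTRUE(exclude_ssr)),
            class = "filter_params")
}

#' Apply the SNP filtering rules to a pooled site table
#'
#' A site passes when, in every pool, the depth is at least `min_depth`
#' (`min_depth_het` when the pool shows both alleles), at most
#' `max_depth_factor` times that pool's mean pre-filter depth, the site base
#' quality is at least `min_base_quality`, and the site lies outside the SSR
#' mask. Removals are attributed to the first failing rule in the fixed
#' order depth, het-depth, max-depth, quality, SSR, so the report is
#' deterministic and conserves the input count.
#'
#' @param sites a pooled site table.
#' @param params a [filter_params()] object.
#' @param mask optional SSR mask as a `GRanges` (1-based, as returned by
#'   [read_mask()]); mask scaffolds absent from `sites` trigger a warning
#'   and are ignored.
#' @return A list: `sites` (the passing records), and `report` with
#'   `n_input`, `n_pass`, the per-rule `removed` counts and per-pool mean
#'   depths.
#' @export
apply_site_filters <- function(sites, params = filter_params(), mask = NULL) {
  if (is.null(sites) || nrow(sites) == 0)
    stop("apply_site_filters: empty input site table")
  stopifnot(inherits(params, "filter_params"))
  pools <- .site_pools(sites)
  n <- nrow(sites)
  depth <- sapply(pools, function(pool)
    sites[[paste0("ref_", pool)]] + sites[[paste0("alt_", pool)]])
  depth <- matrix(depth, nrow = n)
  het <- sapply(pools, function(pool)
    sites[[paste0("ref_", pool)]] > 0 & sites[[paste0("alt_", pool)]] > 0)
  het <- matrix(het, nrow = n)
  mean_depth <- colMeans(depth)

  fail_depth <- rowSums(depth < params$min_depth) > 0
  fail_het <- rowSums(het & depth < params$min_depth_het) > 0
  fail_max <- rowSums(depth > rep(params$max_depth_factor * mean_depth,
                                  each = n)) > 0
  bq <- if ("base_quality" %in% names(sites)) sites$base_quality else
    rep(NA_real_, n)
  fail_qual <- !is.na(bq) & bq < params$min_base_quality
  if (params$exclude_ssr) {
    if (!is.null(mask) && length(mask) > 0) {
      unknown <- setdiff(unique(as.character(seqnames(mask))),
                         unique(sites$scaffold))
      if (length(unknown) > 0)
        warning("SSR mask scaffold(s) absent from site table, ignored: ",
                paste(unknown, collapse = ", "))
      gr <- GRanges(sites$scaffold, IRanges(sites$pos, width = 1))
      in_ssr <- overlapsAny_int(gr, mask)
    } else if ("in_ssr" %in% names(sites) && is.null(mask)) {
      in_ssr <- sites$in_ssr
    } else {
      in_ssr <- rep(FALSE, n)
    }
  } else {
    in_ssr <- rep(FALSE, n)
  }

  # first failing rule wins the attribution
  reason <- rep(NA_character_, n)
  reason[in_ssr] <- "ssr"
  reason[fail_qual] <- "base_quality"
  reason[fail_max] <- "max_depth"
  reason[fail_het] <- "het_depth"
  reason[fail_depth] <- "min_depth"
  pass <- is.na(reason)
  removed <- c(min_depth = sum(reason == "min_depth", na.rm = TRUE),
               het_depth = sum(reason == "het_depth", na.rm = TRUE),
               max_depth = sum(reason == "max_depth", na.rm = TRUE),
               base_quality = sum(reason == "base_quality", na.rm = TRUE),
               ssr = sum(reason == "ssr", na.rm = TRUE))
  out <- sites[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  list(sites = out,
       report = list(n_input = n, n_pass = sum(pass), removed = removed,
                     mean_depth = setNames(mean_depth, pools)))
}

#' Read gene models from GFF3
#'
#' Imports gene and exon features via rtracklayer (GFF3 1-based inclusive
#' coordinates become 1-based `GRanges` at this boundary, the only conversion
#' point). Exons whose `Parent` is a transcript are mapped up to their gene.
#'
#' @param path GFF3 file.
#' @return A `gene_models` list with `genes` (a `GRanges` with `gene_id`)
#'   and `exons` (a `GRanges` with `gene_id`).
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gff$type)
  genes <- gff[types == "gene"]
  if (length(genes) == 0) stop("no gene features in ", path)
  genes$gene_id <- genes$ID
  tx <- gff[types %in% c("mRNA", "transcript")]
  tx2gene <- setNames(as.character(unlist(tx$Parent)), tx$ID)
  exons <- gff[types == "exon"]
  parent <- as.character(unlist(exons$Parent))
  gene_of <- ifelse(parent %in% names(tx2gene), tx2gene[parent], parent)
  exons$gene_id <- unname(gene_of)
  list(genes = genes[, "gene_id"], exons = exons[, "gene_id"])
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and exon records (one transcript per gene) from the
#' 1-based inclusive tables produced by [simulate_annotation()].
#'
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`.
#' @param exons data.frame with `gene_id`, `scaffold`, `start`, `end`.
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, exons, path) {
  g <- GRanges(genes$scaffold, IRanges(genes$start, genes$end),
               strand = genes$strand)
  g$type <- "gene"; g$ID <- genes$gene_id
  g$Parent <- IRanges::CharacterList(vector("list", nrow(genes)))
  tx <- g
  tx$type <- "mRNA"; tx$ID <- paste0(genes$gene_id, ".t1")
  tx$Parent <- IRanges::CharacterList(as.list(genes$gene_id))
  estrand <- genes$strand[match(exons$gene_id, genes$gene_id)]
  e <- GRanges(exons$scaffold, IRanges(exons$start, exons$end),
               strand = estrand)
  e$type <- "exon"; e$ID <- NA_character_
  e$Parent <- IRanges::CharacterList(as.list(paste0(exons$gene_id, ".t1")))
  all <- c(g, tx, e)
  all <- all[order(as.character(seqnames(all)), start(all),
                   match(all$type, c("gene", "mRNA", "exon")))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read an interval mask from BED
#'
#' BED's 0-based half-open intervals become 1-based `GRanges` at this
#' boundary (rtracklayer does the conversion), so `scaffold1 99 200` covers
#' 1-based positions 100..200.
#'
#' @param path BED file.
#' @return A `GRanges`.
#' @export
read_mask <- function(path) {
  if (file.size(path) == 0) return(GRanges())
  rtracklayer::import(path, format = "BED")
}

#' Derive intron intervals from gene models
#'
#' Introns are the per-gene set difference between the gene span and its
#' exons.
#'
#' @param models a `gene_models` list from [read_gene_models()].
#' @return A `GRanges` of introns with a `gene_id` column.
#' @export
gene_introns <- function(models) {
  out <- GRanges()
  for (gid in models$genes$gene_id) {
    span <- models$genes[models$genes$gene_id == gid]
    ex <- models$exons[models$exons$gene_id == gid]
    intr <- GenomicRanges::setdiff(span, ex, ignore.strand = TRUE)
    if (length(intr) > 0) {
      intr$gene_id <- gid
      out <- c(out, intr)
    }
  }
  out
}
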