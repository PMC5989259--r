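#' Configuration for a full differentiation scan
#'
#' Validates paths and parameters before any stage runs. The comparisons
#' are pairwise: each treatment pool against the control pool, one
#' differentiated set per treatment.
#'
#' @param sites path to the pooled variant table.
#' @param format `"sync"` or `"vcf"`.
#' @param gff path to the gene models (GFF3).
#' @param mask path to the SSR mask (BED), or `NULL` for no mask.
#' @param de_genes path to the DE gene list (one ID per line), or `NULL` to
#'   skip the integration stage.
#' @param term_map path to a two-column gene-to-term table (TSV with
#'   header), or `NULL` to skip enrichment.
#' @param pools pool names in the variant table.
#' @param control name of the control pool.
#' @param pool_size diploid individuals per pool.
#' @param afd_threshold AFD selection threshold (default 0.6).
#' @param window_size F_ST window size in bp (default 1000).
#' @param top_fraction fraction of ranked windows selected (default 0.01).
#' @param flank_bp flank around outlier windows for gene extraction
#'   (default 5000).
#' @param afd_flank_bp flank for AFD gene assignment (default 0).
#' @param estimator `"hudson"` or `"nei"`.
#' @param filter a [filter_params()] object.
#' @return A validated `scan_config` list.
#' @export
scan_config <- function(sites, format = c("sync", "vcf"), gff,
                        mask = NULL, de_genes = NULL, term_map = NULL,
                        pools = c("hypo", "hyper", "control"),
                        control = "control", pool_size = 46,
                        afd_threshold = 0.6, window_size = 1000,
                        top_fraction = 0.01, flank_bp = 5000,
                        afd_flank_bp = 0,
                        estimator = c("hudson", "nei"),
                        filter = filter_params()) {
  format <- match.arg(format)
  estimator <- match.arg(estimator)
  for (p in c(sites, gff, mask, de_genes, term_map))
    if (!is.null(p) && !file.exists(p))
      stop("config error: file not found: ", p)
  if (!control %in% pools)
    stop("config error: control pool '", control, "' not among pools")
  if (length(pools) < 2) stop("config error: need at least two pools")
  if (afd_threshold < 0 || afd_threshold > 1)
    stop("config error: afd_threshold must be in [0, 1]")
  if (window_size < 1) stop("config error: window_size must be >= 1")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("config error: top_fraction must be in (0, 1]")
  if (flank_bp < 0 || afd_flank_bp < 0)
    stop("config error: flanks must be >= 0")
  if (pool_size < 1) stop("config error: pool_size must be >= 1")
  stopifnot(inherits(filter, "filter_params"))
  structure(list(sites = sites, format = format, gff = gff, mask = mask,
                 de_genes = de_genes, term_map = term_map, pools = pools,
                 control = control, pool_size = pool_size,
                 afd_threshold = afd_threshold, window_size = window_size,
                 top_fraction = top_fraction, flank_bp = flank_bp,
                 afd_flank_bp = afd_flank_bp, estimator = estimator,
                 filter = filter),
            class = "scan_config")
}

#' Run the full differentiation scan
#'
#' Executes filter -> AFD scan -> windowed F_ST scan -> gene mapping ->
#' evidence integration -> term enrichment for every treatment-vs-control
#' comparison, writing each stage's table under `outdir` together with a
#' JSON manifest (configuration, input checksums, per-stage record counts).
#' The pipeline is a pure function of its inputs and configuration: a rerun
#' with identical inputs produces byte-identical outputs. On a stage
#' failure the partial outputs are retained and the manifest records the
#' failed stage.
#'
#' @param config a [scan_config()] object.
#' @param outdir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list of in-memory results per comparison plus the
#'   manifest.
#' @export
run_scan_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "scan_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(
    config = config[setdiff(names(config), "filter")],
    filter = unclass(config$filter),
    inputs = as.list(md5sum(unlist(config[c("sites", "gff", "mask",
                                            "de_genes", "term_map")],
                                   use.names = TRUE))),
    stages = list(), status = "running")
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      .write_manifest(manifest, outdir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  # load
  inputs <- stage("load", function() {
    sites <- read_pool_sites(config$sites, format = config$format,
                             pools = config$pools)
    models <- read_gene_models(config$gff)
    mask <- if (!is.null(config$mask)) read_mask(config$mask) else NULL
    de <- if (!is.null(config$de_genes)) readLines(config$de_genes) else NULL
    terms <- if (!is.null(config$term_map))
      read.table(config$term_map, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE) else NULL
    list(sites = sites, models = models, mask = mask, de = de, terms = terms)
  })
  manifest$stages$load <- list(n_sites = nrow(inputs$sites),
                               n_multiallelic =
                                 attr(inputs$sites, "n_multiallelic"),
                               n_genes = length(inputs$models$genes))
  say("loaded ", nrow(inputs$sites), " sites, ",
      length(inputs$models$genes), " genes")

  # filter
  filt <- stage("filter", function()
    apply_site_filters(inputs$sites, config$filter, mask = inputs$mask))
  manifest$stages$filter <- filt$report
  write.table(filt$sites, file.path(outdir, "filtered_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("filter: ", filt$report$n_pass, "/", filt$report$n_input,
      " sites pass")

  treatments <- setdiff(config$pools, config$control)
  results <- list()
  background <- sort(inputs$models$genes$gene_id)
  for (tr in treatments) {
    cmp <- paste0(tr, "_vs_", config$control)

    afd <- stage(paste0("afd[", cmp, "]"), function()
      scan_afd(filt$sites, tr, config$control,
               threshold = config$afd_threshold))
    write.table(afd, file.path(outdir, paste0("afd_", cmp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    ag <- stage(paste0("afd_genes[", cmp, "]"), function()
      afd_genes(afd, inputs$models, flank_bp = config$afd_flank_bp))

    wins <- stage(paste0("fst[", cmp, "]"), function() {
      comp <- fst_components(filt$sites, tr, config$control,
                             pool_size = config$pool_size,
                             estimator = config$estimator)
      w <- window_fst(comp, window_size = config$window_size)
      select_top_windows(w, fraction = config$top_fraction)
    })
    wtab <- wins
    wtab$fst_display <- pmax(0, wtab$fst)  # raw fst kept for ranking
    write.table(wtab, file.path(outdir, paste0("windows_", cmp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    outw <- wins[wins$is_outlier, , drop = FALSE]
    writeLines(paste(outw$scaffold, outw$start, outw$end, sep = "\t"),
               file.path(outdir, paste0("outlier_windows_", cmp, ".bed")))

    fg <- stage(paste0("map_genes[", cmp, "]"), function()
      genes_overlapping_windows(wins, inputs$models,
                                flank_bp = config$flank_bp))

    merged <- stage(paste0("integrate[", cmp, "]"), function()
      merge_differentiated(ag$gene_ids, fg, label = cmp))
    write.table(merged, file.path(outdir, paste0("differentiated_genes_",
                                                 cmp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    venn <- NULL; enr <- NULL
    if (!is.null(inputs$de)) {
      venn <- stage(paste0("venn[", cmp, "]"), function()
        venn3(ag$gene_ids, fg, inputs$de))
      write.table(data.frame(region = names(venn$counts),
                             count = unname(venn$counts)),
                  file.path(outdir, paste0("venn_", cmp, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(venn$candidates,
                 file.path(outdir, paste0("candidates_", cmp, ".txt")))
      if (!is.null(inputs$terms) && length(venn$candidates) > 0) {
        enr <- stage(paste0("enrich[", cmp, "]"), function()
          enrich_terms(venn$candidates, background, inputs$terms))
        write.table(enr, file.path(outdir, paste0("enrichment_", cmp,
                                                  ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    manifest$stages[[cmp]] <- list(
      n_afd_snps = sum(afd$pass), n_afd_genes = length(ag$gene_ids),
      n_windows_ranked = sum(!is.na(wins$rank)),
      n_outlier_windows = sum(wins$is_outlier),
      n_fst_genes = length(fg),
      n_differentiated_genes = nrow(merged),
      n_candidates = if (!is.null(venn)) length(venn$candidates) else NA)
    say(cmp, ": ", sum(afd$pass), " AFD SNPs, ",
        sum(wins$is_outlier), " outlier windows, ",
        nrow(merged), " differentiated genes")
    results[[cmp]] <- list(afd = afd, afd_genes = ag, windows = wins,
                           fst_genes = fg, merged = merged, venn = venn,
                           enrichment = enr)
  }
  manifest$status <- "ok"
  .write_manifest(manifest, outdir)
  invisible(c(results, list(manifest = manifest,
                            filter_report = filt$report)))
}

.write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, null = "null")
}
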