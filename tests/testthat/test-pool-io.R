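test_that("sync parsing handles direct, boundary and malformed records", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("scaffold1\t10\tA\t0:0:10:0:0:0",
               "scaffold1\t20\tG\t5:0:0:12:0:0"), path)
  sites <- read_sync(path, pools = "p1")
  expect_equal(sites$alt[1], "C")
  expect_equal(sites$ref_p1[1], 0L)
  expect_equal(sites$alt_p1[1], 10L)
  expect_equal(sites$ref_p1[2], 12L)  # ref G sits in the 4th slot
  expect_equal(sites$alt_p1[2], 5L)   # alt A
  expect_true(all(is.na(sites$base_quality)))

  bad <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("scaffold1\t10\tA\t0:0:10:0:0:0",
               "scaffold1\t20\tA\t0:0:10:0"), bad)
  expect_error(read_sync(bad, pools = "p1"), "line 2")
})

test_that("tri-allelic sync records are dropped and counted", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("scaffold1\t10\tA\t2:5:9:0:0:0",    # T and C both segregate
               "scaffold1\t20\tA\t3:0:14:0:0:0"), path)
  expect_message(sites <- read_sync(path, pools = "p1"), "multi-allelic")
  expect_equal(nrow(sites), 1)
  expect_equal(attr(sites, "n_multiallelic"), 1L)
  expect_equal(sites$pos, 20L)
})

test_that("site tables round-trip through sync with all fields intact", {
  p <- tiny_params(seed = 2)
  truth <- simulate_population_frequencies(p)
  sites <- simulate_pool_reads(truth, p)
  path <- withr::local_tempfile(fileext = ".sync")
  write_sync(sites, path)
  rt <- read_sync(path)
  seg <- sites$alt_hypo + sites$alt_hyper + sites$alt_control > 0
  for (cn in names(rt))
    expect_equal(rt[[cn]][seg], sites[[cn]][seg], label = cn)
})

test_that("VCF AD fields parse and multi-allelic records are dropped", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "hypo", "control", sep = "\t"),
    "scaffold1\t100\t.\tA\tC\t30\tPASS\t.\tAD\t12,8\t20,0",
    "scaffold1\t200\t.\tA\tC,G\t30\tPASS\t.\tAD\t5,5,5\t15,0,0",
    "scaffold1\t300\t.\tG\tT\t35\tPASS\t.\tAD\t0,17\t9,9"), path)
  expect_message(
    sites <- read_pool_sites(path, format = "vcf",
                             pools = c("hypo", "control")),
    "multi-allelic")
  expect_equal(nrow(sites), 2)
  expect_equal(sites$ref_hypo[1], 12L)
  expect_equal(sites$alt_hypo[1], 8L)
  expect_equal(sites$alt_control[2], 9L)
  expect_equal(attr(sites, "n_multiallelic"), 1L)
  expect_error(read_pool_sites(path, format = "vcf", pools = "nosuch"),
               "unknown pool")
})

test_that("sync and VCF writers agree on the same site table", {
  p <- tiny_params(seed = 23)
  truth <- simulate_population_frequencies(p)
  sites <- simulate_pool_reads(truth, p)
  sp <- withr::local_tempfile(fileext = ".sync")
  vp <- withr::local_tempfile(fileext = ".vcf")
  write_sync(sites, sp)
  write_pool_vcf(sites, vp)
  a <- read_pool_sites(sp, format = "sync")
  b <- read_pool_sites(vp, format = "vcf")
  seg <- sites$alt_hypo + sites$alt_hyper + sites$alt_control > 0
  for (cn in c("scaffold", "pos", "ref_hypo", "alt_hypo", "ref_control",
               "alt_control"))
    expect_equal(a[[cn]][seg], b[[cn]][seg], label = cn)
})

test_that("the worked filter fixture removes one site per rule", {
  fx <- filter_fixture()
  res <- apply_site_filters(fx$sites, filter_params(), mask = fx$mask)
  expect_equal(res$report$n_pass, 1L)
  expect_equal(res$sites$pos, 500)
  expect_equal(unname(res$report$removed),
               c(1L, 1L, 1L, 0L, 1L))  # depth, het, max-depth, quality, SSR
  expect_equal(res$report$n_input,
               res$report$n_pass + sum(res$report$removed))
})

test_that("vacuous thresholds make the filter the identity", {
  fx <- filter_fixture()
  lax <- filter_params(min_depth = 1, min_depth_het = 1,
                       max_depth_factor = 1e9, min_base_quality = 0,
                       exclude_ssr = FALSE)
  res <- apply_site_filters(fx$sites, lax)
  expect_equal(nrow(res$sites), nrow(fx$sites))
  expect_true(all(res$report$removed == 0))
  expect_error(apply_site_filters(fx$sites[0, ], lax), "empty")
})

test_that("filter report conserves counts and thresholds act monotonically", {
  for (seed in 1:4) {
    sites <- random_sites(60, seed = seed)
    mask <- GenomicRanges::GRanges("scaffold1",
                                   IRanges::IRanges(1, 10000))
    base <- filter_params(min_depth = 8, min_depth_het = 10,
                          max_depth_factor = 1.5, min_base_quality = 25)
    res <- apply_site_filters(sites, base, mask = mask)
    expect_equal(res$report$n_input,
                 res$report$n_pass + sum(res$report$removed))
    # relaxing any one threshold never loses passing sites
    relaxed <- list(
      filter_params(min_depth = 1, min_depth_het = 10,
                    max_depth_factor = 1.5, min_base_quality = 25),
      filter_params(min_depth = 8, min_depth_het = 8,
                    max_depth_factor = 1.5, min_base_quality = 25),
      filter_params(min_depth = 8, min_depth_het = 10,
                    max_depth_factor = 50, min_base_quality = 25),
      filter_params(min_depth = 8, min_depth_het = 10,
                    max_depth_factor = 1.5, min_base_quality = 0),
      filter_params(min_depth = 8, min_depth_het = 10,
                    max_depth_factor = 1.5, min_base_quality = 25,
                    exclude_ssr = FALSE))
    for (fp in relaxed) {
      r2 <- apply_site_filters(sites, fp, mask = mask)
      expect_gte(r2$report$n_pass, res$report$n_pass)
    }
  }
})

test_that("a mask on an unknown scaffold warns and is ignored", {
  fx <- filter_fixture()
  mask <- GenomicRanges::GRanges("scaffoldX", IRanges::IRanges(1, 1000))
  expect_warning(res <- apply_site_filters(fx$sites, filter_params(),
                                           mask = mask),
                 "scaffoldX")
  expect_equal(unname(res$report$removed["ssr"]), 0L)
})

test_that("GFF and BED coordinates convert once at the file boundary", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "scaffold1\ttest\tgene\t101\t200\t.\t+\t.\tID=gA",
               "scaffold1\ttest\tmRNA\t101\t200\t.\t+\t.\tID=gA.t1;Parent=gA",
               "scaffold1\ttest\texon\t101\t140\t.\t+\t.\tParent=gA.t1",
               "scaffold1\ttest\texon\t171\t200\t.\t+\t.\tParent=gA.t1"), gff)
  models <- read_gene_models(gff)
  # 1-based inclusive gene 101..200 == half-open [100, 200)
  expect_equal(GenomicRanges::start(models$genes), 101)
  expect_equal(GenomicRanges::end(models$genes), 200)
  expect_equal(models$exons$gene_id, c("gA", "gA"))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("scaffold1\t99\t200", bed)
  mask <- read_mask(bed)
  expect_equal(GenomicRanges::start(mask), 100)
  expect_equal(GenomicRanges::end(mask), 200)

  # two exons leave exactly one intron between them
  intr <- gene_introns(models)
  expect_equal(length(intr), 1)
  expect_equal(GenomicRanges::start(intr), 141)
  expect_equal(GenomicRanges::end(intr), 170)
})

test_that("gene models round-trip through the GFF3 writer", {
  p <- tiny_params(seed = 31)
  truth <- simulate_population_frequencies(p)
  ann <- simulate_annotation(truth, p)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(ann$genes, ann$exons, path)
  models <- read_gene_models(path)
  expect_setequal(models$genes$gene_id, ann$genes$gene_id)
  ord <- match(ann$genes$gene_id, models$genes$gene_id)
  expect_equal(GenomicRanges::start(models$genes)[ord], ann$genes$start)
  expect_equal(GenomicRanges::end(models$genes)[ord], ann$genes$end)
  expect_equal(length(models$exons), nrow(ann$exons))
})
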