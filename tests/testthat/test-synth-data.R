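test_that("parameter validation rejects inconsistent settings", {
  expect_error(sim_params(background_divergence = -0.1), "background_divergence")
  expect_error(sim_params(background_divergence = 0.5, outlier_divergence = 0.3),
               "outlier_divergence")
  expect_error(sim_params(outlier_divergence = 1), "outlier_divergence")
  expect_error(sim_params(n_snps = 10, n_outlier_loci = 50), "sim_params")
  expect_error(sim_params(n_snps = 0), "n_snps")
  expect_error(sim_params(de_overlap_fraction = 1.5), "de_overlap_fraction")
  expect_error(sim_params(ssr_fraction = 1), "ssr_fraction")
  expect_s3_class(tiny_params(), "sim_params")
})

test_that("zero divergence collapses background frequencies to the ancestral value", {
  p <- tiny_params(background_divergence = 0, n_outlier_loci = 0,
                   n_outlier_regions = NULL)
  truth <- simulate_population_frequencies(p)
  expect_equal(truth$p_hypo, truth$p_anc)
  expect_equal(truth$p_hyper, truth$p_anc)
  expect_equal(truth$p_control, truth$p_anc)
})

test_that("truth table bookkeeping: outlier count, clustering, frequency bounds", {
  p <- tiny_params(n_outlier_loci = 10, n_outlier_regions = 2)
  truth <- simulate_population_frequencies(p)
  expect_equal(nrow(truth), p$n_snps)
  expect_equal(sum(truth$is_outlier), 10)
  expect_true(all(truth$pos >= 1 & truth$pos <= p$scaffold_length))
  fr <- unlist(truth[c("p_anc", "p_hypo", "p_hyper", "p_control")])
  expect_true(all(fr >= 0 & fr <= 1))
  expect_false(any(duplicated(paste(truth$scaffold, truth$pos))))
  # each planted region sits inside a single 1-kb tile
  out <- truth[truth$is_outlier, ]
  win <- paste(out$scaffold, (out$pos - 1) %/% 1000)
  expect_lte(length(unique(win)), p$n_outlier_regions)
  # planted displacement honours the outlier_divergence floor
  expect_true(all(abs(out$p_hypo - out$p_control) >= p$outlier_divergence - 0.01))
})

test_that("background loci calibrate the Hudson estimator to the Balding-Nichols divergence", {
  # closed-form expectation: E[(p1-p2)^2] = 2 F p q and
  # E[p1(1-p2) + p2(1-p1)] = 2 p q, so the ratio of sums estimates F
  p <- sim_params(n_scaffolds = 10, scaffold_length = 1e5, n_snps = 10000,
                  background_divergence = 0.1, n_outlier_loci = 0,
                  n_genes = 10, seed = 11)
  truth <- simulate_population_frequencies(p)
  sites <- simulate_pool_reads(truth, p)
  comp <- fst_components(sites, "hypo", "control", pool_size = p$pool_size)
  ratio_of_sums <- sum(comp$numerator) / sum(comp$denominator)
  expect_lt(abs(ratio_of_sums - 0.1), 0.02)
})

test_that("pool reads respect depth and boundary-frequency constraints", {
  p <- tiny_params(seed = 3)
  truth <- simulate_population_frequencies(p)
  truth$p_hypo[] <- 0  # monomorphic reference in one pool
  sites <- simulate_pool_reads(truth, p)
  expect_true(all(sites$alt_hypo == 0))
  expect_true(all(sites$ref_hypo + sites$alt_hypo >= 1))

  # depth: mean within +-1 of the target at 10,000 sites
  p2 <- sim_params(n_scaffolds = 10, scaffold_length = 1e5, n_snps = 10000,
                   n_outlier_loci = 0, n_genes = 10, mean_depth = 35,
                   seed = 5)
  t2 <- simulate_population_frequencies(p2)
  s2 <- simulate_pool_reads(t2, p2)
  depth <- s2$ref_control + s2$alt_control
  expect_lt(abs(mean(depth) - 35), 1)
  expect_gte(min(depth), 1)

  # a pool of one diploid collapses to genotype doses {0, 1/2, 1}: at a
  # true frequency of 1/2 about a quarter of sites are fixed for each
  # allele, and (at depth ~35) a dose-1/2 site essentially never is
  p3 <- tiny_params(pool_size = 1, seed = 9)
  t3 <- simulate_population_frequencies(p3)
  t3$p_hypo[] <- 0.5
  s3 <- simulate_pool_reads(t3, p3)
  expect_lt(abs(mean(s3$alt_hypo == 0) - 0.25), 0.1)
  expect_lt(abs(mean(s3$ref_hypo == 0) - 0.25), 0.1)
})

test_that("read counts conserve depth at every site and pool", {
  p <- tiny_params(seed = 13)
  truth <- simulate_population_frequencies(p)
  sites <- simulate_pool_reads(truth, p)
  for (pool in attr(sites, "pools")) {
    depth <- sites[[paste0("ref_", pool)]] + sites[[paste0("alt_", pool)]]
    expect_true(all(depth >= 1))
    expect_true(all(sites[[paste0("ref_", pool)]] >= 0 &
                      sites[[paste0("alt_", pool)]] >= 0))
  }
})

test_that("observed pool frequencies are unbiased and converge for deep, large pools", {
  p <- sim_params(n_scaffolds = 2, scaffold_length = 5e4, n_snps = 500,
                  n_outlier_loci = 0, n_genes = 5, mean_depth = 10000,
                  seed = 21)
  truth <- simulate_population_frequencies(p)
  sites <- simulate_pool_reads(truth, p)
  obs <- sites$alt_control / (sites$ref_control + sites$alt_control)
  expect_lt(abs(mean(obs - truth$p_control)), 0.005)
  # the individual-sampling stage keeps per-locus variance at finite pool
  # size; with a large pool as well, each locus converges
  p2 <- sim_params(n_scaffolds = 2, scaffold_length = 5e4, n_snps = 200,
                   n_outlier_loci = 0, n_genes = 5, mean_depth = 10000,
                   pool_size = 5000, seed = 22)
  t2 <- simulate_population_frequencies(p2)
  s2 <- simulate_pool_reads(t2, p2)
  obs2 <- s2$alt_hypo / (s2$ref_hypo + s2$alt_hypo)
  expect_lt(max(abs(obs2 - t2$p_hypo)), 0.02)
})

test_that("planted loci are more differentiated than background loci", {
  p <- sim_params(n_scaffolds = 10, scaffold_length = 1e5, n_snps = 2000,
                  n_outlier_loci = 100, n_outlier_regions = 20,
                  n_genes = 40, seed = 17)
  truth <- simulate_population_frequencies(p)
  sites <- simulate_pool_reads(truth, p)
  comp <- fst_components(sites, "hypo", "control", pool_size = p$pool_size)
  key <- paste(comp$scaffold, comp$pos)
  tkey <- paste(truth$scaffold, truth$pos)
  is_out <- truth$is_outlier[match(key, tkey)]
  fst_site <- comp$numerator / comp$denominator  # NaN at doubly fixed sites
  expect_gt(mean(fst_site[is_out], na.rm = TRUE),
            mean(fst_site[!is_out], na.rm = TRUE))
})

test_that("annotation generator honours its contracts", {
  p <- tiny_params(seed = 7)
  truth <- simulate_population_frequencies(p)
  ann <- simulate_annotation(truth, p)
  expect_equal(nrow(ann$genes), p$n_genes)
  expect_true(all(ann$genes$start >= 1 & ann$genes$end <= p$scaffold_length))
  # genes never overlap on a scaffold
  for (sc in unique(ann$genes$scaffold)) {
    g <- ann$genes[ann$genes$scaffold == sc, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # exons within their gene span
  sp <- ann$genes[match(ann$exons$gene_id, ann$genes$gene_id), ]
  expect_true(all(ann$exons$start >= sp$start & ann$exons$end <= sp$end))
  # every outlier-containing gene is on the DE list at full overlap
  expect_true(all(ann$gene_truth$gene_id[ann$gene_truth$contains_outlier]
                  %in% ann$de_genes))
  # planted regions always land in a host gene
  expect_equal(sum(ann$gene_truth$contains_outlier), p$n_outlier_regions)

  # no mask when the SSR fraction is zero
  ann0 <- simulate_annotation(truth, tiny_params(ssr_fraction = 0, seed = 7))
  expect_equal(length(ann0$mask), 0)
})

test_that("identical parameters and seed give byte-identical study files", {
  p <- tiny_params(seed = 19)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_poolseq_study(p, d1)
  s2 <- simulate_poolseq_study(p, d2)
  for (f in names(s1$paths)) {
    expect_equal(unname(tools::md5sum(s1$paths[[f]])),
                 unname(tools::md5sum(s2$paths[[f]])), label = f)
  }
})

test_that("phenotype tables have the declared shape and sampling behaviour", {
  ph <- simulate_phenotypes(n_per_group = 3, seed = 4)
  expect_equal(nrow(ph), 4 * 3 * 3)  # 4 traits x 3 groups x 3 replicates
  expect_true(all(table(ph$trait) == 9))
  rates <- compute_rates(ph)
  cnt <- rates$trait != "growth"
  expect_true(all(rates$rate[cnt] >= 0 & rates$rate[cnt] <= 1))

  # survival near 0.5 within binomial sampling error at n = 400
  m <- matrix(0.5, nrow = 4, ncol = 3,
              dimnames = list(c("production", "survival", "growth",
                                "adhesive"), c("g1", "g2", "g3")))
  ph2 <- simulate_phenotypes(m, group_sds = 0, n_per_group = 10, seed = 8,
                             denominators = c(production = 400,
                                              survival = 400,
                                              adhesive = 400))
  r2 <- compute_rates(ph2)
  surv <- r2$rate[r2$trait == "survival"]
  expect_lt(abs(mean(surv) - 0.5), 3 * sqrt(0.25 / 400) / sqrt(30) * 10)
  # equal group means: no group effect detectable
  an <- one_way_anova(surv, r2$group[r2$trait == "survival"])
  expect_gte(an$p, 0.05)
})
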