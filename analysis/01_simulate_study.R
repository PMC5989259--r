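#!/usr/bin/env Rscript
# Stage 1: generate the synthetic pooled-resequencing study.
#
# Three pools (hyposalinity-selected, hypersalinity-selected, control) of 46
# diploids at ~35x mean depth over a 10-scaffold x 100-kb toy genome with
# 5,000 SNPs. Fifty outlier loci are planted as ten linked sweep regions
# targeting the hyposalinity pool (displacement floor 0.6 over background
# divergence 0.05), each inside a host gene, with a fully overlapping DE
# list - so every downstream stage has a known truth to recover.

library(pooldiff)

out <- "results/study"
params <- sim_params(seed = 101)
print(params)
study <- simulate_poolseq_study(params, file.path(out, "sim"))

truth <- study$truth
cat("\nwrote", length(study$paths), "files under", file.path(out, "sim"), "\n")
cat("planted loci:", sum(truth$is_outlier), "in",
    params$n_outlier_regions, "regions;",
    "outlier-containing genes:",
    sum(study$annotation$gene_truth$contains_outlier), "\n")
cat("true |AFD| at planted loci: median",
    round(median(abs(truth$p_hypo - truth$p_control)[truth$is_outlier]), 3),
    "\n")
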