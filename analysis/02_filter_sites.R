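#!/usr/bin/env Rscript
# Stage 2: read the pooled variant table and apply the SNP filters
# (depth >= 2, >= 3 at heterozygous signal, <= 3x mean depth, base quality
# >= 20, outside the SSR mask), attributing each removal to its first
# failing rule.

library(pooldiff)

sim <- "results/study/sim"
sites <- read_pool_sites(file.path(sim, "pools.sync"), format = "sync")
mask <- read_mask(file.path(sim, "ssr_mask.bed"))
res <- apply_site_filters(sites, filter_params(), mask = mask)

dir.create("results/study", showWarnings = FALSE, recursive = TRUE)
write.table(res$sites, "results/study/filtered_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
rep <- res$report
cat("sites in:", rep$n_input, " passing:", rep$n_pass, "\n")
cat("removed per rule:\n")
print(rep$removed)
cat("per-pool mean depth:\n")
print(round(rep$mean_depth, 2))
stopifnot(rep$n_input == rep$n_pass + sum(rep$removed))
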