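#!/usr/bin/env Rscript
# Stage 4: windowed F_ST scan. Hudson-type site components are summed over
# non-overlapping 1-kb windows (ratio of sums); windows in the highest 1%
# of the ranking are the outlier windows.

library(pooldiff)

sim <- "results/study/sim"
sites <- read_pool_sites(file.path(sim, "pools.sync"), format = "sync")
mask <- read_mask(file.path(sim, "ssr_mask.bed"))
sites <- apply_site_filters(sites, filter_params(), mask = mask)$sites

for (treatment in c("hypo", "hyper")) {
  comp <- fst_components(sites, treatment, "control", pool_size = 46,
                         estimator = "hudson")
  wins <- select_top_windows(window_fst(comp, window_size = 1000),
                             fraction = 0.01)
  wins$fst_display <- pmax(0, wins$fst)
  write.table(wins, sprintf("results/study/windows_%s_vs_control.tsv",
                            treatment),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- wins[wins$is_outlier, ]
  writeLines(paste(sel$scaffold, sel$start, sel$end, sep = "\t"),
             sprintf("results/study/outlier_windows_%s_vs_control.bed",
                     treatment))
  cat(sprintf("%s vs control: %d ranked windows, top 1%% = %d selected, max window F_ST %.3f\n",
              treatment, sum(!is.na(wins$rank)), sum(wins$is_outlier),
              max(wins$fst, na.rm = TRUE)))
}
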