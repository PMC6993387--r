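#!/usr/bin/env Rscript
# Stage 2: counts -> frequencies -> anchored fitness scores.
#
# Normalizes counts by depth, filters against the wildtype-control
# threshold (mean + 3 SD), collapses equivalent codons per amino-acid
# change, subtracts background, computes per-replicate enrichment ratios
# anchored on the nonsense/synonymous medians, regularizes errors, merges
# the two low-B6 screens, and applies the well-measured filters
# (pre-selection frequency > 0.005%, SE < 0.2).

suppressMessages(library(cbsmap))

counts <- read_count_table("results/counts.tsv")
truth <- read.delim("results/truth.tsv")

adj <- prepare_frequencies(counts)
low <- combine_low_b6(
  score_map(adj, "select_low_0"), score_map(adj, "select_low_1")
)
high <- score_map(adj, "select_high")
flt_low <- well_measured_filter(low)
flt_high <- well_measured_filter(high)

write_map(flt_low$kept, "results/map_low.tsv")
write_map(flt_low$dropped, "results/map_low_dropped.tsv")
write_map(flt_high$kept, "results/map_high.tsv")
write_map(flt_high$dropped, "results/map_high_dropped.tsv")

for (cond in c("low", "high")) {
  kept <- if (cond == "low") flt_low$kept else flt_high$kept
  truth_col <- paste0("fitness_", cond)
  r <- cor(kept$score, truth$fitness_low[match(kept$hgvs, truth$hgvs)])
  if (cond == "high") {
    r <- cor(kept$score, truth$fitness_high[match(kept$hgvs, truth$hgvs)])
  }
  cat(sprintf(
    paste0(
      "%s-B6 map: %d well-measured variants (%d dropped for imputation), ",
      "median syn score %.3f, median nonsense %.3f, r(truth) = %.3f\n"
    ),
    cond, nrow(kept),
    nrow(if (cond == "low") flt_low$dropped else flt_high$dropped),
    median(kept$score[kept$class == "synonymous"]),
    median(kept$score[kept$class == "nonsense"]), r
  ))
}
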