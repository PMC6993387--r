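#!/usr/bin/env Rscript
# Stage 3: delta scores and FDR-controlled calls.
#
# Deleterious variants: synonymous fitness scores form the empirical null;
# a variant is called when the upper 95% CI bound of its fitness falls
# below the FDR-5% threshold. B6-remediable variants: among the deleterious,
# the nonsense delta-score distribution forms the null and the lower CI
# bound of the delta score must clear the FDR-5% threshold.

suppressMessages(library(cbsmap))

low <- read_map("results/map_low.tsv")
high <- read_map("results/map_high.tsv")
truth <- read.delim("results/truth.tsv")

cls <- classify_variants(low, high, q = 0.05)
write_calls(cls, "results/calls.tsv")

calls <- cls$calls
ti <- match(calls$hgvs, truth$hgvs)
del <- calls$deleterious
rem <- !is.na(calls$remediable) & calls$remediable
cat(sprintf(
  "re-derived thresholds: fitness %.3f (synonymous null), delta %s (nonsense null)\n",
  cls$fdr_threshold_fitness,
  ifelse(is.na(cls$fdr_threshold_delta), "none",
    sprintf("%.3f", cls$fdr_threshold_delta)
  )
))
cat(sprintf(
  "deleterious: %d calls / %d missense; %.1f%% of calls are truly damaging\n",
  sum(del), nrow(calls), 100 * mean(truth$damaging[ti][del])
))
cat(sprintf(
  "remediable: %d calls; %d truly remediable variants among the deleterious\n",
  sum(rem), sum(truth$remediable[ti] & del, na.rm = TRUE)
))
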