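#!/usr/bin/env Rscript
# Stage 4: impute missing scores and refine the measured ones.
#
# Gradient-boosted trees over intrinsic map features (confidence-weighted
# same-position averages, 3- and 4-nearest BLOSUM62 neighbor averages,
# residue physicochemistry), evaluated by 10-fold cross-validation.
# Variants dropped by the well-measured filter are imputed; measured scores
# are refined by inverse-variance averaging with their held-out
# predictions.

suppressMessages(library(cbsmap))

for (cond in c("low", "high")) {
  kept <- read_map(sprintf("results/map_%s.tsv", cond))
  dropped <- read_map(sprintf("results/map_%s_dropped.tsv", cond))
  imp <- impute_map(kept, targets = dropped, folds = 10, seed = 2026)
  out <- imp$refined
  names(out)[names(out) == "hgvs"] <- "hgvs_pro"
  out$condition <- cond
  write.table(out, sprintf("results/refined_%s.tsv", cond),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  prov <- table(imp$refined$provenance)
  cat(sprintf(
    paste0(
      "%s-B6: CV rmsd %.3f, CV pearson %.3f over %d folds; ",
      "map of %d variants (%s)\n"
    ),
    cond, imp$model$rmsd, imp$model$pearson_r, nrow(imp$model$cv),
    nrow(imp$refined),
    paste(sprintf("%d %s", prov, names(prov)), collapse = ", ")
  ))
}
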