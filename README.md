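# cbsmap

Analysis pipeline for pooled yeast-complementation screens of human
cystathionine beta-synthase (CBS) variants — the enzyme whose deficiency
causes classical homocystinuria. From multiplexed variant count tables the
package computes fitness and vitamin-B6-remediability scores, makes
FDR-controlled calls against empirical nulls, imputes and refines complete
variant effect maps, converts scores into pathogenicity evidence, and
predicts diploid patient phenotypes from genotypes. A synthetic-data
generator reproduces the whole data-generating process (mutagenized clone
library → pooled selection → sequencing) with known ground truth, so every
stage is testable offline.

It is written for analysts of multiplexed assays of variant effect (MAVE /
deep mutational scanning) who have per-variant counts per condition and
replicate, and for anyone who wants a worked, tested reference
implementation of the scoring and classification procedures.

## The model in brief

* **Fitness score.** After depth normalization, wildtype-control filtering
  (mean + 3 SD), codon collapsing and background subtraction, each variant
  gets an enrichment ratio Φ = f_selective / f_nonselective and an anchored
  score **s = ln(Φ/Φ_STOP) / ln(Φ_SYN/Φ_STOP)**, where Φ_STOP and Φ_SYN are
  the median ratios of nonsense and synonymous variants: s = 0 for the
  median nonsense variant, s = 1 for the median synonymous one. Errors are
  regularized with two pseudocounts, σ² = (n·v_obs + 2·v_prior)/(n + 2).
* **Remediability.** Δ = s(high B6) − s(low B6). Deleterious calls use the
  synonymous score null, remediable calls the nonsense Δ null, both with
  add-one-smoothed empirical p-values, Benjamini–Hochberg at q = 0.05, and
  95%-CI guard bands.
* **Imputation.** Gradient-boosted trees over intrinsic map features
  (confidence-weighted position averages, BLOSUM62-nearest substitution
  averages, residue physicochemistry), 10-fold cross-validated; measured
  and imputed values merge by inverse-variance weighting.
* **Patients.** Allele score = product of variant fitness (clamped to
  [0,1]; null alleles = 0); diploid score = sum of the two allele scores
  (φ_diploid = φ_X + φ_Y·φ_Z for p.[X];[Y;Z]); recurrent-variant cohort
  reduction; Spearman correlation with ordinal phenotypes.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data and write their tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

Stage outputs (a run with the committed seeds):

```
library: 20000 clones, 2.67 codon changes/clone (lambda 2.65), 4146 distinct protein variants reachable
low-B6 map: 4136 well-measured variants (4 dropped for imputation), median syn score 1.001, median nonsense -0.006, r(truth) = 0.931
re-derived thresholds: fitness 0.205 (synonymous null), delta 0.118 (nonsense null)
deleterious: 1156 calls / 3769 missense; 97.5% of calls are truly damaging
remediable: 222 calls; 226 truly remediable variants among the deleterious
low-B6: CV rmsd 0.274, CV pearson 0.803 over 10 folds
precision-recall: AUPRC 0.989; recall 1.00 at 90% precision (74+/99- refs)
spearman severity    vs phi_low   rho = +0.82 (p = 0.0011, n = 12)
spearman b6_response vs phi_high  rho = +0.85 (p = 0.00049, n = 12)
```

Reading it: the anchors land where they must (synonymous ≈ 1, nonsense ≈
0); scored fitness tracks the generator's true fitness at r = 0.93; the
re-derived FDR thresholds are data-dependent (0.205 / 0.118 here — the
real screen realized 0.60 / 0.22 on its own nulls); deleterious calls are
97.5% truly damaging; cross-validated imputation reaches r ≈ 0.80 at RMSD
≈ 0.27; and diploid scores from the map correlate strongly with the
simulated cohort's ordinal severity and B6-response phenotypes after
recurrence reduction (n = 12 retained of 50).

Equivalent functionality is available programmatically via
`run_pipeline(default_config())`, driven by a single (optionally YAML)
configuration.

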