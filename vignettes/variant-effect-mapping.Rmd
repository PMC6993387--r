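---
title: "Scoring, classifying and interpreting CBS variant effect maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, classifying and interpreting CBS variant effect maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbsmap)
```

## The measurement model

`cbsmap` analyses pooled functional-complementation screens of human
cystathionine beta-synthase (CBS) variants in a *cys4*-null yeast host.
A codon-randomized library of CBS clones is grown competitively under
selection (medium lacking cysteine) at low (0 and 1 ng/ml) and high
(400 ng/ml) concentrations of vitamin B6, the precursor of the CBS cofactor
pyridoxal 5'-phosphate. Deep sequencing before and after selection yields,
for every codon variant, a read count and a sequencing depth per condition
and replicate. Everything upstream of the count table (alignment,
strand-matched base calling) is out of scope; the pipeline starts from
counts.

Counts become allele frequencies (`count / depth`). Wildtype control
libraries, sequenced from wildtype amplicons, measure the spurious
frequency floor contributed by PCR and sequencing errors; variants whose
selective or nonselective frequency is not above the control mean plus
three control standard deviations are removed, equivalent codons for the
same amino-acid change are pooled, and the control mean is subtracted from
what remains. The enrichment ratio of a variant is

$$\Phi = \frac{f_\text{selective}}{f_\text{nonselective}}$$

on the background-adjusted frequencies, and the fitness score anchors each
ratio between the nonsense and synonymous medians:

$$s = \frac{\ln(\Phi / \Phi_\text{STOP})}{\ln(\Phi_\text{SYN} / \Phi_\text{STOP})},$$

so that $s = 0$ at the median nonsense variant and $s = 1$ at the median
synonymous variant. Anchor medians are computed per replicate before
replicate averaging, which normalizes replicate-specific selection
strength; a pooled-anchor variant is available by flag. The natural
logarithm is used throughout.

Measurement error is regularized with two pseudocounts: with $n$
replicates, $\sigma^2 = (n\,v_\text{obs} + 2\,v_\text{prior})/(n+2)$, where
$v_\text{obs}$ is the across-replicate variance and the prior SD comes from
a regression of log coefficient-of-variation on log nonselective read count
and fitness. Because CV is singular for scores near zero, the CV
denominator is floored at $\max(|s|, 0.1)$ — a purely numerical guard; the
floor only matters for variants whose score is within 0.1 of zero, where
relative error is not a meaningful quantity anyway. The standard error is
$\sigma/\sqrt{n}$. The two low-B6 screens (0 and 1 ng/ml) measure the same
condition class and are merged by plain averaging, matching how the
original screens were combined; inverse-variance weighting is available by
flag. Finally a map keeps only well-measured variants: pre-selection allele
frequency above 0.005% (undersampling guard) and standard error below 0.2.
Everything dropped here becomes an imputation target.

## Classification against empirical nulls

The delta score $\Delta = s_\text{high} - s_\text{low}$ quantifies vitamin
B6 remediability, with errors propagated in quadrature. Calls are made
against empirical nulls rather than parametric ones:

* **Deleterious.** The synonymous fitness-score distribution is the null.
  Each missense variant gets a one-sided lower-tail p-value with add-one
  smoothing, $p = (\#\{\text{null} \le s\} + 1)/(N+1)$, Benjamini–Hochberg
  adjustment at $q = 0.05$ sets the score threshold, and a variant is
  called only when the upper bound of its 95% CI ($s + 1.96\,\mathrm{se}$)
  is below that threshold. In the original screen this data-derived
  threshold came out at 0.60; the package always re-derives it from the
  supplied null and records it.
* **Remediable.** Delta scores exist only for variants deleterious at low
  B6, so the upper-tail FDR adjustment runs over that subset, with the
  nonsense delta-score distribution as the null (nonsense variants cannot
  be rescued by cofactor supplementation, making their deltas a clean
  null). The call requires the lower CI bound ($\Delta - 1.96\,
  \mathrm{se}_\Delta$) to clear the threshold (0.22 in the original
  screen).

Add-one smoothing bounds the smallest achievable p-value at $1/(N+1)$.
This has a real consequence at desk scale: with a null of 100 nonsense
deltas and a test set of $m$ deleterious variants, BH can only make calls
when at least $m/(q(N+1))$ variants sit at the minimum p-value, so runs
whose true-remediable count falls slightly below that line yield zero
remediable calls. That is the correct behavior of the procedure, not a
defect, and the calibration studies average over it.

## Imputation and refinement

Missing scores are imputed with gradient-boosted regression trees
(`xgboost`; 500 trees, depth 4, learning rate 0.05, single thread — fixed
and seeded so runs are reproducible) over features intrinsic to the map:
the confidence-weighted (weight $1/\mathrm{se}^2$) mean of the other
missense scores at the same position, the confidence-weighted means of the
3 and of the 4 most BLOSUM62-similar substitutions measured at that
position, wildtype and mutant residue physicochemistry (Kyte–Doolittle
hydropathy, side-chain volume, charge, polarity), the BLOSUM62 exchange
score, and class indicators. Neighbor averages deliberately exclude
synonymous and nonsense neighbors, whose scores reflect their class rather
than positional sensitivity. The "most similar substitutions" are taken
within the same position; external predictor columns (e.g. precomputed
PolyPhen-2/PROVEAN scores) can be supplied as extra features but are never
computed, so the default model is self-contained. Features that cannot be
computed are explicit missing values, which the tree learner routes
natively — never silent zeros.

Model quality is estimated by 10-fold cross-validation (RMSD and Pearson r
per fold); the pooled held-out residual SD becomes the standard error of
every imputed score, since nothing in the fit provides a per-variant error.
Measured scores are refined by inverse-variance averaging with their
*held-out* CV predictions (not the final model's self-fit, which would
leak), and every score in the final map carries a provenance label:
`measured`, `imputed`, or `refined`.

## Clinical interpretation

Reference-set evaluation sweeps a pathogenicity threshold over the scores
(lower score = predicted pathogenic), groups ties, and integrates precision
over recall step-wise for the AUPRC; recall-at-precision reports the
deepest recall achievable at, say, 90% precision. Bayes-factor LLRs follow
the tail definition: $\mathrm{LLR} = \log_{10}[P(S \le s \mid
\text{positive}) / P(S \ge s \mid \text{negative})]$ with add-one-smoothed
empirical tails. Two known pathologies of this definition are surfaced
rather than hidden: the ratio is not monotone in $s$, and scores above the
negative set's maximum are extrapolation (flagged `beyond_negative`); a
kernel-density LLR mode is provided as the smooth alternative. The
fitness–activity relationship is fit as a saturating curve $y = x/(x+k)$
by least squares (one-dimensional minimization to machine tolerance), and
compared against the best linear fit by Gaussian likelihood ratio — the
recessive-enzyme expectation is that fitness saturates at low relative
activity, and the likelihood ratio quantifies it.

## Diploid genotypes and cohorts

Allele fitness is the product of the member variants' scores, clamped to
[0, 1] first because raw map scores can exceed that range; nonsense and
frameshift alleles score 0 regardless of map value, reflecting
nonsense-mediated decay in humans that the cDNA-based yeast assay cannot
see. Diploid scores add the two allele scores (in trans), giving
$\phi_\text{diploid} = \phi_X + \phi_Y \phi_Z$ for a genotype p.[X];[Y;Z],
and are computed per condition plus as a delta. Unphased multi-variant
genotypes are assumed in trans, the conservative choice for a recessive
disease. Patients carrying C-terminal regulatory-domain variants (position
> 413) can be excluded — the complementation assay is insensitive in that
domain — with an override flag.

Recurrent variants bias cohort correlations, so cohorts are reduced by
iteratively removing one patient carrying the currently most frequent
variant until no variant occurs more than three times, preferring (1)
patients with the variant in cis with another, (2) patients with a
nonsense/frameshift/unknown variant in trans, (3) patients with null
variants on both alleles, and otherwise (4) the lexicographically smallest
patient id. The removal protocol leaves ties unspecified in places, so the
lexicographic tie-break is applied inside every rule to make reduction
deterministic and reproducible. Spearman correlations (average ranks,
two-sided t-approximation p-values) relate the three diploid score types
to onset age, disease severity (ordinal 1–5, 1 most severe) and clinical
B6 response (ordinal 1–4, 4 most responsive).

## The synthetic data generator

Every stage above is testable without any external data because the
package simulates the entire data-generating process with known truth:

* **Library.** Each clone draws a Poisson number of codon changes (mean
  2.65, the library's estimated mutational load), at uniform positions,
  with mutant codons uniform over the NNK codons differing from the
  wildtype codon. Synonymous codon changes therefore arise naturally —
  they must, because the scoring anchors need synonymous variants. Clone
  abundances are log-normal (sdlog 0.5), emulating uneven library
  representation.
* **True effects.** Synonymous variants have fitness 1 and nonsense 0 at
  both B6 levels. Missense *damaging* status is structured, not IID: a
  latent liability combines a per-position sensitivity (weight 0.65), a
  BLOSUM62-derived substitution severity (0.35) and Gaussian noise (SD
  0.05), and the top `fraction_deleterious` (default 40%) of missense
  variants by liability are damaging. The structure matters: real maps are
  imputable precisely because intolerance is organized by position and
  substitution similarity, and a generator with IID effects would make the
  imputation stage untestable in principle. Damaging fitness is drawn from
  Beta(2, 8) (concentrated near 0); tolerated fitness from Beta(8, 2)
  scaled to [0.7, 1.1], including mild hyper-complementation. A
  `fraction_remediable` subset (default 20%) of damaging variants gains a
  true delta drawn from Uniform(0.25, 0.6), capped so high-B6 fitness stays
  at or below 1.
* **Selection and sequencing.** Clone fitness is the product of its
  variants' fitness (the in-cis model, consistent with the diploid model);
  selection multiplies abundance by $2^{d \cdot f}$ with $d = 5.5$
  doublings; sequencing draws Poisson counts at depth $2 \times 10^6$ per
  variant around the marginal (carrier-summed) frequency plus a constant
  spurious frequency, which the wildtype control libraries measure alone.
  Error is modeled per variant, not per base, because the pipeline consumes
  counts after strand-matched error suppression. Tiles are not modeled;
  depth is per variant.
* **Calibration mode.** For FDR-calibration studies,
  `simulate_variant_panel(..., null_tolerated = TRUE)` builds a
  one-variant-per-clone panel and draws tolerated missense at fitness
  exactly 1. The reason is statistical, not cosmetic: an empirical-null FDR
  procedure controls false discoveries among *null-true* variants. Under
  the bimodal default mixture, tolerated variants at fitness 0.7–0.95 are
  genuinely hypomorphic, and with depth $2\times10^6$ and no error the
  procedure correctly discovers them — counting those as "false" would
  measure the mixture, not the calibration. Wildtype-like therefore means
  fitness 1 in calibration studies, and the realized false discovery
  proportion against that truth averages well below the nominal 5%.
* **Cohorts.** Patients draw two alleles (one or two variants each) from
  the damaging end of the truth table with a skewed recurrence
  distribution, so that cohort reduction has recurrent variants to remove.
  Ordinal phenotypes are monotone bins of the true diploid scores on a
  latent scale with *scale-free* noise: the noise SD is the `noise`
  parameter times the cohort's true score SD, so `noise = 0.3` means a 30%
  noise-to-signal ratio whatever the score range. Severity bins are latent
  quintiles (fixed-width bins over [0, 2] would leave the mild classes
  empty in a biallelic disease cohort); B6 response uses fixed delta
  breaks; onset age increases with the latent low-B6 score. At `noise = 0`
  phenotypes are deterministic and exactly monotone in the true score —
  though Spearman's correlation against a 5-level ordinal still sits
  slightly below 1 because of ties, which is a property of rank correlation
  on binned data, not of the generator.

What the generator does *not* emulate: read-level errors and tile-boundary
effects, PCR jackpots, position-specific error profiles, epistasis between
in-cis variants (fitness is multiplicative by construction), and the
regulatory-domain insensitivity of the real assay. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under
the stated generative assumptions — not that the assay itself is accurate
on real CBS data.

## Problem sizes and numerical choices

The test suite and the calibration studies run at desk scale, chosen so
each study completes in seconds while keeping the relevant asymptotics
honest: calibration panels of 2,000 missense / 100 synonymous / 100
nonsense variants over 20 seeds; end-to-end screens of $10^4$ clones over
a 100-codon ORF for parameter recovery (scored-vs-true fitness r exceeds
0.9) and for masked-score imputation recovery (3-seed mean r above 0.8);
cohorts of 50 patients over 5 seeds. The worked analysis under `analysis/`
uses a 200-codon ORF and $2\times10^4$ clones.

Other numerical decisions, in one place: background-subtraction floor at
$1/\text{depth}$ (smallest observable frequency; floored rows are flagged
so error models can down-weight them); add-one smoothing in every
empirical tail (no zero p-values or infinite LLRs); normal-quantile 1.96
for all 95% CIs; per-variant control SD with a Poisson fallback for single
control replicates and a pooled-SD option; BH via `stats::p.adjust`;
Spearman p-values by t-approximation with average ranks; Michaelis-type
constant by bracketed 1-D minimization (tolerance near machine epsilon)
rather than a general optimizer, because the problem is one-dimensional
and unimodal.

## Known limitations

Scores for variants absent from both low-B6 screens cannot be rescued by
the merge; the tail LLR is non-monotone and extrapolates beyond the
negative reference range (use the density mode when that matters); the
remediability null is only as large as the nonsense set, which limits FDR
resolution on small maps; and imputation quality degrades on sparse maps
(few measured variants per position) — the cross-validation report, not
the provenance label alone, is the honest quality statement for any
particular map.
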