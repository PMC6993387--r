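# Diploid genotype scoring, cohort reduction, phenotype correlation.

test_that("allele scores multiply in cis with clamping and null classes", {
  map <- toy_map(
    c("p.Ala10Val", "p.Gly20Trp", "p.Leu30Pro"),
    c(0.8, 0.5, 1.3)
  )
  expect_equal(allele_score(character(0), map), 1.0)
  expect_equal(allele_score(c("p.Ala10Val", "p.Gly20Trp"), map), 0.4)
  expect_equal(allele_score("p.Trp40Ter", map), 0.0)
  expect_equal(allele_score("p.Ala10fs", map), 0.0)
  # scores above 1 are clamped before multiplying
  expect_equal(allele_score(c("p.Leu30Pro", "p.Ala10Val"), map), 0.8)
  expect_error(allele_score("p.Gln99Arg", map), "not resolvable")
  expect_equal(allele_score("p.Gln99Arg", map, unresolved = 0.5), 0.5)
})

test_that("diploid scores add allele products", {
  map <- toy_map(
    c("p.Ala10Val", "p.Gly20Trp", "p.Leu30Pro"),
    c(0.5, 0.8, 0.5)
  )
  d <- diploid_score("p.Ala10Val", c("p.Gly20Trp", "p.Leu30Pro"), map, map)
  expect_equal(d$phi_low, 0.5 + 0.8 * 0.5)
  expect_equal(diploid_score(character(0), character(0), map, map)$phi_low, 2)
  expect_equal(
    diploid_score("p.Trp40Ter", "p.Trp40Ter", map, map)$phi_low, 0
  )
})

test_that("raising a variant's fitness never lowers the diploid score", {
  set.seed(61)
  for (i in 1:20) {
    sc <- stats::runif(3)
    map <- toy_map(c("p.Ala10Val", "p.Gly20Trp", "p.Leu30Pro"), sc)
    up <- map
    j <- sample(3, 1)
    up$score[j] <- min(1, up$score[j] + stats::runif(1, 0, 0.5))
    g1 <- c("p.Ala10Val", "p.Gly20Trp")
    g2 <- "p.Leu30Pro"
    expect_gte(
      diploid_score(g1, g2, up, up)$phi_low,
      diploid_score(g1, g2, map, map)$phi_low - 1e-12
    )
  }
})

test_that("cohort reduction follows the removal priority rules", {
  # variant A appears 5x: P1 carries it in cis with B, P2 has a nonsense in
  # trans, P3-P5 are plain compound hets. Two removals bring A down to 3.
  cohort <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5", "P6"),
    allele1 = c("p.Ala10Val;p.Gly20Trp", "p.Ala10Val", "p.Ala10Val",
      "p.Ala10Val", "p.Ala10Val", "p.Leu30Pro"),
    allele2 = c("p.Leu30Pro", "p.Trp40Ter", "p.Gln50Arg",
      "p.His60Tyr", "p.Asn70Ser", "p.Gln50Arg"),
    phase_confirmed = TRUE, onset_age = 10, severity = 3L, b6_response = 2L
  )
  red <- reduce_cohort(cohort, max_occurrence = 3)
  expect_equal(red$log$patient_id, c("P1", "P2"))
  expect_equal(red$log$rule, c("in_cis_with_x", "null_in_trans"))
  expect_equal(red$log$variant, c("p.Ala10Val", "p.Ala10Val"))
  expect_setequal(red$cohort$patient_id, c("P3", "P4", "P5", "P6"))

  # occurrence counting includes homozygotes twice
  hom <- data.frame(
    patient_id = c("Q1", "Q2"),
    allele1 = c("p.Ala10Val", "p.Ala10Val"),
    allele2 = c("p.Ala10Val", "p.Ala10Val"),
    phase_confirmed = TRUE, onset_age = 1, severity = 1L, b6_response = 1L
  )
  red2 <- reduce_cohort(hom, max_occurrence = 3)
  expect_equal(nrow(red2$cohort), 1)
  expect_equal(red2$log$rule, "lexicographic")
  expect_equal(red2$log$patient_id, "Q1")
})

test_that("an already-diverse cohort is returned unchanged, deterministically", {
  cohort <- data.frame(
    patient_id = c("P1", "P2"),
    allele1 = c("p.Ala10Val", "p.Gly20Trp"),
    allele2 = c("p.Leu30Pro", "p.Gln50Arg"),
    phase_confirmed = TRUE, onset_age = 5, severity = 2L, b6_response = 3L
  )
  r1 <- reduce_cohort(cohort)
  expect_identical(r1$cohort, cohort)
  expect_equal(nrow(r1$log), 0)
  # determinism on a cohort that does reduce
  big <- cohort[c(1, 1, 1, 1, 2), ]
  big$patient_id <- paste0("P", 1:5)
  expect_identical(reduce_cohort(big)$log, reduce_cohort(big)$log)
})

test_that("reduction terminates with every variant at or below the cap", {
  set.seed(62)
  vars <- sprintf("p.Ala%dVal", 1:6)
  cohort <- data.frame(
    patient_id = sprintf("P%02d", 1:30),
    allele1 = sample(vars, 30, replace = TRUE),
    allele2 = sample(vars, 30, replace = TRUE),
    phase_confirmed = TRUE, onset_age = 1, severity = 1L, b6_response = 1L
  )
  red <- reduce_cohort(cohort, max_occurrence = 3)
  occ <- table(unlist(strsplit(
    c(red$cohort$allele1, red$cohort$allele2), ";"
  )))
  expect_true(all(occ <= 3))
  expect_lte(nrow(red$log), 30)
})

test_that("spearman matches the stats oracle exactly on small instances", {
  set.seed(63)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    x <- stats::rnorm(n)
    y <- round(stats::rnorm(n), 1) # ties likely
    got <- spearman_rho(x, y)
    want <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)
    )
    expect_equal(got$rho, unname(want$estimate), tolerance = 1e-12)
    expect_equal(got$p, want$p.value, tolerance = 1e-9)
  }
  # perfect monotone relations
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_rho(1:5, -(1:5))$rho, -1)
  expect_true(is.na(spearman_rho(1:5, rep(2, 5))$rho))
})

test_that("noiseless cohorts bin phenotypes monotonically in the true score", {
  cfg <- sim_config(orf_length_codons = 80, n_clones = 1000, seed = 64)
  truth <- simulate_clone_library(cfg)$truth
  sim <- simulate_cohort(truth, 40, noise = 0, seed = 64)
  expect_equal(nrow(sim$cohort), 40)
  ord <- order(sim$truth_scores$true_low)
  expect_true(all(diff(sim$cohort$severity[ord]) >= 0))
  r <- spearman_rho(sim$truth_scores$true_low, sim$cohort$severity)
  expect_gte(r$rho, 0.9)
  # homozygous nonsense genotype lands in the most severe class
  non <- truth$hgvs[truth$class == "nonsense"][1]
  sim2 <- simulate_cohort(truth[truth$hgvs == non, ], 5, noise = 0, seed = 1)
  expect_true(all(sim2$cohort$severity == 1L))
})

test_that("diploid scores from a measured map track severity in noisy cohorts", {
  rhos <- vapply(1:5, function(seed) {
    cfg <- sim_config(orf_length_codons = 80, n_clones = 1000, seed = seed)
    truth <- simulate_clone_library(cfg)$truth
    sim <- simulate_cohort(truth, 50, noise = 0.3, seed = seed)
    # score patients against the true map (maps the assay at its best)
    map <- data.frame(
      hgvs = truth$hgvs, score = truth$fitness_low, se = 0.05
    )
    map_high <- data.frame(
      hgvs = truth$hgvs, score = truth$fitness_high, se = 0.05
    )
    dsc <- score_cohort(sim$cohort, map, map_high,
      exclude_regulatory = FALSE
    )
    corr <- correlate_phenotypes(sim$cohort, dsc)
    corr$rho[corr$phenotype == "severity" & corr$score_type == "phi_low"]
  }, numeric(1))
  expect_true(all(rhos >= 0.6))
})

test_that("cohort tables round-trip through TSV including reference alleles", {
  cohort <- data.frame(
    patient_id = c("P1", "P2"),
    allele1 = c("p.Ala10Val;p.Gly20Trp", "p.Trp40Ter"),
    allele2 = c("", "p.Ala10Val"),
    phase_confirmed = c(TRUE, FALSE),
    onset_age = c(10.5, NA), severity = c(3L, 1L), b6_response = c(2L, 4L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$allele1, cohort$allele1)
  expect_equal(back$allele2, cohort$allele2)
  expect_equal(back$severity, cohort$severity)
})
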