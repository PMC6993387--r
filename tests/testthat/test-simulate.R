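# Generative model: oligo design, clone library, selection, sequencing.

test_that("oligo design yields one NNK oligo per sense codon minus the initiator", {
  orf <- random_orf(551, seed = 11)
  oligos <- design_popcode_oligos(orf)
  expect_equal(nrow(oligos), 550)
  expect_true(all(nchar(oligos$oligo) >= 28 & nchar(oligos$oligo) <= 38))
  expect_false(1 %in% oligos$position)
  # the degenerate codon sits at the target position: N,N,K
  mid <- vapply(seq_len(nrow(oligos)), function(i) {
    off <- 3 * oligos$position[i] - 2 - oligos$start[i]
    substr(oligos$oligo[i], off + 1, off + 3)
  }, character(1))
  expect_true(all(mid == "NNK"))
})

test_that("oligo design validates its input", {
  expect_error(design_popcode_oligos("ATGXYZ"), "non-ACGT")
  expect_error(design_popcode_oligos("ATGCC"), "divisible by 3")
})

test_that("NNK codons cover all 20 amino acids plus one stop", {
  aa <- translate_codon(nnk_codons())
  expect_length(nnk_codons(), 32)
  expect_setequal(setdiff(unique(aa), "*"), rownames(aa_descriptors()))
  expect_equal(sum(aa == "*"), 1) # TAG only
  expect_true(all(substr(nnk_codons(), 3, 3) %in% c("G", "T")))
})

test_that("clone mutational load follows the configured Poisson law", {
  lambda <- 2.65
  n <- 1e5
  cfg <- sim_config(
    orf_length_codons = 100, mutation_load_lambda = lambda,
    n_clones = n, seed = 3
  )
  lib <- simulate_clone_library(cfg)
  k <- tabulate(lib$clone_variants$clone, nbins = n)
  se <- sqrt(lambda / n)
  expect_lt(abs(mean(k) - lambda), 3 * se)
  # fraction of mutated clones matches the closed-form 1 - exp(-lambda)
  p <- 1 - exp(-lambda)
  se_p <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(k > 0) - p), 3 * se_p)
})

test_that("zero mutational load gives an all-wildtype library", {
  cfg <- sim_config(
    orf_length_codons = 50, mutation_load_lambda = 0,
    n_clones = 100, seed = 4
  )
  lib <- simulate_clone_library(cfg)
  expect_equal(nrow(lib$clone_variants), 0)
  expect_true(all(lib$clones$fitness_low == 1))
})

test_that("true effects respect class conventions and the in-cis product", {
  cfg <- sim_config(orf_length_codons = 80, n_clones = 2000, seed = 5)
  lib <- simulate_clone_library(cfg)
  tr <- lib$truth
  expect_true(all(tr$fitness_low[tr$class == "synonymous"] == 1))
  expect_true(all(tr$fitness_low[tr$class == "nonsense"] == 0))
  expect_true(all(tr$fitness_high >= tr$fitness_low - 1e-12))
  expect_true(all(tr$fitness_high[tr$remediable] >
    tr$fitness_low[tr$remediable]))
  # clone fitness is the product of its variants' fitness
  i <- sample(which(tabulate(lib$clone_variants$clone) >= 2), 5)
  for (cl in i) {
    vs <- lib$clone_variants[lib$clone_variants$clone == cl, ]
    f <- tr$fitness_low[match(
      paste(vs$position, vs$mut_aa),
      paste(tr$position, tr$mut_aa)
    )]
    expect_equal(lib$clones$fitness_low[cl], prod(f), tolerance = 1e-12)
  }
})

test_that("selection enriches by 2^(doublings * fitness) and renormalizes", {
  clones <- data.frame(
    clone = 1:2, abundance = c(0.5, 0.5),
    fitness_low = c(0, 1), fitness_high = c(0, 1)
  )
  post <- simulate_selection(clones, doublings = 5, condition = "low")
  expect_equal(sum(post$abundance), 1, tolerance = 1e-9)
  expect_equal(post$abundance[2] / post$abundance[1], 32)

  # neutral library: abundances unchanged
  neutral <- data.frame(
    clone = 1:3, abundance = c(0.2, 0.3, 0.5),
    fitness_low = 1, fitness_high = 1
  )
  expect_equal(
    simulate_selection(neutral, 5.5, "low")$abundance,
    neutral$abundance
  )
  expect_equal(
    simulate_selection(neutral, 5.5, "nonselective")$abundance,
    neutral$abundance
  )
  expect_error(simulate_selection(neutral, -1, "low"), "doublings")
})

test_that("abundances stay normalized and selection is order-independent", {
  cfg <- sim_config(orf_length_codons = 60, n_clones = 500, seed = 6)
  lib <- simulate_clone_library(cfg)
  expect_equal(sum(lib$clones$abundance), 1, tolerance = 1e-9)
  post <- simulate_selection(lib$clones, 5.5, "low")
  expect_equal(sum(post$abundance), 1, tolerance = 1e-9)

  perm <- sample(nrow(lib$clones))
  post_perm <- simulate_selection(lib$clones[perm, ], 5.5, "low")
  mf1 <- cbsmap:::marginal_frequencies(post, lib$clone_variants)
  mf2 <- cbsmap:::marginal_frequencies(post_perm, lib$clone_variants)
  expect_equal(mf1, mf2[names(mf1)], tolerance = 1e-12)
})

test_that("sequencing counts are Poisson around depth x frequency", {
  cfg <- sim_config(
    orf_length_codons = 30, n_clones = 50, depth = 1e5,
    error_rate = 0, mutation_load_lambda = 1, seed = 7
  )
  lib <- simulate_clone_library(cfg)
  mf <- cbsmap:::marginal_frequencies(lib$clones, lib$clone_variants)
  v <- names(mf)[which.max(mf)]
  draws <- vapply(1:100, function(i) {
    cfg2 <- cfg
    cfg2$seed <- cfg$seed + i
    counts <- simulate_sequencing(lib, cfg2)
    counts$count[counts$variant_id == v &
      counts$condition == "nonselective" & counts$replicate == 1]
  }, numeric(1))
  mu <- cfg$depth * mf[[v]]
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(mu / 100))
})

test_that("degenerate depth and error settings behave as limits", {
  cfg <- sim_config(
    orf_length_codons = 30, n_clones = 50, depth = 0,
    error_rate = 0, seed = 8
  )
  lib <- simulate_clone_library(cfg)
  counts <- simulate_sequencing(lib, cfg)
  expect_true(all(counts$count == 0))

  cfg2 <- sim_config(
    orf_length_codons = 30, n_clones = 50, depth = 1e5,
    error_rate = 0, seed = 8
  )
  counts2 <- simulate_sequencing(lib, cfg2)
  expect_true(all(counts2$count[counts2$condition == "wt_control"] == 0))
})

test_that("identical seeds give bit-identical tables", {
  cfg <- sim_config(orf_length_codons = 40, n_clones = 200, seed = 9)
  expect_identical(simulate_screen(cfg)$counts, simulate_screen(cfg)$counts)
})

test_that("a remediable variant is at least as frequent under high B6", {
  cfg <- sim_config(
    orf_length_codons = 60, n_clones = 2000,
    fraction_remediable = 0.5, seed = 10
  )
  lib <- simulate_clone_library(cfg)
  rem <- lib$truth[lib$truth$remediable, ]
  expect_gt(nrow(rem), 0)
  post_low <- simulate_selection(lib$clones, 5.5, "low")
  post_high <- simulate_selection(lib$clones, 5.5, "high")
  mf_low <- cbsmap:::marginal_frequencies(post_low, lib$clone_variants)
  mf_high <- cbsmap:::marginal_frequencies(post_high, lib$clone_variants)
  cv <- lib$clone_variants
  key <- paste0(cv$position, ":", cv$wt_codon, ">", cv$mut_codon)
  for (i in seq_len(min(5, nrow(rem)))) {
    ids <- unique(key[cv$position == rem$position[i] &
      cv$mut_aa == rem$mut_aa[i]])
    expect_gte(sum(mf_high[ids]), sum(mf_low[ids]))
  }
})

test_that("config invariants are enforced", {
  expect_error(sim_config(mutation_load_lambda = -1), "lambda")
  expect_error(sim_config(error_rate = 1.5), "error_rate")
  expect_error(sim_config(depth = -5), "depth")
  expect_error(sim_config(doublings = -0.1), "doublings")
})

test_that("count tables round-trip through TSV", {
  cfg <- sim_config(orf_length_codons = 30, n_clones = 50, seed = 12)
  counts <- simulate_screen(cfg)$counts
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(counts, path)
  back <- read_count_table(path)
  expect_equal(back$count, counts$count)
  expect_equal(back$variant_id, counts$variant_id)
})
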