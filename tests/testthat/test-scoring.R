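# Enrichment ratios, anchored scores, error regularization, merging.

test_that("enrichment ratio is adjusted selective over nonselective", {
  expect_equal(enrichment_ratio(2e-5, 4e-5), 0.5)
  expect_equal(enrichment_ratio(3e-5, 3e-5), 1.0)
  expect_true(is.na(enrichment_ratio(3e-5, 0)))
})

test_that("fitness score hits its anchors and the geometric midpoint", {
  expect_equal(fitness_score(0.1, 0.1, 1.0), 0)
  expect_equal(fitness_score(1.0, 0.1, 1.0), 1)
  expect_equal(fitness_score(0.3162278, 0.1, 1.0), 0.5, tolerance = 1e-6)
  expect_error(fitness_score(0.5, 1.0, 0.5), "anchor failure")
})

test_that("fitness score is strictly increasing in the enrichment ratio", {
  phi <- sort(stats::runif(50, 0.01, 5))
  s <- fitness_score(phi, 0.1, 1.2)
  expect_true(all(diff(s) > 0))
})

test_that("error regularization matches the two-pseudocount closed form", {
  r <- regularize_error(0.04, 0.16, 2)
  expect_equal(r$sigma^2, 0.10)
  expect_equal(r$sigma, sqrt(0.10))
  expect_equal(r$se, sqrt(0.10) / sqrt(2))
  # equal variances are a fixed point for any n
  for (n in c(1, 2, 5, 100)) {
    expect_equal(regularize_error(0.3, 0.3, n)$sigma^2, 0.3)
  }
  # large n converges to the observed variance
  expect_equal(regularize_error(0.04, 0.16, 1000)$sigma^2, 0.04,
    tolerance = 0.01
  )
  # closed form over a grid of (n, v_obs, v_prior)
  grid <- expand.grid(n = c(1, 2, 3, 10), vo = c(0, 0.01, 0.5), vp = c(0.02, 1))
  got <- regularize_error(grid$vo, grid$vp, grid$n)$sigma^2
  expect_equal(got, (grid$n * grid$vo + 2 * grid$vp) / (grid$n + 2),
    tolerance = 1e-14
  )
  # regularized variance stays between the observed and prior variances
  expect_true(all(got >= pmin(grid$vo, grid$vp) - 1e-14 &
    got <= pmax(grid$vo, grid$vp) + 1e-14))
})

test_that("prior error model recovers a known coverage exponent", {
  set.seed(101)
  n <- 400
  coverage <- 10^stats::runif(n, 2, 5)
  score <- stats::runif(n, 0.5, 1.5)
  cv <- 2 / sqrt(coverage)
  m <- prior_variance_model(score, cv * abs(score), coverage)
  expect_equal(m$type, "regression")
  expect_equal(m$coef[2], -0.5, tolerance = 0.05)

  # constant-CV data: coverage coefficient vanishes
  m2 <- prior_variance_model(score, 0.1 * abs(score), coverage)
  expect_lt(abs(m2$coef[2]), 0.05)

  # positivity on an arbitrary grid
  grid <- expand.grid(coverage = c(1, 100, 1e6), score = c(-2, 0, 0.5, 3))
  expect_true(all(predict(m, grid$coverage, grid$score) > 0))

  # sparse data falls back to the global median CV
  m3 <- prior_variance_model(score[1:5], cv[1:5] * score[1:5], coverage[1:5])
  expect_equal(m3$type, "median")
  expect_true(all(predict(m3, grid$coverage, grid$score) > 0))
})

test_that("scoring a noiseless table reproduces hand-computed scores", {
  adj <- toy_adjusted()
  map <- score_map(adj, "select_low_0")
  # anchors: single nonsense median phi = 0.1, synonymous median phi = 1
  a <- attr(map, "anchors")
  expect_equal(a$phi_stop, c(0.1, 0.1), tolerance = 1e-9)
  expect_equal(a$phi_syn, c(1, 1), tolerance = 1e-9)
  get <- function(h) map$score[map$hgvs == h]
  expect_equal(get("p.Leu4Ter"), log(0.08 / 0.1) / log(10), tolerance = 1e-9)
  expect_equal(get("p.Leu4Pro"), 0.5, tolerance = 1e-6)
  expect_equal(get("p.Ala2Val"), log(0.5 / 0.1) / log(10), tolerance = 1e-9)
  # median nonsense = 0 and median synonymous = 1 exactly
  expect_equal(stats::median(map$score[map$class == "nonsense"]), 0,
    tolerance = 1e-12
  )
  expect_equal(stats::median(map$score[map$class == "synonymous"]), 1,
    tolerance = 1e-12
  )
  # identical replicates: replicate mean equals the single-replicate score
  one_rep <- adj[adj$replicate == 1, ]
  map1 <- score_map(one_rep, "select_low_0")
  expect_equal(map$score, map1$score[match(map$hgvs, map1$hgvs)],
    tolerance = 1e-6
  )
})

test_that("anchor medians are exact on simulated maps too", {
  panel <- small_panel(seed = 22)
  adj <- prepare_frequencies(panel$counts)
  map <- score_map(adj, "select_low_0", pooled_anchors = TRUE)
  per_rep_phi <- attr(map, "anchors")
  expect_false(any(is.na(per_rep_phi$phi_stop)))
  # with pooled anchors, per-variant replicate averaging moves individual
  # scores, but nonsense cluster near 0 and synonymous near 1
  expect_lt(abs(stats::median(map$score[map$class == "nonsense"])), 0.05)
  expect_lt(abs(stats::median(map$score[map$class == "synonymous"]) - 1), 0.05)
})

test_that("low-B6 maps merge as plain means with quadrature errors", {
  m0 <- toy_map(c("p.Ala2Val", "p.Gly3Ter"), c(0.2, 0.0), se = 0.1)
  m1 <- toy_map(c("p.Ala2Val", "p.Lys5Arg"), c(0.4, 0.9), se = 0.1)
  cm <- combine_low_b6(m0, m1)
  expect_equal(cm$score[cm$hgvs == "p.Ala2Val"], 0.3)
  expect_equal(cm$se[cm$hgvs == "p.Ala2Val"], sqrt(0.02) / 2)
  # single-source variants pass through
  expect_equal(cm$score[cm$hgvs == "p.Gly3Ter"], 0.0)
  expect_equal(cm$score[cm$hgvs == "p.Lys5Arg"], 0.9)
  # identical inputs reproduce themselves
  same <- combine_low_b6(m0, m0)
  expect_equal(same$score, m0$score)
})

test_that("well-measured filter applies both frequency and SE cuts", {
  map <- toy_map(
    c("p.Ala2Val", "p.Ala3Val", "p.Ala4Val"),
    c(0.5, 0.5, 0.5),
    se = c(0.1, 0.1, 0.25)
  )
  map$pre_selection_freq <- c(6e-5, 4e-5, 6e-5)
  flt <- well_measured_filter(map)
  expect_equal(flt$kept$hgvs, "p.Ala2Val")
  expect_setequal(flt$dropped$hgvs, c("p.Ala3Val", "p.Ala4Val"))
})

test_that("maps round-trip through the MaveDB-style TSV", {
  map <- toy_map(c("p.Ala2Val", "p.Gly3Ter"), c(0.2, 0.0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_map(map, path)
  expect_true("hgvs_pro" %in% names(utils::read.delim(path)))
  back <- read_map(path)
  expect_equal(back$score, map$score)
  expect_equal(back$hgvs, map$hgvs)
})
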