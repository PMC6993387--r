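# Synthetic data generator: mutagenized clone library -> pooled selection ->
# sequencing counts, plus reference sets and patient cohorts, all with known
# ground truth. Emulates a POPCode/TileSeq complementation screen of CBS in a
# cys4-null yeast host.

#' Simulation configuration
#'
#' Bundles every knob of the data-generating process. Defaults emulate the
#' screen conditions: mean mutational load of 2.65 codon changes per clone,
#' 5.5 doublings of pooled selection, 2 million reads of sequencing depth,
#' and two biological replicates per condition.
#'
#' @param orf_length_codons ORF length in codons (including the initiator).
#' @param mutation_load_lambda Poisson mean of codon changes per clone.
#' @param n_clones Number of clones in the library.
#' @param doublings Population doublings during selective growth.
#' @param depth Sequencing reads per variant position per condition.
#' @param error_rate Per-codon-variant spurious frequency (background error
#'   remaining after strand-matched filtering; measured by the wildtype
#'   control libraries).
#' @param fraction_deleterious Proportion of missense variants that are truly
#'   damaging.
#' @param fraction_remediable Proportion of damaging missense variants whose
#'   fitness is rescued by high vitamin B6.
#' @param replicates Biological replicates per condition (also used for the
#'   wildtype control libraries).
#' @param abundance_sdlog Log-normal spread of clone abundances (0 = equal
#'   representation).
#' @param orf_seq Optional explicit ORF nucleotide sequence; when `NULL` a
#'   random stop-free ORF of `orf_length_codons` codons is generated from the
#'   seed.
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(orf_length_codons = 100,
                       mutation_load_lambda = 2.65,
                       n_clones = 10000,
                       doublings = 5.5,
                       depth = 2e6,
                       error_rate = 1e-6,
                       fraction_deleterious = 0.4,
                       fraction_remediable = 0.2,
                       replicates = 2,
                       abundance_sdlog = 0.5,
                       orf_seq = NULL,
                       seed = 42) {
  cfg <- list(
    orf_length_codons = orf_length_codons,
    mutation_load_lambda = mutation_load_lambda,
    n_clones = n_clones,
    doublings = doublings,
    depth = depth,
    error_rate = error_rate,
    fraction_deleterious = fraction_deleterious,
    fraction_remediable = fraction_remediable,
    replicates = replicates,
    abundance_sdlog = abundance_sdlog,
    orf_seq = orf_seq,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  rate_in_01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!rate_in_01(cfg$error_rate)) stop("error_rate must be in [0,1]")
  if (!rate_in_01(cfg$fraction_deleterious)) {
    stop("fraction_deleterious must be in [0,1]")
  }
  if (!rate_in_01(cfg$fraction_remediable)) {
    stop("fraction_remediable must be in [0,1]")
  }
  if (cfg$mutation_load_lambda < 0) stop("mutation_load_lambda must be >= 0")
  if (cfg$depth < 0) stop("depth must be >= 0")
  if (cfg$doublings < 0) stop("doublings must be >= 0")
  if (cfg$n_clones < 1) stop("n_clones must be >= 1")
  if (cfg$replicates < 1) stop("replicates must be >= 1")
  if (cfg$orf_length_codons < 2) stop("orf_length_codons must be >= 2")
  invisible(cfg)
}

#' Generate a random stop-free ORF
#'
#' ATG initiator followed by sense codons drawn uniformly at random.
#'
#' @param n_codons Total codons including the initiator.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @return Nucleotide string of length `3 * n_codons`.
#' @export
random_orf <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 1, replace = TRUE),
    collapse = ""
  ))
}

orf_codons <- function(orf_sequence) {
  orf_sequence <- toupper(orf_sequence)
  if (grepl("[^ACGT]", orf_sequence)) {
    stop("ORF contains non-ACGT characters")
  }
  if (nchar(orf_sequence) %% 3 != 0) {
    stop("ORF length must be divisible by 3")
  }
  substring(
    orf_sequence,
    seq(1, nchar(orf_sequence), 3),
    seq(3, nchar(orf_sequence), 3)
  )
}

#' Design codon-randomization oligos
#'
#' One oligo per sense codon (initiator and any stop codons excluded), each
#' centered on its target codon with the target replaced by the degenerate
#' NNK pattern. Oligo length stays within `[min_len, max_len]`, clipped at
#' the ORF boundaries and extended on the opposite side where a boundary
#' would make it too short.
#'
#' @param orf_sequence ORF nucleotide string (length divisible by 3).
#' @param min_len,max_len Allowed oligo length range in bases.
#' @return data.frame with columns `position` (codon index), `start`, `end`
#'   (1-based nucleotide coordinates), and `oligo`.
#' @export
design_popcode_oligos <- function(orf_sequence, min_len = 28, max_len = 38) {
  codons <- orf_codons(orf_sequence)
  if (length(codons) < 2) stop("ORF must contain at least 2 codons")
  orf_sequence <- toupper(orf_sequence)
  n <- nchar(orf_sequence)
  targets <- setdiff(which(translate_codon(codons) != "*"), 1L)
  flank <- floor((max_len - 3) / 2)
  res <- lapply(targets, function(p) {
    cs <- 3 * p - 2
    ce <- 3 * p
    start <- max(1, cs - flank)
    end <- min(n, ce + flank)
    # near a boundary, extend the other side to respect min_len
    if (end - start + 1 < min_len) {
      if (start == 1) end <- min(n, start + min_len - 1)
      if (end == n) start <- max(1, end - min_len + 1)
    }
    seq <- paste0(
      substr(orf_sequence, start, cs - 1),
      "NNK",
      substr(orf_sequence, ce + 1, end)
    )
    data.frame(position = p, start = start, end = end, oligo = seq)
  })
  do.call(rbind, res)
}

#' Write an oligo set as FASTA
#'
#' @param oligos data.frame from [design_popcode_oligos()].
#' @param path Output file.
#' @export
write_oligos_fasta <- function(oligos, path) {
  lines <- rbind(
    paste0(">codon_", oligos$position),
    oligos$oligo
  )
  writeLines(as.vector(lines), path)
}

# True fitness for every protein variant reachable by NNK replacement.
# Synonymous = 1, nonsense = 0 at both B6 levels; missense from a bimodal
# mixture; a remediable subset of damaging variants gains a positive delta
# at high B6. Consumes RNG draws: call under the library seed.
assign_true_effects <- function(wt_codons, cfg) {
  nnk <- nnk_codons()
  nnk_aa <- translate_codon(nnk)
  positions <- seq_along(wt_codons)[-1]
  tab <- do.call(rbind, lapply(positions, function(p) {
    wt_aa <- translate_codon(wt_codons[p])
    if (wt_aa == "*") {
      return(NULL)
    }
    mut_aa <- unique(nnk_aa[nnk != wt_codons[p]])
    data.frame(
      position = p, wt_aa = wt_aa, mut_aa = mut_aa,
      class = variant_class(wt_aa, mut_aa)
    )
  }))
  n <- nrow(tab)
  tab$fitness_low <- NA_real_
  tab$fitness_high <- NA_real_
  tab$remediable <- FALSE
  tab$damaging <- FALSE
  syn <- tab$class == "synonymous"
  non <- tab$class == "nonsense"
  mis <- tab$class == "missense"
  tab$fitness_low[syn] <- 1
  tab$fitness_high[syn] <- 1
  tab$fitness_low[non] <- 0
  tab$fitness_high[non] <- 0
  # Damaging status is structured in position and substitution severity
  # (as in real proteins, where buried/catalytic positions are broadly
  # intolerant and conservative substitutions are mild): a per-position
  # sensitivity and a BLOSUM62-derived substitution severity combine into a
  # latent liability, and the top fraction_deleterious of missense variants
  # by liability are damaging. This structure is what makes the map
  # imputable from same-position and similar-substitution features.
  n_mis <- sum(mis)
  damaging <- rep(FALSE, n)
  if (n_mis > 0 && cfg$fraction_deleterious > 0) {
    bl <- blosum62()
    pos_sens <- stats::runif(length(wt_codons))
    wt_i <- tab$wt_aa[mis]
    mu_i <- tab$mut_aa[mis]
    blv <- bl[cbind(
      match(wt_i, rownames(bl)), match(mu_i, colnames(bl))
    )]
    sev <- (max(bl) - blv) / (max(bl) - min(bl))
    liability <- 0.65 * pos_sens[tab$position[mis]] + 0.35 * sev +
      stats::rnorm(n_mis, 0, 0.05)
    thr <- stats::quantile(liability, 1 - cfg$fraction_deleterious)
    damaging[mis] <- liability > thr
  }
  tab$damaging <- damaging
  tolerated <- mis & !damaging
  tab$fitness_low[damaging] <- stats::rbeta(sum(damaging), 2, 8)
  # tolerated missense span [0.7, 1.1] to include mild hyper-complementation
  tab$fitness_low[tolerated] <- 0.7 + 0.4 * stats::rbeta(sum(tolerated), 8, 2)
  tab$fitness_high <- ifelse(mis, tab$fitness_low, tab$fitness_high)
  rem <- damaging & stats::runif(n) < cfg$fraction_remediable
  tab$remediable[rem] <- TRUE
  tab$fitness_high[rem] <- pmin(
    1, tab$fitness_low[rem] + stats::runif(sum(rem), 0.25, 0.6)
  )
  tab$hgvs <- hgvs_pro(tab$wt_aa, tab$position, tab$mut_aa)
  rownames(tab) <- NULL
  tab
}

#' Simulate a mutagenized clone library
#'
#' Each clone receives a Poisson-distributed number of codon changes at
#' positions drawn uniformly without replacement; mutant codons are uniform
#' over the NNK codons differing from the wildtype codon. Clone fitness is
#' the product of its variants' true fitness values (the in-cis model), and
#' clone abundances follow a log-normal library representation.
#'
#' @param config A [sim_config()].
#' @return List with `clones` (one row per clone: `clone`, `abundance`,
#'   `fitness_low`, `fitness_high`), `clone_variants` (one row per codon
#'   change), `truth` (protein-level true effects), and `orf` (the ORF used).
#' @export
simulate_clone_library <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  orf <- config$orf_seq
  if (is.null(orf)) orf <- random_orf(config$orf_length_codons)
  wt_codons <- orf_codons(orf)
  truth <- assign_true_effects(wt_codons, config)

  nnk <- nnk_codons()
  # per wildtype codon, the NNK replacements that change the codon
  alt_by_codon <- lapply(wt_codons, function(cd) setdiff(nnk, cd))

  n <- config$n_clones
  k <- stats::rpois(n, config$mutation_load_lambda)
  k <- pmin(k, length(wt_codons) - 1L)
  clone_id <- rep.int(seq_len(n), k)
  pos <- unlist(lapply(k, function(ki) {
    if (ki == 0) integer(0) else 1L + sample.int(length(wt_codons) - 1L, ki)
  }), use.names = FALSE)
  mut_codon <- vapply(pos, function(p) {
    alts <- alt_by_codon[[p]]
    alts[sample.int(length(alts), 1L)]
  }, character(1))

  clone_variants <- data.frame(
    clone = clone_id,
    position = pos,
    wt_codon = wt_codons[pos],
    mut_codon = mut_codon
  )
  clone_variants$wt_aa <- translate_codon(clone_variants$wt_codon)
  clone_variants$mut_aa <- translate_codon(clone_variants$mut_codon)

  fit_key <- paste(truth$position, truth$mut_aa)
  idx <- match(
    paste(clone_variants$position, clone_variants$mut_aa), fit_key
  )
  v_low <- truth$fitness_low[idx]
  v_high <- truth$fitness_high[idx]
  fitness_low <- rep(1, n)
  fitness_high <- rep(1, n)
  if (nrow(clone_variants) > 0) {
    agg_l <- vapply(split(v_low, clone_id), prod, numeric(1))
    agg_h <- vapply(split(v_high, clone_id), prod, numeric(1))
    ids <- as.integer(names(agg_l))
    fitness_low[ids] <- agg_l
    fitness_high[ids] <- agg_h
  }
  ab <- stats::rlnorm(n, 0, config$abundance_sdlog)
  clones <- data.frame(
    clone = seq_len(n),
    abundance = ab / sum(ab),
    fitness_low = fitness_low,
    fitness_high = fitness_high
  )
  list(
    clones = clones, clone_variants = clone_variants,
    truth = truth, orf = orf
  )
}

#' Apply pooled growth selection to clone abundances
#'
#' Under selection each clone grows by `2^(doublings * fitness)`; the
#' nonselective condition leaves abundances untouched.
#'
#' @param clones Clone table from [simulate_clone_library()].
#' @param doublings Population doublings (>= 0).
#' @param condition `"nonselective"`, `"low"` (low-B6 fitness), or `"high"`.
#' @return The clone table with post-selection abundances (renormalized).
#' @export
simulate_selection <- function(clones, doublings = 5.5,
                               condition = c("nonselective", "low", "high")) {
  condition <- match.arg(condition)
  if (doublings < 0) stop("doublings must be >= 0")
  tot <- sum(clones$abundance)
  if (abs(tot - 1) > 1e-6) stop("clone abundances must be normalized")
  if (condition == "nonselective") {
    clones$abundance <- clones$abundance / tot
    return(clones)
  }
  fit <- if (condition == "low") clones$fitness_low else clones$fitness_high
  ab <- clones$abundance * 2^(doublings * fit)
  clones$abundance <- ab / sum(ab)
  clones
}

# Marginal frequency of each codon variant = summed abundance of carriers.
marginal_frequencies <- function(clones, clone_variants) {
  key <- paste0(
    clone_variants$position, ":",
    clone_variants$wt_codon, ">", clone_variants$mut_codon
  )
  ab <- clones$abundance[match(clone_variants$clone, clones$clone)]
  rowsum(ab, key)[, 1]
}

#' Simulate sequencing of all screen conditions
#'
#' Runs selection for each condition, computes per-codon-variant marginal
#' frequencies, and draws Poisson read counts at the configured depth, with
#' a constant spurious background frequency added to every variant. Wildtype
#' control libraries measure the background alone.
#'
#' Conditions emitted: `nonselective`, `select_low_0` and `select_low_1`
#' (the two low-B6 screens, both driven by low-B6 fitness), `select_high`,
#' and `wt_control`.
#'
#' @param library List from [simulate_clone_library()] (or a compatible
#'   `clones` + `clone_variants` pair).
#' @param config The [sim_config()] used to build the library.
#' @return A count table: one row per variant/condition/replicate with
#'   columns `variant_id`, `position`, `wt_codon`, `mut_codon`, `wt_aa`,
#'   `mut_aa`, `condition`, `replicate`, `count`, `depth`.
#' @export
simulate_sequencing <- function(library, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  cv <- unique(library$clone_variants[
    c("position", "wt_codon", "mut_codon", "wt_aa", "mut_aa")
  ])
  cv <- cv[order(cv$position, cv$wt_codon, cv$mut_codon), , drop = FALSE]
  cv$variant_id <- paste0(cv$position, ":", cv$wt_codon, ">", cv$mut_codon)

  cond_fit <- list(
    nonselective = "nonselective",
    select_low_0 = "low",
    select_low_1 = "low",
    select_high = "high"
  )
  out <- list()
  for (cond in names(cond_fit)) {
    post <- simulate_selection(library$clones, config$doublings,
      condition = cond_fit[[cond]]
    )
    mf <- marginal_frequencies(post, library$clone_variants)
    f <- mf[cv$variant_id]
    lambda <- config$depth * (f + config$error_rate)
    for (r in seq_len(config$replicates)) {
      row <- cv
      row$condition <- cond
      row$replicate <- r
      row$count <- stats::rpois(nrow(cv), lambda)
      row$depth <- config$depth
      out[[paste(cond, r)]] <- row
    }
  }
  lambda_bg <- config$depth * config$error_rate
  for (r in seq_len(config$replicates)) {
    row <- cv
    row$condition <- "wt_control"
    row$replicate <- r
    row$count <- stats::rpois(nrow(cv), lambda_bg)
    row$depth <- config$depth
    out[[paste("wt", r)]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c(
    "variant_id", "position", "wt_codon", "mut_codon", "wt_aa", "mut_aa",
    "condition", "replicate", "count", "depth"
  )]
}

#' Run the full generative model
#'
#' Convenience wrapper: clone library + sequencing counts + ground truth.
#'
#' @param config A [sim_config()].
#' @return List with `counts`, `truth`, `library`.
#' @export
simulate_screen <- function(config) {
  lib <- simulate_clone_library(config)
  counts <- simulate_sequencing(lib, config)
  list(counts = counts, truth = lib$truth, library = lib)
}

#' Simulate a screen over a fixed variant panel
#'
#' Builds a library with exactly one clone per variant (no in-cis
#' backgrounds) for a requested number of missense, synonymous, and nonsense
#' protein variants, then sequences it under all conditions. This isolates
#' the count-noise model from the in-cis clone structure and is the
#' workhorse for calibration studies with known truth.
#'
#' @param n_missense,n_synonymous,n_nonsense Panel sizes (protein level; one
#'   representative codon change each).
#' @param config A [sim_config()]; `orf_length_codons` must be large enough
#'   to supply the requested panel.
#' @param null_tolerated Draw non-damaging (tolerated) missense variants at
#'   true fitness exactly 1 instead of the bimodal mixture's [0.7, 1.1]
#'   component. This makes "wildtype-like" exact and is the setting for FDR
#'   calibration studies, where false discoveries are counted among
#'   null-true variants.
#' @return List with `counts`, `truth` (restricted to the panel), `library`.
#' @export
simulate_variant_panel <- function(n_missense, n_synonymous, n_nonsense,
                                   config, null_tolerated = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed)
  orf <- config$orf_seq
  if (is.null(orf)) orf <- random_orf(config$orf_length_codons)
  wt_codons <- orf_codons(orf)
  truth <- assign_true_effects(wt_codons, config)

  pick <- function(cls, nwant) {
    pool <- which(truth$class == cls)
    if (length(pool) < nwant) {
      stop(
        "ORF too short: only ", length(pool), " ", cls,
        " variants available, need ", nwant
      )
    }
    sort(sample(pool, nwant))
  }
  sel <- c(
    pick("missense", n_missense),
    pick("synonymous", n_synonymous),
    pick("nonsense", n_nonsense)
  )
  panel <- truth[sel, , drop = FALSE]
  if (null_tolerated) {
    tol <- panel$class == "missense" & !panel$damaging
    panel$fitness_low[tol] <- 1
    panel$fitness_high[tol] <- 1
  }

  # one representative NNK codon change per protein variant
  nnk <- nnk_codons()
  nnk_aa <- translate_codon(nnk)
  mut_codon <- vapply(seq_len(nrow(panel)), function(i) {
    p <- panel$position[i]
    cands <- nnk[nnk_aa == panel$mut_aa[i] & nnk != wt_codons[p]]
    cands[sample.int(length(cands), 1L)]
  }, character(1))

  n <- nrow(panel)
  clone_variants <- data.frame(
    clone = seq_len(n),
    position = panel$position,
    wt_codon = wt_codons[panel$position],
    mut_codon = mut_codon,
    wt_aa = panel$wt_aa,
    mut_aa = panel$mut_aa
  )
  clones <- data.frame(
    clone = seq_len(n),
    abundance = rep(1 / n, n),
    fitness_low = panel$fitness_low,
    fitness_high = panel$fitness_high
  )
  lib <- list(
    clones = clones, clone_variants = clone_variants,
    truth = panel, orf = orf
  )
  counts <- simulate_sequencing(lib, config)
  list(counts = counts, truth = panel, library = lib)
}

#' Read or write the count-table TSV dialect
#'
#' @param counts Count table data.frame.
#' @param path File path.
#' @return `read_count_table` returns the count table data.frame.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(counts, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  utils::read.delim(path, colClasses = c(
    variant_id = "character", wt_codon = "character",
    mut_codon = "character", wt_aa = "character", mut_aa = "character",
    condition = "character"
  ))
}

#' Simulate a patient cohort with ordinal phenotypes
#'
#' Draws diploid genotypes from the damaging end of a true-effect table
#' (with a skewed variant-recurrence distribution so that cohort reduction
#' has something to do), computes true diploid scores under the
#' multiplicative-in-cis / additive-in-trans model, and assigns ordinal
#' phenotypes by monotone binning of the true scores with optional Gaussian
#' noise on the latent scale.
#'
#' Severity: 5 bins of the low-B6 diploid score (1 = most severe).
#' B6 response: 4 bins of the diploid delta score (4 = most responsive).
#' Onset age increases with the low-B6 diploid score.
#'
#' @param truth True-effect table from the generator.
#' @param n_patients Number of patients (>= 1).
#' @param noise Standard deviation of latent Gaussian noise added to the
#'   true scores before binning (0 = deterministic phenotypes).
#' @param seed Integer seed.
#' @return List with `cohort` (patient table) and `truth_scores` (per
#'   patient: true diploid low/high/delta scores).
#' @export
simulate_cohort <- function(truth, n_patients, noise = 0.3, seed = 1) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (nrow(truth) == 0) stop("truth table is empty")
  set.seed(seed)
  pool <- truth[truth$class == "nonsense" |
    (truth$class == "missense" & truth$fitness_low < 0.7), , drop = FALSE]
  if (nrow(pool) == 0) stop("truth table has no damaging variants")
  # zipf-like recurrence so a few variants dominate the cohort
  w <- 1 / rank(stats::runif(nrow(pool)))^1.5
  draw_allele <- function() {
    k <- 1 + (stats::runif(1) < 0.2)
    idx <- sample.int(nrow(pool), min(k, nrow(pool)), prob = w)
    pool$hgvs[idx]
  }
  fit_of <- function(hgvs, col) {
    f <- pool[[col]][match(hgvs, pool$hgvs)]
    prod(pmin(pmax(f, 0), 1))
  }
  alleles1 <- replicate(n_patients, draw_allele(), simplify = FALSE)
  alleles2 <- replicate(n_patients, draw_allele(), simplify = FALSE)
  low <- vapply(seq_len(n_patients), function(i) {
    fit_of(alleles1[[i]], "fitness_low") + fit_of(alleles2[[i]], "fitness_low")
  }, numeric(1))
  high <- vapply(seq_len(n_patients), function(i) {
    fit_of(alleles1[[i]], "fitness_high") +
      fit_of(alleles2[[i]], "fitness_high")
  }, numeric(1))
  delta <- high - low

  # noise is scale-free: its SD is `noise` times the cohort's true score
  # spread, so noise = 0.3 means a 30% noise-to-signal ratio regardless of
  # how compressed the diploid scores are
  sd_guard <- function(x) if (stats::sd(x) > 0) stats::sd(x) else 1
  lat_low <- low + stats::rnorm(n_patients, 0, noise * sd_guard(low))
  lat_delta <- delta + stats::rnorm(n_patients, 0, noise * sd_guard(delta))
  # quantile bins keep the five severity classes populated across the
  # cohort's realized score range (fixed-width bins over [0, 2] would leave
  # the mild classes empty in a biallelic disease cohort)
  sev_breaks <- unique(stats::quantile(lat_low, probs = seq(0, 1, 0.2)))
  severity <- if (length(sev_breaks) < 2) {
    rep(1L, n_patients)
  } else {
    cut(lat_low,
      breaks = c(-Inf, sev_breaks[-c(1, length(sev_breaks))], Inf),
      labels = FALSE
    )
  }
  b6_response <- cut(pmin(pmax(lat_delta, 0), 2),
    breaks = c(0, 0.1, 0.35, 0.7, 2),
    labels = FALSE, include.lowest = TRUE
  )
  onset_age <- round(pmax(0.2, 1 + 20 * pmax(lat_low, 0)), 1)

  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    allele1 = vapply(alleles1, paste, character(1), collapse = ";"),
    allele2 = vapply(alleles2, paste, character(1), collapse = ";"),
    phase_confirmed = TRUE,
    onset_age = onset_age,
    severity = as.integer(severity),
    b6_response = as.integer(b6_response)
  )
  truth_scores <- data.frame(
    patient_id = cohort$patient_id,
    true_low = low, true_high = high, true_delta = delta
  )
  list(cohort = cohort, truth_scores = truth_scores)
}
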