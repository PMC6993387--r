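# End-to-end orchestration from a single configuration: simulate (or load
# counts) -> frequencies -> score -> classify -> impute -> evaluate ->
# patients. Every stage writes a TSV so any stage can be re-run from the
# saved intermediates.

#' Default pipeline configuration
#'
#' All stage parameters in one nested list, mirroring the screen's stated
#' settings: 0.005% pre-selection frequency filter, SE < 0.2, FDR q = 0.05,
#' 10 cross-validation folds.
#'
#' @param out_dir Output directory for stage TSVs.
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(out_dir = tempfile("cbsmap_run_"), seed = 42) {
  list(
    out_dir = out_dir,
    seed = seed,
    simulate = list(
      enabled = TRUE, counts_file = NULL,
      orf_length_codons = 100, n_clones = 1000, depth = 1e5,
      mutation_load_lambda = 2.65, doublings = 5.5, error_rate = 1e-6,
      fraction_deleterious = 0.4, fraction_remediable = 0.2, replicates = 2
    ),
    conditions = list(
      low = c("select_low_0", "select_low_1"), high = "select_high"
    ),
    score = list(min_freq = 5e-5, max_se = 0.2, pooled_anchors = FALSE,
      pooled_ctrl_sd = FALSE),
    classify = list(q = 0.05),
    impute = list(
      enabled = TRUE, folds = 10, nrounds = 500, max_depth = 4, eta = 0.05
    ),
    evaluate = list(reference_file = NULL),
    patients = list(
      cohort_file = NULL, simulate_n = 50, noise = 0.3,
      exclude_regulatory = FALSE, max_occurrence = 3
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_lists(base[[k]], over[[k]])
      } else {
        over[[k]]
      }
    }
    base
  }
  merge_lists(default_config(), user)
}

#' Validate a pipeline configuration
#'
#' Collects every problem at once; nothing is executed.
#'
#' @param config Configuration list.
#' @return Character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  q <- config$classify$q
  if (!is.numeric(q) || q <= 0 || q >= 1) {
    add("classify$q must be in (0, 1)")
  }
  if (!is.null(config$simulate$depth) && config$simulate$depth < 0) {
    add("simulate$depth must be >= 0")
  }
  if (!is.null(config$simulate$error_rate) &&
    (config$simulate$error_rate < 0 || config$simulate$error_rate > 1)) {
    add("simulate$error_rate must be in [0, 1]")
  }
  if (!is.numeric(config$seed) || config$seed != round(config$seed)) {
    add("seed must be an integer")
  }
  for (f in c(
    config$simulate$counts_file, config$evaluate$reference_file,
    config$patients$cohort_file
  )) {
    if (!is.null(f) && !file.exists(f)) {
      add(paste0("input file does not exist: ", f))
    }
  }
  if (!isTRUE(config$simulate$enabled) &&
    is.null(config$simulate$counts_file)) {
    add("either simulate$enabled or simulate$counts_file is required")
  }
  errs
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order, writing each stage's table under
#' `config$out_dir` together with a run log of parameters and seeds. When
#' the high-B6 condition is absent the delta/remediability stages are
#' skipped with a logged notice.
#'
#' @param config Configuration list (see [default_config()]); invalid
#'   configurations fail before any stage executes.
#' @return Named character vector: manifest of produced artifact paths.
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs) > 0) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  log_lines <- c(
    paste0("cbsmap ", as.character(utils::packageVersion("cbsmap"))),
    paste0("seed: ", config$seed)
  )
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    manifest[[name]] <<- path
    log_lines <<- c(log_lines, paste0("wrote ", name))
  }

  # --- simulate or load counts ---------------------------------------------
  truth <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sc <- config$simulate
    cfg <- sim_config(
      orf_length_codons = sc$orf_length_codons,
      mutation_load_lambda = sc$mutation_load_lambda,
      n_clones = sc$n_clones, doublings = sc$doublings, depth = sc$depth,
      error_rate = sc$error_rate,
      fraction_deleterious = sc$fraction_deleterious,
      fraction_remediable = sc$fraction_remediable,
      replicates = sc$replicates, seed = config$seed
    )
    sim <- simulate_screen(cfg)
    counts <- sim$counts
    truth <- sim$truth
    emit("counts.tsv", function(p) write_count_table(counts, p))
    emit("truth.tsv", function(p) {
      utils::write.table(truth, p, sep = "\t", quote = FALSE,
        row.names = FALSE)
    })
  } else {
    counts <- read_count_table(config$simulate$counts_file)
    log_lines <- c(log_lines, paste0(
      "loaded counts from ", config$simulate$counts_file
    ))
  }

  # --- frequencies and scoring ---------------------------------------------
  adjusted <- prepare_frequencies(counts,
    pooled_sd = isTRUE(config$score$pooled_ctrl_sd))
  low_conds <- intersect(config$conditions$low, counts$condition)
  if (length(low_conds) == 0) stop("no low-B6 condition present in counts")
  low_maps <- lapply(low_conds, function(cond) {
    score_map(adjusted, cond, pooled_anchors = config$score$pooled_anchors)
  })
  low_map <- if (length(low_maps) == 2) {
    combine_low_b6(low_maps[[1]], low_maps[[2]])
  } else {
    low_maps[[1]]
  }
  flt_low <- well_measured_filter(low_map,
    min_freq = config$score$min_freq, max_se = config$score$max_se
  )
  emit("map_low.tsv", function(p) write_map(flt_low$kept, p))

  has_high <- any(config$conditions$high %in% counts$condition)
  flt_high <- NULL
  if (has_high) {
    high_map <- score_map(adjusted, config$conditions$high[1],
      pooled_anchors = config$score$pooled_anchors
    )
    flt_high <- well_measured_filter(high_map,
      min_freq = config$score$min_freq, max_se = config$score$max_se
    )
    emit("map_high.tsv", function(p) write_map(flt_high$kept, p))
  } else {
    log_lines <- c(
      log_lines,
      "notice: high-B6 condition absent; delta/remediability stages skipped"
    )
  }

  # --- classification ------------------------------------------------------
  if (has_high) {
    cls <- classify_variants(flt_low$kept, flt_high$kept,
      q = config$classify$q
    )
    emit("calls.tsv", function(p) write_calls(cls, p))
    log_lines <- c(log_lines, paste0(
      "fdr thresholds: fitness=", signif(cls$fdr_threshold_fitness, 4),
      " delta=", signif(cls$fdr_threshold_delta, 4)
    ))
  }

  # --- imputation / refinement ---------------------------------------------
  maps_final <- list(low = flt_low$kept)
  if (has_high) maps_final$high <- flt_high$kept
  if (isTRUE(config$impute$enabled)) {
    ic <- config$impute
    for (cond in names(maps_final)) {
      flt <- if (cond == "low") flt_low else flt_high
      imp <- impute_map(flt$kept,
        targets = flt$dropped,
        folds = ic$folds, seed = config$seed, nrounds = ic$nrounds,
        max_depth = ic$max_depth, eta = ic$eta
      )
      emit(paste0("refined_", cond, ".tsv"), function(p) {
        out <- imp$refined
        names(out)[names(out) == "hgvs"] <- "hgvs_pro"
        out$condition <- cond
        utils::write.table(out, p, sep = "\t", quote = FALSE,
          row.names = FALSE)
      })
      log_lines <- c(log_lines, paste0(
        "impute[", cond, "]: cv rmsd=", signif(imp$model$rmsd, 3),
        " pearson=", signif(imp$model$pearson_r, 3)
      ))
    }
  }

  # --- reference-set evaluation --------------------------------------------
  if (!is.null(config$evaluate$reference_file)) {
    refset <- read_reference_set(config$evaluate$reference_file)
    pr <- precision_recall(
      maps_final$low[c("hgvs", "score")],
      positive = refset$hgvs[refset$label == "positive"],
      negative = refset$hgvs[refset$label == "negative"]
    )
    ll <- llr(
      maps_final$low$score,
      positive_scores = maps_final$low$score[
        maps_final$low$hgvs %in% refset$hgvs[refset$label == "positive"]
      ],
      negative_scores = maps_final$low$score[
        maps_final$low$hgvs %in% refset$hgvs[refset$label == "negative"]
      ]
    )
    ll$hgvs_pro <- maps_final$low$hgvs
    emit("llr.tsv", function(p) {
      utils::write.table(ll, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    log_lines <- c(log_lines, paste0("auprc(low)=", signif(pr$auprc, 4)))
  }

  # --- patients ------------------------------------------------------------
  if (has_high) {
    pc <- config$patients
    if (!is.null(pc$cohort_file)) {
      cohort <- read_cohort(pc$cohort_file)
    } else if (!is.null(truth)) {
      cohort <- simulate_cohort(truth, pc$simulate_n,
        noise = pc$noise,
        seed = config$seed + 2
      )$cohort
    } else {
      cohort <- NULL
      log_lines <- c(
        log_lines,
        "notice: no cohort file and no simulation truth; patients skipped"
      )
    }
    if (!is.null(cohort)) {
      red <- reduce_cohort(cohort, max_occurrence = pc$max_occurrence)
      dsc <- score_cohort(red$cohort, maps_final$low, maps_final$high,
        exclude_regulatory = isTRUE(pc$exclude_regulatory),
        unresolved = 1
      )
      corr <- correlate_phenotypes(red$cohort, dsc)
      emit("cohort_reduced.tsv", function(p) write_cohort(red$cohort, p))
      emit("cohort_removals.tsv", function(p) {
        utils::write.table(red$log, p, sep = "\t", quote = FALSE,
          row.names = FALSE)
      })
      emit("diploid_scores.tsv", function(p) {
        utils::write.table(dsc, p, sep = "\t", quote = FALSE,
          row.names = FALSE)
      })
      emit("phenotype_correlations.tsv", function(p) {
        utils::write.table(corr, p, sep = "\t", quote = FALSE,
          row.names = FALSE)
      })
    }
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  manifest[["run_log.txt"]] <- file.path(config$out_dir, "run_log.txt")
  manifest
}
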