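# Count table -> background-corrected amino-acid-level allele frequencies.
# Fixed pipeline order: normalize -> wildtype-threshold filter -> collapse
# equivalent codons -> subtract background.

#' Depth-normalize counts to allele frequencies
#'
#' Frequency = count / depth per row. Wildtype-control summary statistics
#' (mean and SD of control-replicate frequencies) are attached to every
#' variant; with a single control replicate the SD falls back to the Poisson
#' estimate `sqrt(f / depth)`. Rows with non-positive depth are rejected
#' with a warning.
#'
#' @param counts Count table (`variant_id`, `position`, `wt_codon`,
#'   `mut_codon`, `wt_aa`, `mut_aa`, `condition`, `replicate`, `count`,
#'   `depth`); the `wt_control` condition carries the control libraries.
#' @return A frequency table: the non-control rows with a `frequency`
#'   column, plus `ctrl_mean` and `ctrl_sd` per variant.
#' @export
normalize_counts <- function(counts) {
  bad <- counts$depth <= 0
  if (any(bad)) {
    warning(sum(bad), " rows with non-positive depth rejected")
    counts <- counts[!bad, , drop = FALSE]
  }
  counts$frequency <- counts$count / counts$depth

  ctrl <- counts[counts$condition == "wt_control", , drop = FALSE]
  main <- counts[counts$condition != "wt_control", , drop = FALSE]
  if (nrow(ctrl) > 0) {
    sp <- split(ctrl$frequency, ctrl$variant_id)
    cm <- vapply(sp, mean, numeric(1))
    cs <- vapply(sp, function(x) {
      if (length(x) >= 2) stats::sd(x) else NA_real_
    }, numeric(1))
    # single-replicate fallback: Poisson sampling error of the frequency
    dp <- vapply(split(ctrl$depth, ctrl$variant_id), `[`, numeric(1), 1)
    cs[is.na(cs)] <- sqrt(cm[is.na(cs)] / dp[is.na(cs)])
    i <- match(main$variant_id, names(cm))
    main$ctrl_mean <- ifelse(is.na(i), 0, cm[i])
    main$ctrl_sd <- ifelse(is.na(i), 0, cs[i])
  } else {
    main$ctrl_mean <- 0
    main$ctrl_sd <- 0
  }
  rownames(main) <- NULL
  main
}

#' Filter variants against the wildtype-control threshold
#'
#' A variant is kept for a selective condition only if, in every replicate,
#' both its selective and its nonselective frequency exceed
#' `ctrl_mean + 3 * ctrl_sd`. Nonselective rows are kept when they pass the
#' threshold in every nonselective replicate.
#'
#' @param freqs Frequency table from [normalize_counts()].
#' @param pooled_sd Use one pooled control SD across variants instead of the
#'   per-variant SD.
#' @return Filtered frequency table.
#' @export
filter_by_wt_threshold <- function(freqs, pooled_sd = FALSE) {
  sd_use <- if (pooled_sd) {
    sqrt(mean(freqs$ctrl_sd^2)) # root-mean-square SD across variants
  } else {
    freqs$ctrl_sd
  }
  thr <- freqs$ctrl_mean + 3 * sd_use
  pass_row <- freqs$frequency > thr

  # variant passes a condition iff it passes in all that condition's reps
  key <- paste(freqs$variant_id, freqs$condition)
  pass_cond <- vapply(split(pass_row, key), all, logical(1))
  nonsel_key <- paste(freqs$variant_id, "nonselective")
  pass_nonsel <- pass_cond[nonsel_key]
  pass_nonsel[is.na(pass_nonsel)] <- FALSE

  keep <- pass_cond[key] & pass_nonsel
  out <- freqs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse equivalent codons to amino-acid variants
#'
#' Frequencies of codon variants encoding the same amino-acid change are
#' summed per condition/replicate; control means are summed and control
#' variances are summed (SDs combined in quadrature).
#'
#' @param freqs Codon-level frequency table.
#' @return Amino-acid-level table keyed by (`position`, `wt_aa`, `mut_aa`)
#'   with `hgvs` names and a `class` column.
#' @export
collapse_codons_to_aa <- function(freqs) {
  key <- paste(
    freqs$position, freqs$wt_aa, freqs$mut_aa,
    freqs$condition, freqs$replicate
  )
  first <- !duplicated(key)
  out <- freqs[first, c(
    "position", "wt_aa", "mut_aa", "condition",
    "replicate", "depth"
  ), drop = FALSE]
  out$frequency <- rowsum(freqs$frequency, key)[key[first], 1]
  out$ctrl_mean <- rowsum(freqs$ctrl_mean, key)[key[first], 1]
  out$ctrl_sd <- sqrt(rowsum(freqs$ctrl_sd^2, key)[key[first], 1])
  out$hgvs <- hgvs_pro(out$wt_aa, out$position, out$mut_aa)
  out$class <- variant_class(out$wt_aa, out$mut_aa)
  rownames(out) <- NULL
  out
}

#' Subtract the wildtype-control background
#'
#' Adjusted frequency = frequency - control mean. Non-positive results are
#' floored at the smallest observable frequency `1 / depth` and flagged, so
#' downstream log-ratios stay finite.
#'
#' @param freqs Collapsed amino-acid-level frequency table.
#' @return The table with `adj_frequency` and a `floored` flag.
#' @export
subtract_wt_background <- function(freqs) {
  adj <- freqs$frequency - freqs$ctrl_mean
  floor_at <- 1 / freqs$depth
  freqs$floored <- adj <= 0
  freqs$adj_frequency <- ifelse(adj <= 0, floor_at, adj)
  freqs
}

#' Run the whole frequency stage
#'
#' normalize -> filter -> collapse -> subtract, in that order.
#'
#' @param counts Count table.
#' @param pooled_sd Passed to [filter_by_wt_threshold()].
#' @return Adjusted amino-acid-level frequency table.
#' @export
prepare_frequencies <- function(counts, pooled_sd = FALSE) {
  subtract_wt_background(
    collapse_codons_to_aa(
      filter_by_wt_threshold(normalize_counts(counts), pooled_sd = pooled_sd)
    )
  )
}
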