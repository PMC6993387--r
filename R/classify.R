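# Delta (B6-remediability) scores and FDR-controlled calls against
# empirical nulls: synonymous fitness scores are the null for deleterious
# calls, nonsense delta scores the null for remediability calls.

#' Delta scores between B6 conditions
#'
#' delta = score(high B6) - score(low B6), with SEs propagated in
#' quadrature. Variants missing from either map are omitted.
#'
#' @param high_map,low_map Variant-effect maps of the high- and low-B6
#'   conditions.
#' @return data.frame with `hgvs`, `class`, `score_low`, `score_high`,
#'   `se_low`, `se_high`, `delta`, `se_delta`.
#' @export
delta_scores <- function(high_map, low_map) {
  common <- intersect(high_map$hgvs, low_map$hgvs)
  ih <- match(common, high_map$hgvs)
  il <- match(common, low_map$hgvs)
  data.frame(
    hgvs = common,
    position = low_map$position[il],
    class = low_map$class[il],
    score_low = low_map$score[il],
    score_high = high_map$score[ih],
    se_low = low_map$se[il],
    se_high = high_map$se[ih],
    delta = high_map$score[ih] - low_map$score[il],
    se_delta = sqrt(high_map$se[ih]^2 + low_map$se[il]^2)
  )
}

#' Empirical-null FDR threshold
#'
#' Assigns each test score a one-sided empirical p-value against the null
#' scores with add-one smoothing, `p = (#null at-or-beyond + 1) / (N + 1)`,
#' applies Benjamini-Hochberg adjustment, and returns the most extreme test
#' score whose q-value is at or below `q` (the largest such score for the
#' lower tail, the smallest for the upper tail).
#'
#' @param test_scores Scores to be called (e.g. missense).
#' @param null_scores Empirical null scores (e.g. synonymous).
#' @param q Nominal FDR level.
#' @param tail `"lower"` (small scores are discoveries) or `"upper"`.
#' @return List with `threshold` (`NA` when nothing passes), `p`, `q_values`
#'   and the logical `discovery` vector aligned with `test_scores`.
#' @export
empirical_fdr_threshold <- function(test_scores, null_scores, q = 0.05,
                                    tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (length(null_scores) == 0) stop("null score set is empty")
  if (length(test_scores) == 0) {
    return(list(
      threshold = NA_real_, p = numeric(0), q_values = numeric(0),
      discovery = logical(0)
    ))
  }
  beyond <- if (tail == "lower") {
    vapply(test_scores, function(s) sum(null_scores <= s), numeric(1))
  } else {
    vapply(test_scores, function(s) sum(null_scores >= s), numeric(1))
  }
  p <- (beyond + 1) / (length(null_scores) + 1)
  qv <- stats::p.adjust(p, method = "BH")
  disc <- qv <= q
  threshold <- if (!any(disc)) {
    NA_real_
  } else if (tail == "lower") {
    max(test_scores[disc])
  } else {
    min(test_scores[disc])
  }
  list(threshold = threshold, p = p, q_values = qv, discovery = disc)
}

#' Call deleterious variants
#'
#' A variant is deleterious when the upper end of the 95% confidence
#' interval of its fitness score falls below the threshold:
#' `score + 1.96 * se < threshold`.
#'
#' @param map Variant-effect map with `score` and `se`.
#' @param threshold Fitness-score threshold (derive it from the synonymous
#'   null with [empirical_fdr_threshold()]; 0.60 was the value realized at
#'   FDR 5% in the original screen).
#' @return Logical vector aligned with `map` (`FALSE` when `threshold` is
#'   `NA`).
#' @export
classify_deleterious <- function(map, threshold = 0.60) {
  if (is.na(threshold)) {
    return(rep(FALSE, nrow(map)))
  }
  map$score + 1.96 * map$se < threshold
}

#' Call B6-remediable variants
#'
#' Evaluated only for variants deleterious at low B6: remediable when the
#' lower end of the 95% CI of the delta score exceeds the threshold:
#' `delta - 1.96 * se_delta > threshold`.
#'
#' @param deltas Delta-score table from [delta_scores()].
#' @param deleterious Logical vector aligned with `deltas`.
#' @param threshold Delta threshold (derive from the nonsense-delta null;
#'   0.22 was the value realized at FDR 5% in the original screen).
#' @return Logical vector; `NA` (not applicable) for non-deleterious
#'   variants.
#' @export
classify_remediable <- function(deltas, deleterious, threshold = 0.22) {
  call <- rep(NA, nrow(deltas))
  if (!is.na(threshold)) {
    call[deleterious] <-
      (deltas$delta - 1.96 * deltas$se_delta > threshold)[deleterious]
  } else {
    call[deleterious] <- FALSE
  }
  call
}

#' Classify a pair of maps end to end
#'
#' Derives the deleterious threshold from the synonymous fitness-score null
#' and the remediable threshold from the nonsense delta-score null (both at
#' FDR `q`), then applies the 95%-CI call rules. Thresholds are re-derived
#' from the supplied data rather than fixed, and are recorded in the result.
#'
#' @param low_map,high_map Variant-effect maps (measured variants only; the
#'   nulls pool all synonymous / nonsense variants present).
#' @param q Nominal FDR level.
#' @return List with `calls` (per missense variant: scores, delta,
#'   `deleterious`, `remediable`, `q_fitness`, `q_delta`),
#'   `fdr_threshold_fitness`, `fdr_threshold_delta`.
#' @export
classify_variants <- function(low_map, high_map, q = 0.05) {
  deltas <- delta_scores(high_map, low_map)
  mis <- deltas[deltas$class == "missense", , drop = FALSE]
  syn_null <- low_map$score[low_map$class == "synonymous"]
  non_null <- deltas$delta[deltas$class == "nonsense"]

  fit_fdr <- empirical_fdr_threshold(mis$score_low, syn_null,
    q = q, tail = "lower"
  )
  deleterious <- classify_deleterious(
    data.frame(score = mis$score_low, se = mis$se_low),
    fit_fdr$threshold
  )
  # delta scores exist only for variants deleterious at low B6, so the
  # delta FDR adjustment runs over that subset
  delta_fdr <- empirical_fdr_threshold(mis$delta[deleterious], non_null,
    q = q, tail = "upper"
  )
  remediable <- classify_remediable(mis, deleterious, delta_fdr$threshold)

  q_delta <- rep(NA_real_, nrow(mis))
  q_delta[deleterious] <- delta_fdr$q_values
  calls <- data.frame(
    hgvs = mis$hgvs,
    score_low = mis$score_low,
    score_high = mis$score_high,
    delta = mis$delta,
    deleterious = deleterious,
    remediable = remediable,
    q_fitness = fit_fdr$q_values,
    q_delta = q_delta
  )
  list(
    calls = calls,
    fdr_threshold_fitness = fit_fdr$threshold,
    fdr_threshold_delta = delta_fdr$threshold
  )
}

#' Write classification calls as TSV
#'
#' @param classification Result of [classify_variants()].
#' @param path File path.
#' @export
write_calls <- function(classification, path) {
  out <- classification$calls
  names(out)[names(out) == "hgvs"] <- "hgvs_pro"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
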