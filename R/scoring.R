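# Enrichment ratios and anchored fitness scores. Scores are anchored so the
# median nonsense variant maps to 0 and the median synonymous variant to 1:
#   s = ln(phi_mut / phi_stop) / ln(phi_syn / phi_stop)
# Errors are regularized against a coverage/fitness-dependent prior with two
# pseudocounts (weights n/(n+2) observed, 2/(n+2) prior).

#' Enrichment ratio of a variant
#'
#' Ratio of background-adjusted selective to nonselective allele frequency.
#'
#' @param adjusted_selective,adjusted_nonselective Background-adjusted
#'   frequencies (post-floor, so > 0).
#' @return Numeric vector of ratios; rows with non-positive nonselective
#'   frequency come back `NA` (dropped downstream).
#' @export
enrichment_ratio <- function(adjusted_selective, adjusted_nonselective) {
  ifelse(adjusted_nonselective > 0,
    adjusted_selective / adjusted_nonselective, NA_real_
  )
}

#' Anchored fitness score
#'
#' `s = ln(phi_mut/phi_stop) / ln(phi_syn/phi_stop)`: 0 at the nonsense
#' anchor, 1 at the synonymous anchor.
#'
#' @param phi_mut Enrichment ratio(s) of the variant(s).
#' @param phi_stop Median enrichment ratio of nonsense variants.
#' @param phi_syn Median enrichment ratio of synonymous variants.
#' @return Numeric vector of fitness scores.
#' @export
fitness_score <- function(phi_mut, phi_stop, phi_syn) {
  if (any(c(phi_stop, phi_syn) <= 0)) stop("anchors must be positive")
  if (phi_syn <= phi_stop) {
    stop(
      "anchor failure: synonymous median enrichment (", signif(phi_syn, 4),
      ") does not exceed nonsense median (", signif(phi_stop, 4),
      "); selection failed"
    )
  }
  log(phi_mut / phi_stop) / log(phi_syn / phi_stop)
}

#' Baldi-Long error regularization
#'
#' Maximum-a-posteriori variance with two pseudocounts:
#' `sigma^2 = (n * observed_var + 2 * prior_var) / (n + 2)`.
#'
#' @param observed_var Across-replicate sample variance (`NA` allowed when
#'   fewer than 2 replicates; the prior is then used alone).
#' @param prior_var Prior variance from the coverage/fitness regression.
#' @param n Replicate count (>= 1).
#' @return List with `sigma` (regularized SD) and `se` (`sigma / sqrt(n)`).
#' @export
regularize_error <- function(observed_var, prior_var, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(stats::na.omit(c(observed_var, prior_var)) < 0)) {
    stop("variances must be >= 0")
  }
  obs <- ifelse(is.na(observed_var), prior_var, observed_var)
  sigma2 <- (n * obs + 2 * prior_var) / (n + 2)
  sigma <- sqrt(sigma2)
  list(sigma = sigma, se = sigma / sqrt(n))
}

#' Fit the prior error model
#'
#' Regresses log coefficient-of-variation on log sequencing coverage and
#' fitness score across variants measured in at least two replicates; the
#' fit supplies the prior SD for error regularization. With fewer than 30
#' usable variants the model falls back to the global median CV.
#'
#' CV is computed against `max(|score|, score_floor)` so scores near zero do
#' not blow up the relative error.
#'
#' @param score,sd_obs,coverage Per-variant replicate-mean score, observed
#'   across-replicate SD, and nonselective read count.
#' @param score_floor Floor on `|score|` in the CV denominator.
#' @return Object of class `prior_model`: `predict(model, coverage, score)`
#'   returns a positive prior SD.
#' @export
prior_variance_model <- function(score, sd_obs, coverage, score_floor = 0.1) {
  ok <- !is.na(sd_obs) & sd_obs > 0 & !is.na(coverage) & coverage > 0 &
    !is.na(score)
  denom <- pmax(abs(score), score_floor)
  cv <- sd_obs / denom
  m <- list(score_floor = score_floor)
  if (sum(ok) >= 30) {
    fit <- stats::lm(log(cv[ok]) ~ log(coverage[ok]) + score[ok])
    m$coef <- unname(stats::coef(fit))
    m$type <- "regression"
  } else {
    m$median_cv <- stats::median(cv[ok])
    if (!is.finite(m$median_cv)) m$median_cv <- 0.1
    m$type <- "median"
  }
  class(m) <- "prior_model"
  m
}

#' @param object A `prior_model`.
#' @param coverage,score Points at which to predict the prior SD.
#' @param ... Unused.
#' @rdname prior_variance_model
#' @export
predict.prior_model <- function(object, coverage, score, ...) {
  denom <- pmax(abs(score), object$score_floor)
  cv <- if (object$type == "regression") {
    exp(object$coef[1] + object$coef[2] * log(pmax(coverage, 1)) +
      object$coef[3] * score)
  } else {
    rep(object$median_cv, length(score))
  }
  pmax(cv * denom, .Machine$double.eps)
}

#' Score one selective condition
#'
#' Per replicate, computes enrichment ratios against the matching
#' nonselective replicate, anchors them on that replicate's nonsense and
#' synonymous medians, and scores. Replicate scores are then averaged, the
#' observed across-replicate variance is regularized against the fitted
#' prior, and standard errors are attached.
#'
#' @param adjusted Adjusted amino-acid-level frequency table from
#'   [prepare_frequencies()].
#' @param condition Which selective condition to score (e.g.
#'   `"select_low_0"`).
#' @param pooled_anchors Compute the anchor medians from replicate-pooled
#'   enrichment ratios instead of per replicate.
#' @return A variant-effect map: data.frame with `hgvs`, `position`,
#'   `wt_aa`, `mut_aa`, `class`, `score`, `sd`, `se`, `df`,
#'   `pre_selection_freq`, `condition`; anchors recorded in
#'   `attr(, "anchors")`.
#' @export
score_map <- function(adjusted, condition, pooled_anchors = FALSE) {
  sel <- adjusted[adjusted$condition == condition, , drop = FALSE]
  nonsel <- adjusted[adjusted$condition == "nonselective", , drop = FALSE]
  if (nrow(sel) == 0) stop("no rows for condition ", condition)
  reps <- sort(unique(sel$replicate))

  per_rep <- lapply(reps, function(r) {
    s <- sel[sel$replicate == r, , drop = FALSE]
    n <- nonsel[nonsel$replicate == r, , drop = FALSE]
    i <- match(s$hgvs, n$hgvs)
    keep <- !is.na(i)
    s <- s[keep, , drop = FALSE]
    i <- i[keep]
    phi <- enrichment_ratio(s$adj_frequency, n$adj_frequency[i])
    data.frame(
      hgvs = s$hgvs, position = s$position, wt_aa = s$wt_aa,
      mut_aa = s$mut_aa, class = s$class, replicate = r, phi = phi,
      nonsel_freq = n$frequency[i],
      nonsel_count = n$frequency[i] * n$depth[i]
    )
  })
  per_rep <- do.call(rbind, per_rep)
  per_rep <- per_rep[!is.na(per_rep$phi), , drop = FALSE]

  if (pooled_anchors) {
    phi_stop <- stats::median(per_rep$phi[per_rep$class == "nonsense"])
    phi_syn <- stats::median(per_rep$phi[per_rep$class == "synonymous"])
    anchors <- data.frame(
      replicate = NA_integer_, phi_stop = phi_stop, phi_syn = phi_syn
    )
    per_rep$score <- fitness_score(per_rep$phi, phi_stop, phi_syn)
  } else {
    anchors <- do.call(rbind, lapply(reps, function(r) {
      rows <- per_rep$replicate == r
      data.frame(
        replicate = r,
        phi_stop = stats::median(per_rep$phi[rows &
          per_rep$class == "nonsense"]),
        phi_syn = stats::median(per_rep$phi[rows &
          per_rep$class == "synonymous"])
      )
    }))
    per_rep$score <- NA_real_
    for (r in reps) {
      rows <- per_rep$replicate == r
      a <- anchors[anchors$replicate == r, ]
      per_rep$score[rows] <- fitness_score(
        per_rep$phi[rows], a$phi_stop, a$phi_syn
      )
    }
  }

  key <- per_rep$hgvs
  n_rep <- rowsum(rep(1, nrow(per_rep)), key)[, 1]
  s_sum <- rowsum(per_rep$score, key)[, 1]
  s_sq <- rowsum(per_rep$score^2, key)[, 1]
  score_mean <- s_sum / n_rep
  var_obs <- ifelse(n_rep >= 2,
    pmax((s_sq - n_rep * score_mean^2) / (n_rep - 1), 0), NA_real_
  )
  first <- per_rep[!duplicated(key), , drop = FALSE]
  ord <- match(names(n_rep), first$hgvs)
  map <- data.frame(
    hgvs = first$hgvs[ord], position = first$position[ord],
    wt_aa = first$wt_aa[ord], mut_aa = first$mut_aa[ord],
    class = first$class[ord],
    score = score_mean,
    var_obs = var_obs,
    df = n_rep,
    coverage = rowsum(per_rep$nonsel_count, key)[, 1] / n_rep,
    pre_selection_freq = rowsum(per_rep$nonsel_freq, key)[, 1] / n_rep
  )
  rownames(map) <- NULL

  prior <- prior_variance_model(
    map$score, sqrt(map$var_obs), map$coverage
  )
  prior_sd <- predict(prior, map$coverage, map$score)
  reg <- regularize_error(map$var_obs, prior_sd^2, map$df)
  map$sd <- reg$sigma
  map$se <- reg$se
  map$condition <- condition
  map <- map[order(map$position, map$mut_aa), c(
    "hgvs", "position", "wt_aa", "mut_aa", "class", "score", "sd", "se",
    "df", "pre_selection_freq", "condition"
  )]
  rownames(map) <- NULL
  attr(map, "anchors") <- anchors
  attr(map, "prior_model") <- prior
  map
}

#' Merge the two low-B6 maps
#'
#' The 0 and 1 ng/ml vitamin-B6 screens measure the same condition class and
#' are averaged: per variant, the score is the arithmetic mean of the
#' available scores; when both are present the combined SE is
#' `sqrt(se0^2 + se1^2) / 2`; single-source variants pass through.
#'
#' @param map0,map1 Variant-effect maps of the two low-B6 screens.
#' @param inverse_variance Weight by 1/se^2 instead of a plain mean.
#' @return Combined map labeled `condition = "low"`.
#' @export
combine_low_b6 <- function(map0, map1, inverse_variance = FALSE) {
  all_hgvs <- union(map0$hgvs, map1$hgvs)
  i0 <- match(all_hgvs, map0$hgvs)
  i1 <- match(all_hgvs, map1$hgvs)
  both <- !is.na(i0) & !is.na(i1)
  out <- map0[rep(1, length(all_hgvs)), , drop = FALSE]
  for (col in names(map0)) {
    v0 <- map0[[col]][i0]
    v1 <- map1[[col]][i1]
    out[[col]] <- ifelse(is.na(i0), v1, v0)
  }
  s0 <- map0$score[i0]
  s1 <- map1$score[i1]
  e0 <- map0$se[i0]
  e1 <- map1$se[i1]
  if (inverse_variance) {
    w0 <- 1 / e0^2
    w1 <- 1 / e1^2
    out$score[both] <- ((s0 * w0 + s1 * w1) / (w0 + w1))[both]
    out$se[both] <- (1 / sqrt(w0 + w1))[both]
  } else {
    out$score[both] <- ((s0 + s1) / 2)[both]
    out$se[both] <- (sqrt(e0^2 + e1^2) / 2)[both]
  }
  out$sd[both] <- (sqrt(map0$sd[i0]^2 + map1$sd[i1]^2) / 2)[both]
  out$df[both] <- (map0$df[i0] + map1$df[i1])[both]
  out$pre_selection_freq[both] <- ((map0$pre_selection_freq[i0] +
    map1$pre_selection_freq[i1]) / 2)[both]
  out$condition <- "low"
  rownames(out) <- NULL
  out
}

#' Well-measured filter
#'
#' Keeps variants whose pre-selection (nonselective) allele frequency
#' exceeds `min_freq` (0.005% by default, to avoid undersampling) and whose
#' standard error is below `max_se`. Dropped variants are returned alongside
#' as imputation targets.
#'
#' @param map A variant-effect map.
#' @param min_freq Minimum pre-selection allele frequency.
#' @param max_se Maximum standard error.
#' @return List with `kept` and `dropped` maps.
#' @export
well_measured_filter <- function(map, min_freq = 5e-5, max_se = 0.2) {
  ok <- map$pre_selection_freq > min_freq & map$se < max_se
  list(
    kept = map[ok, , drop = FALSE],
    dropped = map[!ok, , drop = FALSE]
  )
}

#' Write / read a variant-effect map TSV
#'
#' Score-table dialect compatible with MaveDB-style score files
#' (`hgvs_pro`, `score`, `sd`, `se`, `df`, ...).
#'
#' @param map Variant-effect map.
#' @param path File path.
#' @return `read_map` returns the map data.frame (with `hgvs` column).
#' @export
write_map <- function(map, path) {
  out <- map
  names(out)[names(out) == "hgvs"] <- "hgvs_pro"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  m <- utils::read.delim(path)
  names(m)[names(m) == "hgvs_pro"] <- "hgvs"
  m
}
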