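# Imputation of missing variant scores with gradient-boosted trees over
# intrinsic map features, cross-validated, plus confidence-weighted
# refinement of measured scores.

#' Build intrinsic imputation features
#'
#' For each target variant: the confidence-weighted (1/se^2) mean of other
#' measured scores at the same position (excluding the target itself), the
#' confidence-weighted means of the 3 and of the 4 most BLOSUM62-similar
#' substitutions measured at that position, the wildtype/mutant
#' physicochemical descriptors, and the BLOSUM62 exchange score of the
#' substitution itself. Optional externally supplied feature columns (e.g.
#' computational predictor scores) are carried through when given. Features
#' that cannot be computed (no measured neighbor at the position) are `NA`,
#' which the tree model treats as an explicit missing value.
#'
#' @param targets data.frame with `hgvs`, `position`, `wt_aa`, `mut_aa`.
#' @param measured Well-measured variant-effect map (`hgvs`, `position`,
#'   `mut_aa`, `score`, `se`).
#' @param extra Optional data.frame of additional numeric features keyed by
#'   an `hgvs` column.
#' @return Numeric feature matrix with rownames = target `hgvs`.
#' @export
build_features <- function(targets, measured, extra = NULL) {
  desc <- aa_descriptors()
  bl <- blosum62()
  by_pos <- split(
    measured[c("hgvs", "mut_aa", "score", "se")], measured$position
  )

  wmean <- function(s, se) {
    w <- 1 / se^2
    sum(s * w) / sum(w)
  }
  feat <- t(vapply(seq_len(nrow(targets)), function(i) {
    p <- as.character(targets$position[i])
    tg_hgvs <- targets$hgvs[i]
    tg_mut <- targets$mut_aa[i]
    wt <- as.character(targets$wt_aa[i])
    mu <- tg_mut
    nb <- by_pos[[p]]
    if (!is.null(nb)) {
      # neighbor averages use missense substitutions only: synonymous and
      # nonsense neighbors reflect their class, not positional sensitivity
      nb <- nb[nb$hgvs != tg_hgvs & nb$mut_aa != wt & nb$mut_aa != "*", ,
        drop = FALSE
      ]
    }
    pos_mean <- bl3 <- bl4 <- NA_real_
    if (!is.null(nb) && nrow(nb) > 0) {
      pos_mean <- wmean(nb$score, nb$se)
      nb_std <- nb[nb$mut_aa %in% rownames(desc), , drop = FALSE]
      if (tg_mut %in% rownames(bl) && nrow(nb_std) > 0) {
        sim <- bl[tg_mut, nb_std$mut_aa]
        ord <- order(-sim, nb_std$mut_aa) # deterministic tie-break
        top3 <- ord[seq_len(min(3, length(ord)))]
        top4 <- ord[seq_len(min(4, length(ord)))]
        bl3 <- wmean(nb_std$score[top3], nb_std$se[top3])
        bl4 <- wmean(nb_std$score[top4], nb_std$se[top4])
      }
    }
    dwt <- if (wt %in% rownames(desc)) {
      as.numeric(desc[wt, ])
    } else {
      rep(NA_real_, 4)
    }
    dmu <- if (mu %in% rownames(desc)) {
      as.numeric(desc[mu, ])
    } else {
      rep(NA_real_, 4)
    }
    bself <- if (wt %in% rownames(bl) && mu %in% rownames(bl)) {
      bl[wt, mu]
    } else {
      NA_real_
    }
    c(
      pos_mean = pos_mean, blosum3_mean = bl3, blosum4_mean = bl4,
      wt_hydropathy = dwt[1], wt_volume = dwt[2], wt_charge = dwt[3],
      wt_polarity = dwt[4],
      mut_hydropathy = dmu[1], mut_volume = dmu[2], mut_charge = dmu[3],
      mut_polarity = dmu[4],
      blosum_self = bself,
      is_synonymous = as.numeric(mu == wt),
      is_nonsense = as.numeric(mu == "*"),
      position = targets$position[i]
    )
  }, numeric(15)))
  rownames(feat) <- targets$hgvs
  if (!is.null(extra)) {
    j <- match(targets$hgvs, extra$hgvs)
    ex <- as.matrix(extra[j, setdiff(names(extra), "hgvs"), drop = FALSE])
    rownames(ex) <- targets$hgvs
    feat <- cbind(feat, ex)
  }
  feat
}

#' Train the imputation model with cross-validation
#'
#' Gradient-boosted regression trees (fixed, seeded hyperparameters) on the
#' well-measured variants, evaluated by k-fold cross-validation. The pooled
#' held-out residual SD becomes the standard error attached to every
#' imputed score.
#'
#' @param features Feature matrix from [build_features()] for the training
#'   variants (rownames = hgvs).
#' @param scores Numeric vector of training scores aligned with `features`.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @param nrounds,max_depth,eta GBT hyperparameters.
#' @return List of class `impute_model`: `model`, `cv` (data.frame of
#'   per-fold `rmsd` and `pearson_r` plus overall values), `imputation_se`,
#'   `importance`, `degenerate` flag.
#' @export
train_impute <- function(features, scores, folds = 10, seed = 1,
                         nrounds = 500, max_depth = 4, eta = 0.05) {
  stopifnot(nrow(features) == length(scores))
  if (length(scores) < 2 * folds) {
    folds <- max(2, floor(length(scores) / 5))
  }
  degenerate <- stats::var(scores) < 1e-12
  if (degenerate) {
    const <- mean(scores)
    res <- list(
      model = NULL, constant = const,
      cv = data.frame(fold = NA, rmsd = 0, pearson_r = NA),
      rmsd = 0, pearson_r = NA_real_,
      imputation_se = .Machine$double.eps,
      cv_predictions = rep(const, length(scores)),
      importance = NULL, degenerate = TRUE,
      feature_names = colnames(features), folds = folds, seed = seed
    )
    class(res) <- "impute_model"
    return(res)
  }

  params <- list(
    objective = "reg:squarederror", max_depth = max_depth, eta = eta,
    nthread = 1
  )
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = length(scores)))
  residuals <- numeric(length(scores))
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    bst <- xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(features[tr, , drop = FALSE],
        label = scores[tr]
      ),
      nrounds = nrounds, verbose = 0
    )
    pred <- predict(bst, xgboost::xgb.DMatrix(features[!tr, , drop = FALSE]))
    residuals[!tr] <<- scores[!tr] - pred
    data.frame(
      fold = f,
      rmsd = sqrt(mean((scores[!tr] - pred)^2)),
      pearson_r = if (stats::sd(pred) > 0) {
        stats::cor(scores[!tr], pred)
      } else {
        NA_real_
      }
    )
  })
  cv <- do.call(rbind, per_fold)

  final <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(features, label = scores),
    nrounds = nrounds, verbose = 0
  )
  res <- list(
    model = final, constant = NULL, cv = cv,
    rmsd = sqrt(mean(residuals^2)),
    pearson_r = stats::cor(scores, scores - residuals),
    imputation_se = max(sqrt(mean(residuals^2)), .Machine$double.eps),
    cv_predictions = scores - residuals,
    importance = tryCatch(xgboost::xgb.importance(model = final),
      error = function(e) NULL
    ),
    degenerate = FALSE,
    feature_names = colnames(features), folds = folds, seed = seed
  )
  class(res) <- "impute_model"
  res
}

#' Predict imputed scores
#'
#' @param object An `impute_model` from [train_impute()].
#' @param features Feature matrix of target variants.
#' @param ... Unused.
#' @return data.frame with `hgvs`, `score`, `se`, `provenance = "imputed"`.
#' @export
predict.impute_model <- function(object, features, ...) {
  pred <- if (object$degenerate) {
    rep(object$constant, nrow(features))
  } else {
    predict(object$model, xgboost::xgb.DMatrix(features))
  }
  data.frame(
    hgvs = rownames(features), score = pred,
    se = object$imputation_se, provenance = "imputed"
  )
}

#' Refine measured scores with imputed values
#'
#' Inverse-variance weighted average of measured and imputed scores:
#' `refined = (s_m/se_m^2 + s_i/se_i^2) / (1/se_m^2 + 1/se_i^2)` with
#' `se = 1/sqrt(1/se_m^2 + 1/se_i^2)`. Variants present in only one source
#' pass through with provenance `"measured"` or `"imputed"`.
#'
#' @param measured data.frame with `hgvs`, `score`, `se` (measured map).
#' @param imputed data.frame with `hgvs`, `score`, `se` (imputed scores).
#' @return Refined map: `hgvs`, `score`, `se`, `provenance` in
#'   `{measured, imputed, refined}`.
#' @export
refine_scores <- function(measured, imputed) {
  all_hgvs <- union(measured$hgvs, imputed$hgvs)
  im <- match(all_hgvs, measured$hgvs)
  ii <- match(all_hgvs, imputed$hgvs)
  both <- !is.na(im) & !is.na(ii)
  score <- ifelse(is.na(im), imputed$score[ii], measured$score[im])
  se <- ifelse(is.na(im), imputed$se[ii], measured$se[im])
  provenance <- ifelse(is.na(im), "imputed", "measured")
  wm <- 1 / measured$se[im]^2
  wi <- 1 / imputed$se[ii]^2
  score[both] <- ((measured$score[im] * wm + imputed$score[ii] * wi) /
    (wm + wi))[both]
  se[both] <- (1 / sqrt(wm + wi))[both]
  provenance[both] <- "refined"
  data.frame(hgvs = all_hgvs, score = score, se = se, provenance = provenance)
}

#' Impute and refine a variant-effect map
#'
#' Convenience wrapper: builds features for the well-measured training set
#' and the imputation targets, trains the model, predicts the targets, and
#' refines the measured scores.
#'
#' @param kept Well-measured map (training set).
#' @param targets data.frame of variants to impute (`hgvs`, `position`,
#'   `wt_aa`, `mut_aa`); defaults to nothing.
#' @param extra Optional external feature columns (see [build_features()]).
#' @param ... Passed to [train_impute()].
#' @return List with `refined` map (provenance-labeled), `model`, `cv`.
#' @export
impute_map <- function(kept, targets = NULL, extra = NULL, ...) {
  train_feat <- build_features(kept, kept, extra = extra)
  model <- train_impute(train_feat, kept$score, ...)
  imputed <- if (!is.null(targets) && nrow(targets) > 0) {
    predict(model, build_features(targets, kept, extra = extra))
  } else {
    data.frame(
      hgvs = character(0), score = numeric(0), se = numeric(0),
      provenance = character(0)
    )
  }
  # measured variants are refined against their held-out CV predictions so
  # the imputed component is not a self-fit
  refined_measured <- refine_scores(
    kept[c("hgvs", "score", "se")],
    data.frame(
      hgvs = kept$hgvs, score = model$cv_predictions,
      se = model$imputation_se
    )
  )
  refined <- rbind(refined_measured, imputed[!(imputed$hgvs %in%
    refined_measured$hgvs), , drop = FALSE])
  list(refined = refined, model = model, cv = model$cv, imputed = imputed)
}
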