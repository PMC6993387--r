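# Pathogenicity evidence from map scores: precision-recall against
# reference variant sets, Bayes-factor log-likelihood ratios, and the
# fitness-activity Michaelis-Menten relationship.

#' Precision-recall evaluation against a reference set
#'
#' Sweeps a threshold over the observed scores (lower score = predicted
#' pathogenic), grouping tied scores, and computes precision and recall at
#' each threshold. AUPRC is the step-wise integral of precision over
#' recall; recall-at-precision(p) is the maximum recall among sweep points
#' with precision >= p.
#'
#' @param scores Named numeric vector (names = hgvs) or data.frame with
#'   `hgvs` and `score`.
#' @param positive,negative Character vectors of reference variant names
#'   (disease-associated / presumed benign).
#' @param precision_at Precision levels for recall-at-precision.
#' @return List with `curve` (threshold, precision, recall), `auprc`,
#'   `recall_at_precision`, `n_missing` (reference variants absent from the
#'   score set).
#' @export
precision_recall <- function(scores, positive, negative,
                             precision_at = 0.9) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$hgvs)
  }
  if (length(positive) == 0) stop("positive reference set is empty")
  labels <- c(
    stats::setNames(rep(TRUE, length(positive)), positive),
    stats::setNames(rep(FALSE, length(negative)), negative)
  )
  present <- names(labels)[names(labels) %in% names(scores)]
  n_missing <- length(labels) - length(present)
  y <- labels[present]
  s <- scores[present]
  if (sum(y) == 0) stop("no positive reference variants present in the map")

  thr <- sort(unique(s))
  curve <- do.call(rbind, lapply(thr, function(t) {
    pred <- s <= t
    data.frame(
      threshold = t,
      precision = sum(y & pred) / sum(pred),
      recall = sum(y & pred) / sum(y)
    )
  }))
  # step-wise integration over recall
  rec <- c(0, curve$recall)
  auprc <- sum(diff(rec) * curve$precision)
  rap <- vapply(precision_at, function(p) {
    ok <- curve$precision >= p
    if (!any(ok)) 0 else max(curve$recall[ok])
  }, numeric(1))
  list(
    curve = curve, auprc = auprc,
    recall_at_precision = stats::setNames(rap, precision_at),
    n_missing = n_missing
  )
}

#' Bayes-factor log-likelihood ratio of pathogenicity
#'
#' Tail mode (default): `LLR = log10[ P(S <= s | positive) /
#' P(S >= s | negative) ]` with add-one-smoothed empirical tail
#' probabilities `(count + 1) / (n + 1)`. Density mode: log10 ratio of
#' Gaussian kernel density estimates at `s`. Scores above the maximum of
#' the negative reference set are flagged (`beyond_negative`), where the
#' tail definition becomes extrapolation.
#'
#' @param score Numeric vector of scores to evaluate.
#' @param positive_scores,negative_scores Reference score distributions.
#' @param mode `"tail"` or `"density"`.
#' @return data.frame with `score`, `llr`, `p_tail_pos`, `p_tail_neg`,
#'   `beyond_negative`.
#' @export
llr <- function(score, positive_scores, negative_scores,
                mode = c("tail", "density")) {
  mode <- match.arg(mode)
  if (length(positive_scores) == 0 || length(negative_scores) == 0) {
    stop("both reference score sets must be non-empty")
  }
  p_pos <- vapply(score, function(s) {
    (sum(positive_scores <= s) + 1) / (length(positive_scores) + 1)
  }, numeric(1))
  p_neg <- vapply(score, function(s) {
    (sum(negative_scores >= s) + 1) / (length(negative_scores) + 1)
  }, numeric(1))
  value <- if (mode == "tail") {
    log10(p_pos / p_neg)
  } else {
    dp <- stats::density(positive_scores)
    dn <- stats::density(negative_scores)
    log10(pmax(stats::approx(dp$x, dp$y, score, rule = 2)$y, 1e-12) /
      pmax(stats::approx(dn$x, dn$y, score, rule = 2)$y, 1e-12))
  }
  data.frame(
    score = score, llr = value, p_tail_pos = p_pos, p_tail_neg = p_neg,
    beyond_negative = score > max(negative_scores)
  )
}

#' Michaelis-Menten prediction
#'
#' `y = x / (x + k)`; bounded in `[0, 1)` for `x >= 0` and increasing in x.
#'
#' @param x Relative enzyme activity (>= 0).
#' @param k Michaelis-like constant (> 0).
#' @return Predicted fitness scores.
#' @export
mm_predict <- function(x, k) x / (x + k)

#' Fit the fitness-activity curve
#'
#' Least-squares fit of `y = x / (x + k)` relating fitness score to
#' relative enzyme activity, under a Gaussian error model. The Gaussian
#' log-likelihood of the fitted curve is compared with the best linear fit;
#' `likelihood_ratio = exp(loglik_mm - loglik_linear)` says how much more
#' likely the data are under the saturating curve.
#'
#' @param activity Relative enzyme activities (>= 0).
#' @param fitness Paired fitness scores.
#' @return List with `k`, `loglik_mm`, `loglik_linear`, `likelihood_ratio`,
#'   `fitted`.
#' @export
fit_activity_curve <- function(activity, fitness) {
  if (length(activity) != length(fitness)) stop("inputs must be paired")
  if (length(activity) < 4) stop("need at least 4 paired observations")
  if (any(activity < 0)) stop("activities must be non-negative")

  sse <- function(k) sum((fitness - mm_predict(activity, k))^2)
  upper <- max(10 * max(activity), 1)
  opt <- stats::optimize(sse, c(1e-9, upper), tol = 1e-12)
  # polish to full precision
  opt2 <- stats::optimize(sse,
    c(max(1e-10, opt$minimum / 2), 2 * opt$minimum),
    tol = .Machine$double.eps^0.5
  )
  k <- if (opt2$objective <= opt$objective) opt2$minimum else opt$minimum

  n <- length(fitness)
  gauss_ll <- function(rss) {
    s2 <- max(rss / n, 1e-300)
    -n / 2 * (log(2 * pi * s2) + 1)
  }
  ll_mm <- gauss_ll(sse(k))
  lin <- stats::lm(fitness ~ activity)
  ll_lin <- gauss_ll(sum(stats::residuals(lin)^2))
  list(
    k = k,
    loglik_mm = ll_mm,
    loglik_linear = ll_lin,
    likelihood_ratio = exp(ll_mm - ll_lin),
    fitted = mm_predict(activity, k)
  )
}

#' Read a reference variant set TSV
#'
#' Two-column dialect: `hgvs_pro`, `label` (`positive`/`negative`), with an
#' optional `domain` column for stratified evaluation.
#'
#' @param path File path.
#' @return data.frame with `hgvs`, `label`, and `domain` (NA when absent).
#' @export
read_reference_set <- function(path) {
  d <- utils::read.delim(path)
  names(d)[names(d) == "hgvs_pro"] <- "hgvs"
  if (!"domain" %in% names(d)) d$domain <- NA_character_
  d
}
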