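# Diploid genotype scoring (multiplicative in cis, additive in trans),
# recurrent-variant cohort reduction, and ordinal phenotype correlation.

parse_hgvs_position <- function(hgvs) {
  as.integer(sub("^p\\.[A-Za-z*]+(\\d+).*$", "\\1", hgvs))
}

# nonsense / frameshift / unknown / missense from the variant name
hgvs_class <- function(hgvs) {
  ifelse(grepl("Ter$|\\*$", hgvs), "nonsense",
    ifelse(grepl("fs", hgvs), "frameshift",
      ifelse(grepl("\\?|unknown", hgvs), "unknown", "missense")
    )
  )
}

split_allele <- function(allele) {
  if (is.na(allele) || allele == "") {
    return(character(0))
  }
  strsplit(allele, ";", fixed = TRUE)[[1]]
}

#' Fitness score of one allele
#'
#' Product of the individual variants' fitness values, each clamped to
#' [0, 1]. The reference allele (no variants) scores 1; nonsense and
#' frameshift variants score 0 regardless of map value (nonsense-mediated
#' decay is expected in humans even where the assay scores read-through).
#'
#' @param variants Character vector of variant names (may be empty).
#' @param map Variant-effect map with `hgvs` and `score` columns.
#' @param unresolved `"error"` to fail on a missense variant absent from the
#'   map, or a numeric pass-through fitness for such variants.
#' @return Allele fitness in [0, 1].
#' @export
allele_score <- function(variants, map, unresolved = "error") {
  if (length(variants) == 0) {
    return(1)
  }
  cls <- hgvs_class(variants)
  fit <- numeric(length(variants))
  fit[cls %in% c("nonsense", "frameshift")] <- 0
  need <- !(cls %in% c("nonsense", "frameshift"))
  if (any(need)) {
    i <- match(variants[need], map$hgvs)
    if (anyNA(i)) {
      missing <- variants[need][is.na(i)]
      if (identical(unresolved, "error")) {
        stop(
          "variant(s) not resolvable in the map: ",
          paste(missing, collapse = ", ")
        )
      }
      stopifnot(is.numeric(unresolved))
    }
    v <- map$score[i]
    v[is.na(v)] <- if (is.numeric(unresolved)) unresolved else NA_real_
    fit[need] <- pmin(pmax(v, 0), 1)
  }
  prod(fit)
}

#' Diploid variant-effect score of a patient genotype
#'
#' In-cis variants combine multiplicatively within an allele; the two
#' allele scores add: for genotype p.[X];[Y;Z],
#' `phi_diploid = phi_X + phi_Y * phi_Z`. Unphased multi-variant genotypes
#' are assumed in trans upstream of this function.
#'
#' @param allele1,allele2 Character vectors of variant names per allele.
#' @param low_map,high_map Variant-effect maps for the two B6 conditions.
#' @param unresolved See [allele_score()].
#' @return List with `phi_low`, `phi_high`, `phi_delta` (each in [0, 2]).
#' @export
diploid_score <- function(allele1, allele2, low_map, high_map,
                          unresolved = "error") {
  lo <- allele_score(allele1, low_map, unresolved) +
    allele_score(allele2, low_map, unresolved)
  hi <- allele_score(allele1, high_map, unresolved) +
    allele_score(allele2, high_map, unresolved)
  list(phi_low = lo, phi_high = hi, phi_delta = hi - lo)
}

#' Score every patient in a cohort
#'
#' @param cohort Cohort table (`patient_id`, `allele1`, `allele2`,
#'   semicolon-joined variant names, empty string = reference allele).
#' @param low_map,high_map Variant-effect maps.
#' @param exclude_regulatory Drop patients carrying a variant in the
#'   C-terminal regulatory domain, where the assay is insensitive.
#' @param regulatory_boundary Last catalytic-domain residue; positions
#'   beyond it count as regulatory.
#' @param unresolved See [allele_score()].
#' @return data.frame with `patient_id`, `phi_low`, `phi_high`,
#'   `phi_delta`; excluded patients are omitted (reported in
#'   `attr(, "excluded")`).
#' @export
score_cohort <- function(cohort, low_map, high_map,
                         exclude_regulatory = TRUE,
                         regulatory_boundary = 413,
                         unresolved = "error") {
  alle1 <- lapply(cohort$allele1, split_allele)
  alle2 <- lapply(cohort$allele2, split_allele)
  if (exclude_regulatory) {
    reg <- vapply(seq_len(nrow(cohort)), function(i) {
      pos <- parse_hgvs_position(c(alle1[[i]], alle2[[i]]))
      any(pos > regulatory_boundary, na.rm = TRUE)
    }, logical(1))
  } else {
    reg <- rep(FALSE, nrow(cohort))
  }
  rows <- lapply(which(!reg), function(i) {
    d <- diploid_score(alle1[[i]], alle2[[i]], low_map, high_map, unresolved)
    data.frame(
      patient_id = cohort$patient_id[i],
      phi_low = d$phi_low, phi_high = d$phi_high, phi_delta = d$phi_delta
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- cohort$patient_id[reg]
  out
}

#' Reduce recurrent-variant bias in a cohort
#'
#' While any variant occurs more than `max_occurrence` times (counting
#' patient-allele occurrences), remove one patient carrying the most common
#' variant X, preferring in order: (1) patients where X occurs in cis with
#' another variant, (2) patients whose trans allele carries a nonsense,
#' frameshift, or unknown variant, (3) patients with nonsense/frameshift
#' variants on both alleles, (4) the lexicographically smallest patient id
#' (the deterministic tie-break, applied within every rule).
#'
#' @param cohort Cohort table.
#' @param max_occurrence Maximum allowed occurrences per variant.
#' @return List with `cohort` (reduced) and `log` (one row per removal:
#'   `iteration`, `patient_id`, `variant`, `rule`).
#' @export
reduce_cohort <- function(cohort, max_occurrence = 3) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  removal_log <- list()
  iter <- 0
  repeat {
    a1 <- lapply(cohort$allele1, split_allele)
    a2 <- lapply(cohort$allele2, split_allele)
    occ <- table(unlist(c(a1, a2)))
    if (length(occ) == 0 || max(occ) <= max_occurrence) break
    # most common variant; alphabetical tie-break for determinism
    x <- sort(names(occ)[occ == max(occ)])[1]

    carries <- vapply(seq_len(nrow(cohort)), function(i) {
      x %in% a1[[i]] || x %in% a2[[i]]
    }, logical(1))
    cand <- which(carries)

    in_cis <- vapply(cand, function(i) {
      (x %in% a1[[i]] && length(a1[[i]]) > 1) ||
        (x %in% a2[[i]] && length(a2[[i]]) > 1)
    }, logical(1))
    bad_trans <- vapply(cand, function(i) {
      trans <- if (x %in% a1[[i]]) a2[[i]] else a1[[i]]
      length(trans) > 0 &&
        any(hgvs_class(trans) %in% c("nonsense", "frameshift", "unknown"))
    }, logical(1))
    both_null <- vapply(cand, function(i) {
      n1 <- length(a1[[i]]) > 0 &&
        all(hgvs_class(a1[[i]]) %in% c("nonsense", "frameshift"))
      n2 <- length(a2[[i]]) > 0 &&
        all(hgvs_class(a2[[i]]) %in% c("nonsense", "frameshift"))
      n1 && n2
    }, logical(1))

    pick_from <- function(idx) idx[order(cohort$patient_id[idx])][1]
    if (any(in_cis)) {
      victim <- pick_from(cand[in_cis])
      rule <- "in_cis_with_x"
    } else if (any(bad_trans)) {
      victim <- pick_from(cand[bad_trans])
      rule <- "null_in_trans"
    } else if (any(both_null)) {
      victim <- pick_from(cand[both_null])
      rule <- "both_alleles_null"
    } else {
      victim <- pick_from(cand)
      rule <- "lexicographic"
    }
    iter <- iter + 1
    removal_log[[iter]] <- data.frame(
      iteration = iter, patient_id = cohort$patient_id[victim],
      variant = x, rule = rule
    )
    cohort <- cohort[-victim, , drop = FALSE]
  }
  list(
    cohort = cohort,
    log = if (iter > 0) {
      do.call(rbind, removal_log)
    } else {
      data.frame(
        iteration = integer(0), patient_id = character(0),
        variant = character(0), rule = character(0)
      )
    }
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from the t distribution with n - 2
#' degrees of freedom.
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped).
#' @return List with `rho`, `p`, `n`; `rho = NA` when either input is
#'   constant.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    return(list(rho = rho, p = 0, n = n))
  }
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Correlate diploid scores with ordinal phenotypes
#'
#' Spearman correlation of each phenotype (onset age, severity, B6
#' response) against each diploid score type (low, high, delta), with
#' missing phenotypes dropped pairwise.
#'
#' @param cohort Cohort table with phenotype columns `onset_age`,
#'   `severity`, `b6_response`.
#' @param scores Diploid score table from [score_cohort()].
#' @return data.frame with `phenotype`, `score_type`, `rho`, `p`, `n`.
#' @export
correlate_phenotypes <- function(cohort, scores) {
  m <- merge(cohort, scores, by = "patient_id")
  if (nrow(m) < 3) stop("need at least 3 scored patients")
  combos <- expand.grid(
    phenotype = c("onset_age", "severity", "b6_response"),
    score_type = c("phi_low", "phi_high", "phi_delta"),
    stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(combos)), function(i) {
    r <- spearman_rho(m[[combos$score_type[i]]], m[[combos$phenotype[i]]])
    data.frame(
      phenotype = combos$phenotype[i], score_type = combos$score_type[i],
      rho = r$rho, p = r$p, n = r$n
    )
  })
  do.call(rbind, res)
}

#' Read / write the cohort TSV dialect
#'
#' @param cohort Cohort table.
#' @param path File path.
#' @return `read_cohort` returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.delim(path, colClasses = c(
    patient_id = "character", allele1 = "character", allele2 = "character"
  ))
  d$allele1[is.na(d$allele1)] <- ""
  d$allele2[is.na(d$allele2)] <- ""
  d
}
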