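# Shared fixtures, built in code at test time.

# Small variant panel screen: fast enough for per-module tests.
small_panel <- function(seed = 1, n_mis = 150, n_syn = 40, n_non = 40,
                        depth = 2e5, error_rate = 0, orf_len = 120, ...) {
  cfg <- sim_config(
    orf_length_codons = orf_len, n_clones = n_mis + n_syn + n_non,
    depth = depth, error_rate = error_rate, seed = seed, ...
  )
  simulate_variant_panel(n_mis, n_syn, n_non, cfg)
}

# Deterministic adjusted frequency table: two replicates, noiseless, with
# known per-variant enrichment ratios relative to depth-1e6 frequencies.
# phi values chosen so nonsense median = 0.1 and synonymous median = 1.
toy_adjusted <- function() {
  variants <- data.frame(
    position = c(2, 2, 3, 3, 4, 4, 5, 5),
    wt_aa = c("A", "A", "G", "G", "L", "L", "K", "K"),
    mut_aa = c("A", "V", "G", "*", "*", "P", "K", "*"),
    phi = c(1.05, 0.5, 0.95, 0.12, 0.08, 0.3162278, 1.0, 0.1)
  )
  nonsel_freq <- 2e-4
  rows <- lapply(c("select_low_0", "nonselective"), function(cond) {
    do.call(rbind, lapply(1:2, function(r) {
      d <- variants
      d$condition <- cond
      d$replicate <- r
      d$frequency <- if (cond == "nonselective") {
        nonsel_freq
      } else {
        nonsel_freq * d$phi
      }
      d
    }))
  })
  out <- do.call(rbind, rows)
  out$depth <- 1e6
  out$ctrl_mean <- 0
  out$ctrl_sd <- 0
  out$adj_frequency <- out$frequency
  out$floored <- FALSE
  out$hgvs <- hgvs_pro(out$wt_aa, out$position, out$mut_aa)
  out$class <- variant_class(out$wt_aa, out$mut_aa)
  out$phi <- NULL
  out
}

# Minimal variant-effect map for classification / patient tests.
toy_map <- function(hgvs, score, se = 0.05, class = NULL, position = NULL) {
  if (is.null(class)) {
    class <- ifelse(grepl("Ter$", hgvs), "nonsense",
      ifelse(
        sub("^p\\.([A-Za-z]+)\\d+.*", "\\1", hgvs) ==
          sub("^p\\.[A-Za-z]+\\d+([A-Za-z*]+)$", "\\1", hgvs),
        "synonymous", "missense"
      )
    )
  }
  if (is.null(position)) {
    position <- as.integer(sub("^p\\.[A-Za-z*]+(\\d+).*$", "\\1", hgvs))
  }
  data.frame(
    hgvs = hgvs, position = position,
    wt_aa = "A", mut_aa = "V", class = class,
    score = score, sd = se * sqrt(2), se = se, df = 2,
    pre_selection_freq = 1e-4, condition = "test"
  )
}
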