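# Independent brute-force oracles used to cross-check the package's
# implementations. Each is written from the textbook definition, not from
# the code path it verifies.

# Benjamini-Hochberg step-up by literal definition: q_i = p_(i) * m / i,
# monotonized from the largest rank downward.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  pmin(q, 1)
}

# One-sided Fisher enrichment p by exhaustive enumeration over all
# possible selections of the same size from the universe.
fisher_enum_oracle <- function(selected, term, universe) {
  s <- length(selected)
  a_obs <- length(intersect(selected, term))
  sel_sets <- utils::combn(length(universe), s)
  hits <- 0
  term_idx <- which(universe %in% term)
  for (j in seq_len(ncol(sel_sets)))
    if (sum(sel_sets[, j] %in% term_idx) >= a_obs) hits <- hits + 1
  hits / ncol(sel_sets)
}

# Pearson r from the raw summation formula.
pearson_formula_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Position-by-position E-box matcher.
ebox_oracle <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  pos <- integer(0)
  if (length(s) >= 6)
    for (i in 1:(length(s) - 5))
      if (s[i] == "C" && s[i + 1] == "A" && s[i + 4] == "T" &&
          s[i + 5] == "G")
        pos <- c(pos, i - 1L)
  pos
}

# Exhaustive target-decoy threshold sweep: try every distinct score as the
# threshold, keep those with decoy/target ratio <= level, take the most
# permissive.
fdr_sweep_oracle <- function(scores, is_decoy, level) {
  best <- NULL
  for (thr in sort(unique(scores))) {
    nt <- sum(scores >= thr & !is_decoy)
    nd <- sum(scores >= thr & is_decoy)
    if (nt > 0 && nd / nt <= level)
      if (is.null(best) || thr < best) best <- thr
  }
  best
}

small_sim_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_proteins = 120, n_up_pan = 6, n_down_pan = 3,
               n_subtype_markers = 8, n_spectra = 10, n_psms = 400,
               n_genes = 60, n_correlated = 3)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
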