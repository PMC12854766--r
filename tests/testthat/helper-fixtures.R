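# shared in-code fixtures for the suite

tiny_grid <- function(n = 9) build_grid(n = n)

# a small noiseless single-pathway study: every assay curve is exactly
# Hill, so harmonization round trips are exact
tiny_exact_study <- function(seed = 11, n_chemicals = 15) {
  generate_study(synth_config(n_assays = 6, n_proteins = 3,
                              n_pathways = 1, n_chemicals = n_chemicals,
                              noise_sd = 0, missing_frac = 0,
                              seed = seed))
}

# hand-built fingerprint set: `sizes` cliques of identical vectors plus
# `n_single` mutually dissimilar singletons
clique_fps <- function(sizes, n_single = 0, nbits = 64) {
  rows <- list()
  bit <- 1
  for (k in seq_along(sizes)) {
    v <- rep(FALSE, nbits); v[bit:(bit + 5)] <- TRUE
    bit <- bit + 8
    for (i in seq_len(sizes[k])) rows[[length(rows) + 1]] <- v
  }
  for (i in seq_len(n_single)) {
    v <- rep(FALSE, nbits); v[bit] <- TRUE; bit <- bit + 1
    rows[[length(rows) + 1]] <- v
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("X%02d", seq_len(nrow(m)))
  m
}

# brute-force step-up BH oracle (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# brute-force rank-biserial oracle over all pairs
rrb_oracle <- function(toxic, nontoxic) {
  fav <- 0
  for (x in toxic) for (y in nontoxic) {
    fav <- fav + (x > y) + 0.5 * (x == y)
  }
  2 * fav / (length(toxic) * length(nontoxic)) - 1
}
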