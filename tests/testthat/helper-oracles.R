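# Independent oracles and small fixture builders used across the suite.

# Per-base coverage oracle: mark covered bases of the window in a logical
# vector and count.
coverage_oracle <- function(window, elements) {
  len <- window$end - window$start
  covered <- logical(len)
  el <- elements[elements$chrom == window$chrom, , drop = FALSE]
  for (i in seq_len(nrow(el))) {
    lo <- max(el$start[i], window$start)
    hi <- min(el$end[i], window$end)
    if (hi > lo) covered[(lo - window$start + 1):(hi - window$start)] <- TRUE
  }
  sum(covered)
}

# Per-base density oracle on a clipped, nominally-normalized window.
density_oracle <- function(chrom, anchor, elements, chrom_sizes,
                           window_size = 300000) {
  half <- window_size / 2
  ws <- max(0, anchor - half)
  we <- min(chrom_sizes[[chrom]], anchor + half)
  if (we <= ws) return(0)
  win <- gintervals(chrom, ws, we)
  100 * coverage_oracle(win, elements) / window_size
}

# Independent affine-gap Smith-Waterman (Gotoh) scoring oracle; a gap of
# length k costs gap_open + k * gap_extend.
sw_score_oracle <- function(query, subject, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  q <- strsplit(chartr("U", "T", toupper(query)), "")[[1]]
  s <- strsplit(chartr("U", "T", toupper(subject)), "")[[1]]
  n <- length(q); m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (consume subject)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (consume query)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- if (q[i - 1] == s[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

revcomp_rna <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Single-linkage clustering oracle: connected components of the
# "same chrom+strand and boundary gap < max_gap" graph (transitive closure
# by repeated relabelling, independent of the package's sweep algorithm).
cluster_oracle <- function(mirnas, max_gap = 10000) {
  n <- nrow(mirnas)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || comp[i] == comp[j]) next
      same <- mirnas$chrom[i] == mirnas$chrom[j] &&
        mirnas$strand[i] == mirnas$strand[j]
      gap <- max(mirnas$start[i], mirnas$start[j]) -
        min(mirnas$end[i], mirnas$end[j])
      if (same && gap < max_gap) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(mirnas$id, comp))
}

# Small-but-complete simulation settings for fast end-to-end tests.
small_config <- function(seed = 1, ...) {
  defaults <- list(
    n_chroms = 2, chrom_length = 12e6, n_genes = 180,
    n_mirnas = 40, n_intergenic = 34, n_planted_targets = 8,
    n_pol3 = 2, n_intragenic_zf_intergenic = 3,
    n_random_bivalent = 10, n_grbs = 2, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Deterministic random genome pieces for property tests.
random_intervals <- function(n, chrom = "chr1", max_pos = 5000,
                             max_len = 400) {
  start <- floor(stats::runif(n) * (max_pos - max_len))
  len <- 1 + floor(stats::runif(n) * max_len)
  gintervals(chrom, start, start + len)
}
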