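# Statistical layer: bootstrapped two-sample KS test, exact one-sided Fisher,
# one-sided Wilcoxon rank-sum, and the enriched/poor median split.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum absolute difference of the two empirical CDFs, with correct
#' handling of ties (the difference is evaluated only at distinct values).
#'
#' @param x,y Numeric samples.
#' @return D in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  n <- length(x); m <- length(y)
  stopifnot(n > 0, m > 0)
  w <- c(x, y)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= n, 1 / n, -1 / m))
  ws <- w[ord]
  keep <- c(diff(ws) != 0, TRUE)
  max(abs(z[keep]))
}

#' Bootstrapped two-sided KS test
#'
#' Tie-robust bootstrap of the two-sample KS statistic under the null of a
#' common distribution: `nboot` statistic replicates are computed from pairs
#' of resamples (sizes `|x|` and `|y|`) drawn with replacement from the
#' pooled data, and `p = #\{D* >= D_obs\} / nboot`. With the default
#' estimator p can be exactly 0; `conservative = TRUE` uses
#' `(r + 1) / (nboot + 1)` instead.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param nboot Bootstrap replicates (default 10000).
#' @param seed Integer seed; the test is reproducible from it.
#' @param conservative Use the (r+1)/(nboot+1) estimator.
#' @return An `enrichment_result`: list(D, p_boot, nboot, seed, n_x, n_y).
#' @export
ks_boot_pvalue <- function(x, y, nboot = 10000, seed = 1,
                           conservative = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  d_obs <- ks_statistic(x, y)
  pooled <- c(x, y)
  n <- length(x); m <- length(y); tot <- n + m
  r <- with_rng_seed(seed, {
    hits <- 0L
    for (b in seq_len(nboot)) {
      ix <- sample.int(tot, tot, replace = TRUE)
      db <- ks_statistic(pooled[ix[seq_len(n)]], pooled[ix[(n + 1):tot]])
      if (db >= d_obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  p <- if (conservative) (r + 1) / (nboot + 1) else r / nboot
  structure(list(D = d_obs, p_boot = p, nboot = nboot, seed = seed,
                 n_x = n, n_y = m), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> D = %.4f, p_boot = %g (nboot = %d, n = %d vs %d)\n",
              x$D, x$p_boot, x$nboot, x$n_x, x$n_y))
  invisible(x)
}

#' One-sided Fisher's exact test (enrichment direction)
#'
#' Upper-tail hypergeometric probability of observing at least `a` successes
#' in the first row of the 2x2 table `[[a, b], [c, d]]` with all margins
#' fixed — the probability that the "enriched" group has at least as many
#' successes as observed. `two_sided = TRUE` instead sums the probabilities
#' of all tables at most as probable as the observed one (the usual
#' two-sided convention).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param two_sided Compute the two-sided p-value.
#' @return p-value.
#' @export
fisher_exact_one_sided <- function(a, b, c, d, two_sided = FALSE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + c        # total successes
  n_f <- b + d      # total failures
  k <- a + b        # size of first group
  support <- max(0, k - n_f):min(k, m)
  probs <- stats::dhyper(support, m, n_f, k)
  if (!two_sided) {
    sum(probs[support >= a])
  } else {
    p_obs <- stats::dhyper(a, m, n_f, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

#' One-sided Wilcoxon rank-sum test
#'
#' Midranks for ties; exact enumeration for small samples without ties
#' (total n <= 20), normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y Numeric samples.
#' @param direction "x<y" (alternative: x shifted below y) or "x>y".
#' @return p-value.
#' @export
wilcoxon_one_sided <- function(x, y, direction = c("x<y", "x>y")) {
  direction <- match.arg(direction)
  alt <- if (direction == "x<y") "less" else "greater"
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y, alternative = alt, exact = exact,
                     correct = TRUE)$p.value
}

#' Median split of loci by a density score
#'
#' Sorts ids by score descending and labels the top `ceiling(n/2)` as
#' "enriched", the rest as "poor". Boundary ties are broken by id order
#' (stable and documented), so the split is deterministic.
#'
#' @param scores Named numeric vector (names are locus ids).
#' @return A `split_result`: list(enriched, poor, score_name).
#' @param score_name Label for the score used.
#' @export
median_split <- function(scores, score_name = "density") {
  stopifnot(length(scores) > 0, !is.null(names(scores)))
  ord <- order(-scores, names(scores))
  n_top <- ceiling(length(scores) / 2)
  structure(list(enriched = names(scores)[ord[seq_len(n_top)]],
                 poor = names(scores)[ord[-seq_len(n_top)]],
                 score_name = score_name),
            class = "split_result")
}

#' Bivalent-association contingency analysis
#'
#' Builds the 2x2 table of bivalent-promoter association against the
#' enriched/poor split, reports the association percentage in each group
#' (rounded to whole percent, as printed), and both Fisher p-values. Loci
#' with NA flags (e.g. intragenic loci, whose features cannot be attributed
#' to the miRNA) are excluded from the table.
#'
#' @param flags Named logical vector: locus id -> associated with a bivalent
#'   domain in at least one cell type (NA allowed).
#' @param split A `split_result` over the same ids.
#' @return List: table (2x2 matrix), pct_enriched, pct_poor, p_one_sided,
#'   p_two_sided, n_enriched, n_poor.
#' @export
bivalent_contingency <- function(flags, split) {
  use <- names(flags)[!is.na(flags)]
  enr <- intersect(split$enriched, use)
  poor <- intersect(split$poor, use)
  a <- sum(flags[enr]); b <- length(enr) - a
  c_ <- sum(flags[poor]); d <- length(poor) - c_
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("enriched", "poor"),
                                c("bivalent", "not_bivalent")))
  list(table = tab,
       pct_enriched = round(100 * a / max(1, a + b)),
       pct_poor = round(100 * c_ / max(1, c_ + d)),
       p_one_sided = fisher_exact_one_sided(a, b, c_, d),
       p_two_sided = fisher_exact_one_sided(a, b, c_, d, two_sided = TRUE),
       n_enriched = a + b, n_poor = c_ + d)
}
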