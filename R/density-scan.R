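# Enhancer (HCNE / p300) density in 300 kb windows.

#' Element density in a fixed window centered on an anchor point
#'
#' The window is `window_size` bp centered on the anchor (clipped at the
#' chromosome ends); density is the percentage of bases covered by at least
#' one element. By default the denominator is the nominal `window_size` even
#' for clipped windows, which keeps densities comparable along the chromosome
#' (loci near ends are underestimated); `nominal_denominator = FALSE` divides
#' by the clipped width instead.
#'
#' @param chrom Chromosome of the anchor.
#' @param anchor 0-based anchor base offset (pre-miRNA midpoint for miRNA
#'   loci, TSS for genes; see [anchor_point()]).
#' @param elements Element interval table (one track / lineage).
#' @param chrom_sizes Named chromosome lengths.
#' @param window_size Window width in bp (default 300 kb).
#' @param nominal_denominator Normalize by `window_size` even when clipped.
#' @return Density percentage in `[0, 100]`.
#' @export
density_at_feature <- function(chrom, anchor, elements, chrom_sizes,
                               window_size = 300000,
                               nominal_denominator = TRUE) {
  d <- densities_at_anchors(chrom, anchor, elements, chrom_sizes, window_size,
                            nominal_denominator)
  d[[1]]
}

#' Vectorized density at many anchors
#'
#' Same computation as [density_at_feature()] for vectors of anchors; this is
#' what the genome-wide scans and control-set evaluations call.
#'
#' @inheritParams density_at_feature
#' @param chrom,anchor Equal-length vectors.
#' @return Numeric vector of density percentages.
#' @export
densities_at_anchors <- function(chrom, anchor, elements, chrom_sizes,
                                 window_size = 300000,
                                 nominal_denominator = TRUE) {
  n <- length(anchor)
  if (n == 0) return(numeric())
  half <- window_size / 2
  ws <- pmax(0, anchor - half)
  we <- pmin(unname(chrom_sizes[chrom]), anchor + half)
  cov <- numeric(n)
  ok <- we > ws
  if (any(ok) && nrow(elements)) {
    wins <- GenomicRanges::GRanges(chrom[ok],
                                   IRanges::IRanges(ws[ok] + 1, we[ok]))
    el <- GenomicRanges::reduce(as_granges(elements))
    hits <- GenomicRanges::findOverlaps(wins, el)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(wins)[q],
        IRanges::ranges(el)[S4Vectors::subjectHits(hits)]))
      agg <- tapply(ov, q, sum)
      cov[which(ok)[as.integer(names(agg))]] <- as.numeric(agg)
    }
  }
  denom <- if (nominal_denominator) window_size else pmax(we - ws, 1)
  100 * cov / denom
}

#' Anchor points for a feature table
#'
#' miRNA loci and generic regions are anchored at their midpoint; genes at
#' their strand-aware TSS.
#'
#' @param features Interval table.
#' @param type "midpoint" or "tss".
#' @return Numeric vector of 0-based anchor offsets.
#' @export
anchor_point <- function(features, type = c("midpoint", "tss")) {
  type <- match.arg(type)
  if (type == "tss") gene_tss(features)
  else floor((features$start + features$end) / 2)
}

#' Sliding density profile along a chromosome
#'
#' Evaluates [density_at_feature()] at anchors `0, step, 2*step, ...` along
#' the chromosome.
#'
#' @inheritParams density_at_feature
#' @param step Step size in bp.
#' @return Data frame (position, density).
#' @export
genome_profile <- function(chrom, elements, chrom_sizes, window_size = 300000,
                           step = 10000) {
  len <- unname(chrom_sizes[[chrom]])
  anchors <- seq(0, len, by = step)
  data.frame(position = anchors,
             density = densities_at_anchors(rep(chrom, length(anchors)),
                                            anchors, elements, chrom_sizes,
                                            window_size))
}

#' Remove peaks overlapping strong HCNEs
#'
#' Drops p300 peaks that overlap (>= 1 bp) any HCNE with percent identity at
#' least `min_identity` and length at least `min_len` — used to show that
#' enhancer-density enrichment is not driven by conserved elements.
#'
#' @param peaks Peak interval table.
#' @param hcnes HCNE table with an `identity_pct` column.
#' @param min_identity Identity threshold, percent (default 98).
#' @param min_len Length threshold, bp (default 50).
#' @return Filtered peak table.
#' @export
exclude_hcne_overlapping_peaks <- function(peaks, hcnes, min_identity = 98,
                                           min_len = 50) {
  if (nrow(peaks) == 0 || nrow(hcnes) == 0) return(peaks)
  strong <- hcnes[hcnes$identity_pct >= min_identity &
                    (hcnes$end - hcnes$start) >= min_len, , drop = FALSE]
  if (nrow(strong) == 0) return(peaks)
  hit <- GenomicRanges::countOverlaps(as_granges(peaks), as_granges(strong))
  out <- peaks[hit == 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
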