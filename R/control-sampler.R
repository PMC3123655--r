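# Matched random control regions.
#
# Controls reproduce the reference set's length multiset, its
# intergenic/intragenic composition and its gene-density distribution by
# exact stratified rejection sampling: each control region copies its
# reference feature's length and context class and must fall in the same
# gene-density bin.

#' Protein-coding gene count in a window centered on an anchor
#'
#' @param chrom,anchor Vectors of chromosome names and 0-based anchor offsets.
#' @param genes Gene table (protein-coding rows counted).
#' @param window_size Window width in bp (default 300 kb).
#' @return Integer vector of overlapping gene counts.
#' @export
gene_density <- function(chrom, anchor, genes, window_size = 300000) {
  pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  if (length(anchor) == 0) return(integer())
  out <- integer(length(anchor))
  if (nrow(pc) == 0) return(out)
  half <- window_size / 2
  ws <- pmax(0, anchor - half)
  we <- anchor + half
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    g <- pc[pc$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    ss <- sort(g$start)
    ee <- sort(g$end)
    # genes overlapping [ws, we): start < we and end > ws
    out[ix] <- findInterval(we[ix] - 0.5, ss) - findInterval(ws[ix], ee)
  }
  out
}

#' Bin gene-density counts
#'
#' Bins are `{0, 1, ..., 9, >=10}` (the last bin open-ended), matching the
#' stratification used when drawing controls.
#'
#' @param counts Integer vector.
#' @param cap Counts at or above `cap` share one bin (default 10).
#' @return Integer bin labels in `0..cap`.
#' @export
gene_density_bin <- function(counts, cap = 10L) {
  pmin(as.integer(counts), cap)
}

#' Context class of candidate regions
#' @keywords internal
region_class <- function(chrom, start, end, genes) {
  pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  n <- length(start)
  if (n == 0) return(character())
  out <- rep("intergenic", n)
  if (nrow(pc) == 0) return(out)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    g <- pc[pc$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    ord <- order(g$start)
    ss <- g$start[ord]
    cend <- cummax(g$end[ord])   # containment works for overlapping genes too
    ee <- sort(g$end)
    novl <- findInterval(end[ix] - 0.5, ss) - findInterval(start[ix], ee)
    idx <- findInterval(start[ix], ss)
    contained <- idx > 0 & cend[pmax(1, idx)] >= end[ix]
    cls <- ifelse(novl == 0, "intergenic",
                  ifelse(contained, "intragenic", "boundary"))
    out[ix] <- cls
  }
  out   # "boundary" straddles a gene edge: matches neither reference class
}

#' Draw matched random control sets
#'
#' For every reference feature and every replicate, one control region with
#' (a) exactly the reference length, (b) the same intergenic/intragenic
#' context (intergenic: no overlap with a protein-coding gene body;
#' intragenic: contained in one), and (c) a gene-density count in the same
#' bin. `category = "protein_coding"` instead samples gene TSS anchors
#' matched on gene-density bin only. Fully reproducible from `seed`.
#'
#' @param reference Classified reference table (chrom, start, end,
#'   class_label, id).
#' @param bundle Annotation bundle (genes + chrom_sizes are used).
#' @param n_sets Number of replicate control sets.
#' @param category "non_coding" or "protein_coding".
#' @param seed Integer seed.
#' @param window_size Gene-density window (default 300 kb).
#' @param max_attempts Per-feature rejection-sampling cap; exceeding it stops
#'   with an error naming the feature and its stratum (a genuinely
#'   unsatisfiable stratum, e.g. intragenic on a gene-free genome, fails
#'   fast; the default cap only trips when no matching region exists at
#'   realistic rarity).
#' @return Data frame of control regions: replicate, ref_id, chrom, start,
#'   end, class_label, density_bin; `attr(, "seed")` records the seed.
#' @export
sample_matched_sets <- function(reference, bundle, n_sets = 100,
                                category = c("non_coding", "protein_coding"),
                                seed = 1, window_size = 300000,
                                max_attempts = 400000) {
  category <- match.arg(category)
  stopifnot(nrow(reference) > 0)
  genes <- bundle$genes
  sizes <- bundle$chrom_sizes
  ref_anchor <- anchor_point(reference)
  ref_bin <- gene_density_bin(gene_density(reference$chrom, ref_anchor, genes,
                                           window_size))
  out <- with_rng_seed(seed, {
    if (category == "protein_coding") {
      pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
      pc_bin <- gene_density_bin(gene_density(pc$chrom, pc$tss, pc,
                                              window_size))
      res <- lapply(seq_len(n_sets), function(r) {
        ix <- vapply(seq_len(nrow(reference)), function(i) {
          pool <- which(pc_bin == ref_bin[i])
          if (!length(pool)) {
            stop(sprintf(
              "no protein-coding control for '%s' (gene-density bin %d)",
              reference$id[i], ref_bin[i]), call. = FALSE)
          }
          pool[sample.int(length(pool), 1)]
        }, integer(1))
        data.frame(replicate = r, ref_id = reference$id,
                   chrom = pc$chrom[ix], start = pc$start[ix],
                   end = pc$end[ix], class_label = "protein_coding",
                   density_bin = pc_bin[ix], anchor = pc$tss[ix],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    } else {
      # one pending unit per (replicate, reference feature); candidates for
      # all pending units are drawn and evaluated together each round
      units <- data.frame(
        replicate = rep(seq_len(n_sets), each = nrow(reference)),
        ref_row = rep(seq_len(nrow(reference)), n_sets))
      units$len <- (reference$end - reference$start)[units$ref_row]
      units$class <- reference$class_label[units$ref_row]
      units$bin <- ref_bin[units$ref_row]
      chrom_names <- names(sizes)
      chrom_prob <- sizes / sum(sizes)
      found <- vector("list", nrow(units))
      pending <- seq_len(nrow(units))
      attempts <- rep(0L, nrow(units))
      round_i <- 0L
      while (length(pending)) {
        round_i <- round_i + 1L
        # rare strata (e.g. intergenic in a gene-dense bin) need many draws;
        # grow the per-unit batch so they converge without flooding round 1
        per_round <- min(256L, 4L * 2L^(round_i %/% 5L))
        over <- pending[attempts[pending] >= max_attempts]
        if (length(over)) {
          i <- units$ref_row[over[1]]
          stop(sprintf(
            "control sampling cap exceeded for '%s' (class %s, bin %d)",
            reference$id[i], reference$class_label[i], ref_bin[i]),
            call. = FALSE)
        }
        u <- rep(pending, each = per_round)
        ch <- sample(chrom_names, length(u), replace = TRUE,
                     prob = chrom_prob)
        maxs <- unname(sizes[ch]) - units$len[u]
        st <- floor(stats::runif(length(u)) * pmax(1, maxs + 1))
        en <- st + units$len[u]
        ok <- maxs >= 0
        cls <- rep(NA_character_, length(u))
        bin <- rep(NA_integer_, length(u))
        if (any(ok)) {
          cls[ok] <- region_class(ch[ok], st[ok], en[ok], genes)
          mid <- floor((st[ok] + en[ok]) / 2)
          bin[ok] <- gene_density_bin(gene_density(ch[ok], mid, genes,
                                                   window_size))
        }
        hit <- ok & cls == units$class[u] & bin == units$bin[u]
        first <- tapply(which(hit), u[hit], function(ix) ix[1])
        for (ix in first) {
          found[[u[ix]]] <- data.frame(
            replicate = units$replicate[u[ix]],
            ref_id = reference$id[units$ref_row[u[ix]]],
            chrom = ch[ix], start = st[ix], end = en[ix],
            class_label = cls[ix], density_bin = bin[ix],
            anchor = floor((st[ix] + en[ix]) / 2), stringsAsFactors = FALSE)
        }
        attempts[pending] <- attempts[pending] + per_round
        pending <- pending[vapply(found[pending], is.null, logical(1))]
      }
      out <- do.call(rbind, found)
      out[order(out$replicate,
                match(out$ref_id, reference$id)), , drop = FALSE]
    }
  })
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Flag features whose density window overlaps a GRB
#'
#' @param features Interval table.
#' @param grbs GRB interval table.
#' @param chrom_sizes Named chromosome lengths.
#' @param window_size Window width centered on the feature midpoint.
#' @return Logical vector, TRUE when the window shares >= 1 bp with any GRB.
#' @export
flag_grb_overlaps <- function(features, grbs, chrom_sizes,
                              window_size = 300000) {
  n <- nrow(features)
  if (n == 0) return(logical())
  if (is.null(grbs) || nrow(grbs) == 0) return(rep(FALSE, n))
  mid <- anchor_point(features)
  half <- window_size / 2
  ws <- pmax(0, mid - half)
  we <- pmin(unname(chrom_sizes[features$chrom]), mid + half)
  wins <- GenomicRanges::GRanges(features$chrom,
                                 IRanges::IRanges(ws + 1, pmax(we, ws + 1)))
  GenomicRanges::countOverlaps(wins, as_granges(grbs)) > 0
}
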