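# Pri-miRNA extent estimation and search-window construction.

#' Fractions of TSSs/TESs within fixed distances of their pre-miRNAs
#'
#' For each primary-transcript model, the TSS distance is the strand-aware 5'
#' gap between the transcript start and the pre-miRNA (0 when the TSS lies
#' inside the pre-miRNA), and analogously for the transcript end. Returns the
#' fractions of models whose TSS lies within `d_up` upstream and whose TES
#' lies within `d_down` downstream.
#'
#' @param models Transcript-model table: mirna_id, chrom, start, end.
#' @param pre_mirnas Pre-miRNA table (stranded, with `id`).
#' @param d_up Upstream cutoff in bp (default 50 kb).
#' @param d_down Downstream cutoff in bp (default 20 kb).
#' @return Named numeric vector `c(tss_within = , tes_within = )`.
#' @export
distance_fractions <- function(models, pre_mirnas, d_up = 50000,
                               d_down = 20000) {
  if (nrow(models) == 0) stop("distance_fractions: no transcript models",
                              call. = FALSE)
  ix <- match(models$mirna_id, pre_mirnas$id)
  if (anyNA(ix)) stop("distance_fractions: model without pre-miRNA",
                      call. = FALSE)
  pre <- pre_mirnas[ix, , drop = FALSE]
  plus <- pre$strand == "+"
  tss_dist <- ifelse(plus, pmax(0, pre$start - models$start),
                     pmax(0, models$end - pre$end))
  tes_dist <- ifelse(plus, pmax(0, models$end - pre$end),
                     pmax(0, pre$start - models$start))
  c(tss_within = mean(tss_dist <= d_up), tes_within = mean(tes_dist <= d_down))
}

#' Build a truncated search window around a miRNA locus
#'
#' The raw window is strand-aware: `full` mode spans `d_up` upstream of the
#' pre-miRNA 5' end to `d_down` downstream of its 3' end; `promoter` mode is
#' the `d_up` bases immediately upstream of the 5' end; `annotated` mode uses
#' the supplied transcript model. The window is clipped to the chromosome and
#' every part overlapping a protein-coding gene body padded by `pad` bp on
#' each side is removed (the locus's own host gene, if any, is not a
#' truncator). By default the remainder segments beyond a truncating gene are
#' kept; `cut_at_first_gene = TRUE` instead keeps only the contiguous region
#' nearest the locus.
#'
#' @param locus Single-row stranded interval table (id, optional host_gene).
#' @param mode "full", "promoter" or "annotated".
#' @param genes Gene table (protein-coding rows are the truncators).
#' @param chrom_sizes Named chromosome lengths.
#' @param transcript Single-row transcript interval (mode = "annotated").
#' @param d_up,d_down Window extents in bp.
#' @param pad Gene padding in bp (default 1 kb).
#' @param cut_at_first_gene Drop remainder segments beyond the first
#'   truncating gene on each side.
#' @return A `search_window`: list(locus_id, mode, chrom, strand, raw =
#'   c(start, end), segments = interval table, empty = flag).
#' @export
build_search_window <- function(locus, mode = c("full", "promoter", "annotated"),
                                genes, chrom_sizes, transcript = NULL,
                                d_up = 50000, d_down = 20000, pad = 1000,
                                cut_at_first_gene = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(locus$chrom) == 1, locus$strand %in% c("+", "-"))
  size <- unname(chrom_sizes[[locus$chrom]])
  plus <- locus$strand == "+"
  raw <- switch(mode,
    full = if (plus) c(locus$start - d_up, locus$end + d_down)
           else c(locus$start - d_down, locus$end + d_up),
    promoter = if (plus) c(locus$start - d_up, locus$start)
               else c(locus$end, locus$end + d_up),
    annotated = {
      if (is.null(transcript)) stop("annotated mode needs a transcript model",
                                    call. = FALSE)
      c(transcript$start, transcript$end)
    })
  raw <- c(max(0, raw[1]), min(size, raw[2]))
  empty_segments <- gintervals(character(), numeric(), numeric())
  if (raw[1] >= raw[2]) {
    return(structure(list(locus_id = locus$id, mode = mode,
                          chrom = locus$chrom, strand = locus$strand,
                          raw = raw, segments = empty_segments, empty = TRUE),
                     class = "search_window"))
  }
  pc <- genes[genes$biotype == "protein_coding" & genes$chrom == locus$chrom, ,
              drop = FALSE]
  if (!is.null(locus$host_gene) && !is.na(locus$host_gene)) {
    pc <- pc[pc$id != locus$host_gene, , drop = FALSE]
  }
  win <- IRanges::IRanges(raw[1] + 1, raw[2])
  segs <- if (nrow(pc)) {
    trunc <- IRanges::reduce(IRanges::IRanges(pmax(0, pc$start - pad) + 1,
                                              pc$end + pad))
    IRanges::setdiff(win, trunc)
  } else {
    win
  }
  seg_df <- if (length(segs)) {
    gintervals(locus$chrom, IRanges::start(segs) - 1, IRanges::end(segs))
  } else empty_segments
  if (cut_at_first_gene && nrow(seg_df) > 0) {
    # keep only the contiguous region containing (or abutting) the locus side
    anchor <- switch(mode,
      promoter = if (plus) locus$start else locus$end,
      if (plus) locus$start else locus$end)
    d <- pmax(seg_df$start - anchor, anchor - seg_df$end, 0)
    seg_df <- seg_df[which.min(d), , drop = FALSE]
  }
  structure(list(locus_id = locus$id, mode = mode, chrom = locus$chrom,
                 strand = locus$strand, raw = raw, segments = seg_df,
                 empty = nrow(seg_df) == 0),
            class = "search_window")
}

#' @export
print.search_window <- function(x, ...) {
  cat(sprintf("<search_window> %s [%s] %s:%s-%s (%d segment%s)\n",
              x$locus_id, x$mode, x$chrom, format_coord(x$raw[1]),
              format_coord(x$raw[2]), nrow(x$segments),
              if (nrow(x$segments) == 1) "" else "s"))
  invisible(x)
}

#' Windows for a whole locus table
#' @param loci Stranded interval table with `id` (and optional host_gene).
#' @inheritParams build_search_window
#' @return Named list of `search_window` objects keyed by locus id.
#' @export
build_search_windows <- function(loci, mode, genes, chrom_sizes, ...) {
  out <- lapply(seq_len(nrow(loci)), function(i) {
    build_search_window(loci[i, , drop = FALSE], mode, genes, chrom_sizes, ...)
  })
  stats::setNames(out, loci$id)
}
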