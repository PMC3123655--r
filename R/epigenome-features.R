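# Bivalent-promoter association and CpG-island features.

#' Bivalent-domain association of a promoter window
#'
#' A locus is associated with a bivalent domain in a cell type iff any domain
#' of that cell type shares at least 1 bp with any segment of the locus's
#' promoter window (50 kb upstream, gene-truncated). For the enriched/poor
#' contingency analysis the association is only defined for intergenic loci
#' (for intragenic loci the chromatin cannot be attributed to the miRNA
#' rather than the host gene), so `intragenic_na = TRUE` returns NA flags
#' there; the genome-wide prediction stage evaluates all ST loci
#' (`intragenic_na = FALSE`).
#'
#' @param window A `search_window` built in promoter mode.
#' @param domains Bivalent-domain table with a `cell_type` column.
#' @param intergenic Is the locus intergenic?
#' @param intragenic_na Return NA flags for intragenic loci.
#' @param cell_types Cell-type vocabulary (defaults to those present).
#' @return Named logical vector, one flag per cell type (or NAs).
#' @export
bivalent_association <- function(window, domains, intergenic = TRUE,
                                 intragenic_na = TRUE,
                                 cell_types = sort(unique(domains$cell_type))) {
  if (length(cell_types) == 0) return(stats::setNames(logical(), character()))
  if (!intergenic && intragenic_na) {
    return(stats::setNames(rep(NA, length(cell_types)), cell_types))
  }
  segs <- window$segments
  if (nrow(segs) == 0) {
    return(stats::setNames(rep(FALSE, length(cell_types)), cell_types))
  }
  seg_gr <- as_granges(segs)
  vapply(stats::setNames(cell_types, cell_types), function(ct) {
    dd <- domains[domains$cell_type == ct, , drop = FALSE]
    nrow(dd) > 0 &&
      sum(GenomicRanges::countOverlaps(seg_gr, as_granges(dd))) > 0
  }, logical(1))
}

#' CpG-island features of a primary transcript
#'
#' `cgi_count` is the number of CGIs sharing at least 1 bp with the
#' transcript; the CpG-to-gene ratio is the number of transcript bases
#' covered by CGIs (CGIs merged first, overlap clipped to the transcript, so
#' the ratio is always <= 1) divided by the transcript length. Loci without a
#' primary transcript model get NA features.
#'
#' @param transcript Single-row transcript interval, or NULL.
#' @param cgis CGI interval table.
#' @return List: cgi_count, cpg_to_gene_ratio, transcript_len (NAs when no
#'   transcript model exists).
#' @export
cgi_features <- function(transcript, cgis) {
  if (is.null(transcript) || nrow(transcript) == 0) {
    return(list(cgi_count = NA_integer_, cpg_to_gene_ratio = NA_real_,
                transcript_len = NA_real_))
  }
  len <- transcript$end - transcript$start
  on_chrom <- cgis[cgis$chrom == transcript$chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0) {
    return(list(cgi_count = 0L, cpg_to_gene_ratio = 0, transcript_len = len))
  }
  ov <- pmin(on_chrom$end, transcript$end) - pmax(on_chrom$start,
                                                  transcript$start)
  count <- sum(ov > 0)
  bases <- coverage_bp(transcript, on_chrom)
  list(cgi_count = as.integer(count), cpg_to_gene_ratio = bases / len,
       transcript_len = len)
}

#' Number of distinct CGIs overlapping a search window
#'
#' Counts CGIs sharing at least 1 bp with any window segment; a CGI spanning
#' several (truncated) segments is counted once.
#'
#' @param window A `search_window` (full mode: 50 kb up / 20 kb down).
#' @param cgis CGI interval table.
#' @return Integer count.
#' @export
cgi_count_in_window <- function(window, cgis) {
  if (nrow(window$segments) == 0 || nrow(cgis) == 0) return(0L)
  hit <- GenomicRanges::countOverlaps(as_granges(cgis),
                                      as_granges(window$segments))
  sum(hit > 0)
}
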