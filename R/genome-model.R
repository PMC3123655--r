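# Coordinate model and annotation-track I/O.
#
# All intervals are 0-based half-open [start, end), BED-native; GFF (1-based,
# inclusive) is converted on read. Overlap means >= 1 shared base throughout.

#' Construct a validated interval table
#'
#' The universal coordinate unit of the package: a data frame with columns
#' `chrom`, `start`, `end` (0-based half-open) and optionally `strand`
#' (`"+"`, `"-"` or `"*"` for unstranded).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-valued offsets, `0 <= start < end`.
#' @param strand Optional strand vector; recycled. `"*"` means unstranded.
#' @param ... Further equal-length columns appended to the table.
#' @return A `data.frame` with one row per interval.
#' @export
gintervals <- function(chrom, start, end, strand = NULL, ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- rep_len(as.character(strand), nrow(df))
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  df
}

#' @keywords internal
validate_intervals <- function(df, where = "intervals") {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("%s: invalid coordinates (need 0 <= start < end) at row %d",
                 where, bad[1]), call. = FALSE)
  }
  if (!is.null(df$strand)) {
    bad_strand <- which(!df$strand %in% c("+", "-", "*"))
    if (length(bad_strand)) {
      stop(sprintf("%s: unknown strand '%s' at row %d", where,
                   df$strand[bad_strand[1]], bad_strand[1]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Convert an interval table to GRanges (1-based, for overlap machinery)
#' @keywords internal
as_granges <- function(df, use_strand = FALSE) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  strand <- if (use_strand && !is.null(df$strand)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand
  )
}

#' Merge overlapping intervals on one chromosome
#'
#' Returns the sorted union of the input intervals: pairwise non-overlapping,
#' covering exactly the same bases. Strand is ignored (result is unstranded).
#'
#' @param intervals Interval table, all rows on the same chromosome.
#' @return Interval table of merged intervals, sorted by start.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(gintervals(character(), numeric(), numeric()))
  }
  if (length(unique(intervals$chrom)) > 1) {
    stop("merge_intervals: intervals span multiple chromosomes", call. = FALSE)
  }
  ir <- IRanges::reduce(IRanges::IRanges(intervals$start + 1, intervals$end))
  gintervals(intervals$chrom[1], IRanges::start(ir) - 1, IRanges::end(ir))
}

#' Bases of a window covered by a set of elements
#'
#' Number of bases of `window` covered by at least one element (elements are
#' merged first, so overlaps are not double-counted).
#'
#' @param window A single-row interval table (or list with chrom/start/end).
#' @param elements Interval table of covering elements (any chromosomes;
#'   only those on the window's chromosome contribute).
#' @return Integer base count in `[0, end - start]`.
#' @export
coverage_bp <- function(window, elements) {
  stopifnot(length(window$chrom) == 1)
  el <- elements[elements$chrom == window$chrom, , drop = FALSE]
  if (nrow(el) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(el$start + 1, el$end))
  win <- IRanges::IRanges(window$start + 1, window$end)
  sum(IRanges::width(IRanges::intersect(ir, win)))
}

# ---- readers / writers ------------------------------------------------------

#' Read a BED file (BED3/6/12 plus package dialects)
#'
#' BED is 0-based half-open. Columns beyond the third are mapped to
#' `name`, `score`, `strand` when present; `col_names` renames them (e.g.
#' `c("name" = "cell_type")` for bivalent-domain tracks, or
#' `c("score" = "identity_pct")` for HCNE tracks).
#'
#' @param path File path.
#' @param col_names Optional named character vector renaming standard columns.
#' @return Interval table.
#' @export
read_bed <- function(path, col_names = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(gintervals(character(), numeric(), numeric()))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    stop(sprintf("%s: line %d: fewer than 3 BED fields", path,
                 idx[which(ncols < 3)[1]]), call. = FALSE)
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("%s: line %d: invalid BED coordinates '%s'", path, idx[bad[1]],
                 lines[idx[bad[1]]]), call. = FALSE)
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  nmax <- max(ncols)
  if (nmax >= 4) df$name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  if (nmax >= 5) df$score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_, "")))
  if (nmax >= 6) {
    df$strand <- vapply(fields, function(f) if (length(f) >= 6) f[6] else "*", "")
    df$strand[df$strand == "."] <- "*"
    bad_strand <- which(!df$strand %in% c("+", "-", "*"))
    if (length(bad_strand)) {
      stop(sprintf("%s: line %d: unknown strand '%s'", path, idx[bad_strand[1]],
                   df$strand[bad_strand[1]]), call. = FALSE)
    }
  }
  if (!is.null(col_names)) {
    for (old in names(col_names)) {
      names(df)[names(df) == old] <- col_names[[old]]
    }
  }
  df
}

#' Write an interval table as BED
#'
#' Inverse of [read_bed()]: `read_bed(write_bed(x, f))` is the identity on
#' canonical records.
#'
#' @param df Interval table; optional `name`, `score`, `strand` columns are
#'   emitted as BED columns 4-6.
#' @param path Output path.
#' @param extra_as Optional named vector mapping dialect columns back onto
#'   standard BED columns (inverse of `col_names` in [read_bed()]).
#' @export
write_bed <- function(df, path, extra_as = NULL) {
  if (!is.null(extra_as)) {
    for (std in names(extra_as)) {
      names(df)[names(df) == extra_as[[std]]] <- std
    }
  }
  cols <- list(df$chrom, format_coord(df$start), format_coord(df$end))
  if (!is.null(df$name) || !is.null(df$score) || !is.null(df$strand)) {
    cols <- c(cols, list(if (is.null(df$name)) rep(".", nrow(df)) else df$name))
  }
  if (!is.null(df$score) || !is.null(df$strand)) {
    cols <- c(cols, list(if (is.null(df$score)) rep(0, nrow(df)) else df$score))
  }
  if (!is.null(df$strand)) {
    s <- df$strand
    s[s == "*"] <- "."
    cols <- c(cols, list(s))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' @keywords internal
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read gene models from GFF3
#'
#' Keeps `gene` features; coordinates are converted from GFF's 1-based
#' inclusive convention to the internal 0-based half-open one. Gene id is
#' taken from the `ID` attribute and biotype from `biotype`/`gene_biotype`
#' (defaulting to `"other"` when absent).
#'
#' @param path GFF3 file path.
#' @return Gene table with columns chrom, start, end, strand, id, biotype and
#'   `tss` (strand-aware 5' base offset).
#' @export
read_gff_genes <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  if (nrow(g)) g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) {
    return(gintervals(character(), numeric(), numeric(), strand = character(),
                      id = character(), biotype = character(), tss = numeric()))
  }
  bad <- which(g$start > g$end | g$start < 1)
  if (length(bad)) {
    stop(sprintf("%s: gene feature %d: invalid GFF coordinates %d..%d", path,
                 bad[1], g$start[bad[1]], g$end[bad[1]]), call. = FALSE)
  }
  strand <- as.character(g$strand)
  if (any(!strand %in% c("+", "-"))) {
    stop(sprintf("%s: gene feature %d: genes must be stranded", path,
                 which(!strand %in% c("+", "-"))[1]), call. = FALSE)
  }
  bt <- if (!is.null(g$biotype)) as.character(g$biotype)
        else if (!is.null(g$gene_biotype)) as.character(g$gene_biotype)
        else rep("other", nrow(g))
  bt[is.na(bt)] <- "other"
  id <- if (!is.null(g$ID)) as.character(g$ID) else paste0("gene", seq_len(nrow(g)))
  out <- gintervals(as.character(g$seqid), g$start - 1, g$end, strand = strand,
                    id = id, biotype = bt)
  out$tss <- gene_tss(out)
  out
}

#' Write gene models as GFF3
#' @param genes Gene table (see [read_gff_genes()]).
#' @param path Output path.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- c("##gff-version 3")
  if (nrow(genes)) {
    lines <- c(lines, sprintf(
      "%s\tmirgrb\tgene\t%s\t%s\t.\t%s\t.\tID=%s;biotype=%s",
      genes$chrom, format_coord(genes$start + 1), format_coord(genes$end),
      genes$strand, genes$id, genes$biotype))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Strand-aware TSS (5' base offset) of genes
#' @param genes Gene table with strand.
#' @return Numeric vector of 0-based base offsets.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' Read a two-column chrom.sizes file
#' @param path File path (chrom, length; tab- or space-separated).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$size, tab$chrom)
}

#' Write a chrom.sizes file
#' @param sizes Named numeric vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), format_coord(sizes), sep = "\t"), path)
  invisible(path)
}

#' Check every interval of a bundle against its chromosome bounds
#' @keywords internal
check_bounds <- function(df, chrom_sizes, what = "track") {
  if (is.null(df) || nrow(df) == 0) return(invisible(TRUE))
  sz <- chrom_sizes[df$chrom]
  if (anyNA(sz)) {
    stop(sprintf("%s: unknown chromosome '%s'", what,
                 df$chrom[which(is.na(sz))[1]]), call. = FALSE)
  }
  if (any(df$start < 0 | df$end > sz)) {
    stop(sprintf("%s: interval outside chromosome bounds", what), call. = FALSE)
  }
  invisible(TRUE)
}
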