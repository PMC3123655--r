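# Reciprocal best-hit miRNA orthology by exact local alignment.
#
# At miRNA lengths (~60-120 nt precursors, ~22 nt matures) exact
# Smith-Waterman is cheap and fully reproducible, so the homology search is
# done by optimal local alignment under BLASTN-like affine-gap scoring
# (match +2, mismatch -3, gap open 5, gap extend 2), searching both strands
# of the subject.

#' Default alignment scoring
#' @export
default_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2)
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman local alignment with affine gaps (via Biostrings). U is
#' treated as T; both strands of the subject are searched and the better
#' orientation kept (forward wins ties).
#'
#' @param query,subject Nucleotide strings over A/C/G/T/U, length >= 1.
#' @param scoring List with match, mismatch, gap_open, gap_extend (a gap of
#'   length k costs `gap_open + k * gap_extend`).
#' @param both_strands Search the reverse complement of the subject too.
#' @return A `local_alignment` object: score, strand, aligned_query_len,
#'   aligned_subject_len, mismatches, gap_columns, query_len, subject_len,
#'   and per-position match status for query and subject (named logical
#'   vectors over the 1-based positions inside the aligned region; TRUE =
#'   aligned to an identical base, FALSE = mismatch or opposite a gap).
#' @export
local_align <- function(query, subject, scoring = default_scoring(),
                        both_strands = TRUE) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("local_align: empty sequence", call. = FALSE)
  }
  q <- norm_seq(query)
  s <- norm_seq(subject)
  fwd <- align_one(q, s, scoring, "+")
  if (!both_strands) return(fwd)
  rev <- align_one(q, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))), scoring, "-")
  if (rev$score > fwd$score) rev else fwd
}

#' @keywords internal
norm_seq <- function(x) chartr("U", "T", toupper(x))

#' @keywords internal
align_one <- function(q, s, scoring, strand) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    pattern = q, subject = s, type = "local", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  qpos <- Biostrings::start(Biostrings::pattern(al)) - 1 + cumsum(pat != "-")
  spos_fwd <- Biostrings::start(Biostrings::subject(al)) - 1 + cumsum(sub != "-")
  # subject positions reported on the original (forward) subject coordinates
  spos <- if (strand == "+") spos_fwd else nchar(s) - spos_fwd + 1
  is_col_match <- pat != "-" & sub != "-" & pat == sub
  qstat <- stats::setNames(is_col_match[pat != "-"],
                           qpos[pat != "-"])
  sstat <- stats::setNames(is_col_match[sub != "-"],
                           spos[sub != "-"])
  structure(list(
    score = as.numeric(Biostrings::score(al)),
    strand = strand,
    aligned_query_len = sum(pat != "-"),
    aligned_subject_len = sum(sub != "-"),
    mismatches = sum(pat != "-" & sub != "-" & pat != sub),
    gap_columns = sum(pat == "-" | sub == "-"),
    query_len = nchar(q),
    subject_len = nchar(s),
    query_match_status = qstat,
    subject_match_status = sstat
  ), class = "local_alignment")
}

#' Precursor-level ortholog filter
#'
#' A precursor hit passes when the aligned region covers at least 56% of the
#' query length and the alignment contains at most 10 gapped columns.
#' Percentage thresholds are compared on integers (`aligned * 100 >= 56 *
#' len`) so boundaries are exact.
#'
#' @param a A `local_alignment`.
#' @param query_len Query length in bases (defaults to the alignment's).
#' @param min_aligned_pct Minimum aligned fraction of the query, percent.
#' @param max_gap Maximum gapped columns.
#' @return TRUE/FALSE.
#' @export
filter_precursor_hit <- function(a, query_len = a$query_len,
                                 min_aligned_pct = 56, max_gap = 10) {
  a$aligned_query_len * 100 >= min_aligned_pct * query_len &&
    a$gap_columns <= max_gap
}

#' Mature-level ortholog filter
#'
#' A mature hit passes when the aligned region covers at least 80% of the
#' query, there are at most 3 non-matching aligned bases, and the seed region
#' (query positions 2-8 inclusive) is fully aligned without mismatch or gap.
#'
#' @inheritParams filter_precursor_hit
#' @param max_mismatches Maximum mismatching aligned bases.
#' @param seed_positions Query positions that must be conserved.
#' @return TRUE/FALSE.
#' @export
filter_mature_hit <- function(a, query_len = a$query_len,
                              min_aligned_pct = 80, max_mismatches = 3,
                              seed_positions = 2:8) {
  seed_ok <- all(as.character(seed_positions) %in%
                   names(a$query_match_status)) &&
    all(a$query_match_status[as.character(seed_positions)])
  a$aligned_query_len * 100 >= min_aligned_pct * query_len &&
    a$mismatches <= max_mismatches && seed_ok
}

#' Reciprocal best-hit orthologs between two miRNA catalogs
#'
#' All-vs-all local alignment of precursor sequences; a pair is reported when
#' each sequence is the other's unique top-scoring hit among hits passing the
#' precursor filter (score ties for best hit make the query ambiguous: no
#' pair). Queries unmatched at the precursor level are retried with their
#' mature sequences under the mature filter. The result is one-to-one.
#'
#' @param a_seqs,b_seqs Named character vectors of precursor sequences.
#' @param a_mature,b_mature Optional named character vectors of mature
#'   sequences, keyed by the same ids.
#' @param scoring Alignment scoring, see [local_align()].
#' @return Data frame: a_id, b_id, level ("precursor"/"mature"), score.
#' @export
reciprocal_best_orthologs <- function(a_seqs, b_seqs,
                                      a_mature = NULL, b_mature = NULL,
                                      scoring = default_scoring()) {
  pairs <- rbh_level(a_seqs, b_seqs, scoring, level = "precursor")
  res <- pairs
  left_a <- setdiff(names(a_seqs), pairs$a_id)
  left_b <- setdiff(names(b_seqs), pairs$b_id)
  if (!is.null(a_mature) && !is.null(b_mature)) {
    am <- a_mature[intersect(left_a, names(a_mature))]
    bm <- b_mature[intersect(left_b, names(b_mature))]
    if (length(am) && length(bm)) {
      res <- rbind(res, rbh_level(am, bm, scoring, level = "mature"))
    }
  }
  rownames(res) <- NULL
  res
}

#' @keywords internal
rbh_level <- function(a_seqs, b_seqs, scoring, level) {
  empty <- data.frame(a_id = character(), b_id = character(),
                      level = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(a_seqs) || !length(b_seqs)) return(empty)
  na <- length(a_seqs); nb <- length(b_seqs)
  # all-vs-all statistics from vectorized alignment, one call per subject
  # and strand; identical scoring to local_align()
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  qset <- Biostrings::DNAStringSet(vapply(a_seqs, norm_seq, ""))
  batch <- function(subj) {
    al <- Biostrings::pairwiseAlignment(
      qset, subj, type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    ni <- Biostrings::nindel(al)
    ins <- Biostrings::insertion(ni)[, "WidthSum"]
    del <- Biostrings::deletion(ni)[, "WidthSum"]
    cols <- Biostrings::nchar(al)
    list(score = Biostrings::score(al), q_aligned = cols - del,
         s_aligned = cols - ins, mismatches = Biostrings::nmismatch(al),
         gaps = ins + del)
  }
  score <- q_al <- s_al <- mm <- gaps <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    s <- norm_seq(b_seqs[[j]])
    fwd <- batch(s)
    rev <- batch(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))))
    use_rev <- rev$score > fwd$score     # forward wins ties, as local_align
    pick <- function(f) ifelse(use_rev, rev[[f]], fwd[[f]])
    score[, j] <- pick("score")
    q_al[, j] <- pick("q_aligned")
    s_al[, j] <- pick("s_aligned")
    mm[, j] <- pick("mismatches")
    gaps[, j] <- pick("gaps")
  }
  qlen <- nchar(vapply(a_seqs, norm_seq, ""))
  slen <- nchar(vapply(b_seqs, norm_seq, ""))
  if (level == "precursor") {
    pass_ab <- q_al * 100 >= 56 * qlen & gaps <= 10
    pass_ba <- t(t(s_al * 100) >= 56 * slen) & gaps <= 10
  } else {
    # prefilter on aligned fraction and mismatches; the seed rule needs the
    # full alignment, so it is checked per candidate pair below
    pre_ab <- q_al * 100 >= 80 * qlen & mm <= 3
    pre_ba <- t(t(s_al * 100) >= 80 * slen) & mm <= 3
    pass_ab <- pre_ab
    pass_ba <- pre_ba
    for (ix in which(pre_ab | pre_ba)) {
      i <- (ix - 1) %% na + 1
      j <- (ix - 1) %/% na + 1
      al <- local_align(a_seqs[[i]], b_seqs[[j]], scoring)
      pass_ab[i, j] <- pre_ab[i, j] && filter_mature_hit(al)
      pass_ba[i, j] <- pre_ba[i, j] &&
        filter_mature_hit(swap_alignment(al))
    }
  }
  best_a <- vapply(seq_len(na), function(i) {
    ok <- which(pass_ab[i, ])
    if (!length(ok)) return(NA_integer_)
    top <- max(score[i, ok])
    cand <- ok[score[i, ok] == top]
    if (length(cand) == 1L) cand else NA_integer_
  }, integer(1))
  best_b <- vapply(seq_len(nb), function(j) {
    ok <- which(pass_ba[, j])
    if (!length(ok)) return(NA_integer_)
    top <- max(score[ok, j])
    cand <- ok[score[ok, j] == top]
    if (length(cand) == 1L) cand else NA_integer_
  }, integer(1))
  mutual <- !is.na(best_a)
  mutual[mutual] <- !is.na(best_b[best_a[mutual]]) &
    best_b[best_a[mutual]] == which(mutual)
  keep <- which(mutual)
  if (!length(keep)) return(empty)
  data.frame(a_id = names(a_seqs)[keep], b_id = names(b_seqs)[best_a[keep]],
             level = level, score = score[cbind(keep, best_a[keep])],
             stringsAsFactors = FALSE)
}

#' Swap query and subject roles of an alignment
#' @keywords internal
swap_alignment <- function(a) {
  structure(list(
    score = a$score, strand = a$strand,
    aligned_query_len = a$aligned_subject_len,
    aligned_subject_len = a$aligned_query_len,
    mismatches = a$mismatches, gap_columns = a$gap_columns,
    query_len = a$subject_len, subject_len = a$query_len,
    query_match_status = a$subject_match_status,
    subject_match_status = a$query_match_status
  ), class = "local_alignment")
}
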