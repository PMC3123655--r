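test_that("local alignment matches the independent DP oracle on short pairs", {
  q <- paste(rep("ACGUAUGCGUACGGAUCGAUGC", 1), collapse = "")
  a <- local_align(q, q)
  expect_equal(a$score, 44)   # identical 22-mers at match +2
  expect_equal(a$mismatches, 0)
  expect_equal(a$gap_columns, 0)
  expect_equal(a$aligned_query_len, 22)

  set.seed(31)
  alph <- c("A", "C", "G", "U")
  for (i in 1:25) {
    n1 <- sample(8:30, 1); n2 <- sample(8:30, 1)
    s1 <- paste(sample(alph, n1, TRUE), collapse = "")
    s2 <- paste(sample(alph, n2, TRUE), collapse = "")
    got <- local_align(s1, s2, both_strands = FALSE)$score
    expect_equal(got, sw_score_oracle(s1, s2), info = paste(s1, s2))
  }
})

test_that("both subject strands are searched and the better orientation kept", {
  set.seed(32)
  q <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
  rc <- revcomp_rna(q)
  a <- local_align(q, rc)
  expect_equal(a$score, 60)          # perfect on the reverse strand
  expect_equal(a$strand, "-")
  # brute force over both orientations
  expect_equal(a$score, max(sw_score_oracle(q, rc),
                            sw_score_oracle(q, revcomp_rna(rc))))
  fwd_only <- local_align(q, rc, both_strands = FALSE)
  expect_lt(fwd_only$score, a$score)
  expect_error(local_align("", "ACGU"), "empty")
})

fake_alignment <- function(aligned_query_len, mismatches = 0, gap_columns = 0,
                           query_len = 100, match_status = NULL) {
  if (is.null(match_status)) {
    match_status <- stats::setNames(rep(TRUE, aligned_query_len),
                                    seq_len(aligned_query_len))
  }
  structure(list(score = 0, strand = "+",
                 aligned_query_len = aligned_query_len,
                 aligned_subject_len = aligned_query_len,
                 mismatches = mismatches, gap_columns = gap_columns,
                 query_len = query_len, subject_len = query_len,
                 query_match_status = match_status,
                 subject_match_status = match_status),
            class = "local_alignment")
}

test_that("precursor filter boundaries: 56% aligned and 10 gap columns", {
  expect_true(filter_precursor_hit(fake_alignment(56, query_len = 100)))
  expect_false(filter_precursor_hit(fake_alignment(55, query_len = 100)))
  expect_true(filter_precursor_hit(fake_alignment(60, gap_columns = 10,
                                                  query_len = 100)))
  expect_false(filter_precursor_hit(fake_alignment(60, gap_columns = 11,
                                                   query_len = 100)))
})

test_that("mature filter boundaries: 80% aligned, 3 mismatches, seed 2-8", {
  # 18 of 22 aligned (81.8%), 2 mismatches outside the seed -> pass
  ms <- stats::setNames(rep(TRUE, 18), 1:18)
  ms[c("12", "15")] <- FALSE
  expect_true(filter_mature_hit(fake_alignment(18, mismatches = 2,
                                               query_len = 22,
                                               match_status = ms)))
  # 17 of 22 aligned (77.3%) -> fail
  expect_false(filter_mature_hit(fake_alignment(17, query_len = 22)))
  # boundary: exactly 80% of 20 passes
  expect_true(filter_mature_hit(fake_alignment(16, query_len = 20)))
  # 4 mismatches -> fail even with seed intact
  ms4 <- stats::setNames(rep(TRUE, 20), 1:20)
  ms4[c("10", "12", "15", "18")] <- FALSE
  expect_false(filter_mature_hit(fake_alignment(20, mismatches = 4,
                                                query_len = 22,
                                                match_status = ms4)))
  # a single mismatch at query position 5 breaks the seed rule
  ms5 <- stats::setNames(rep(TRUE, 20), 1:20)
  ms5["5"] <- FALSE
  expect_false(filter_mature_hit(fake_alignment(20, mismatches = 1,
                                                query_len = 22,
                                                match_status = ms5)))
  # seed position absent from the aligned region -> fail
  ms_abs <- stats::setNames(rep(TRUE, 18), 5:22)
  expect_false(filter_mature_hit(fake_alignment(18, query_len = 22,
                                                match_status = ms_abs)))
})

test_that("filters are monotone: improving an alignment never flips pass to fail", {
  base <- fake_alignment(60, mismatches = 3, gap_columns = 8, query_len = 100)
  expect_true(filter_precursor_hit(base))
  better <- fake_alignment(70, mismatches = 1, gap_columns = 4,
                           query_len = 100)
  expect_true(filter_precursor_hit(better))
})

test_that("reciprocal best hits recover mutated ortholog catalogs one-to-one", {
  set.seed(33)
  alph <- c("A", "C", "G", "U")
  n <- 10
  a_seqs <- stats::setNames(
    vapply(1:n, function(i) paste(sample(alph, 80, TRUE), collapse = ""), ""),
    sprintf("hsa-%02d", 1:n))
  mutate1 <- function(s, k = 6) {
    b <- strsplit(s, "")[[1]]
    ix <- sample(seq_along(b), k)
    b[ix] <- vapply(b[ix], function(x) sample(setdiff(alph, x), 1), "")
    paste(b, collapse = "")
  }
  perm <- sample(n)
  b_seqs <- stats::setNames(vapply(a_seqs[perm], mutate1, ""),
                            sprintf("dre-%02d", 1:n))
  pairs <- reciprocal_best_orthologs(a_seqs, b_seqs)
  expect_equal(nrow(pairs), n)
  expect_equal(pairs$level, rep("precursor", n))
  # truth pairing: b_j derives from a_{perm[j]}
  truth <- stats::setNames(sprintf("dre-%02d", order(perm)), names(a_seqs))
  expect_equal(stats::setNames(pairs$b_id, pairs$a_id)[names(truth)], truth)
  # one-to-one
  expect_false(any(duplicated(pairs$a_id)))
  expect_false(any(duplicated(pairs$b_id)))
})

test_that("self-comparison maps every sequence to itself", {
  set.seed(34)
  alph <- c("A", "C", "G", "U")
  seqs <- stats::setNames(
    vapply(1:6, function(i) paste(sample(alph, 70, TRUE), collapse = ""), ""),
    sprintf("s%d", 1:6))
  pairs <- reciprocal_best_orthologs(seqs, seqs)
  expect_equal(nrow(pairs), 6)
  expect_equal(pairs$a_id, pairs$b_id)
})

test_that("non-reciprocal best hits and score ties produce no pair", {
  set.seed(35)
  alph <- c("A", "C", "G", "U")
  a1 <- paste(sample(alph, 80, TRUE), collapse = "")
  # B1 close to A1; A2 identical to B1 -> B1's best is A2, so A1 gets no pair
  b1 <- local_mut <- strsplit(a1, "")[[1]]
  b1[c(3, 9, 20)] <- vapply(b1[c(3, 9, 20)],
                            function(x) sample(setdiff(alph, x), 1), "")
  b1 <- paste(b1, collapse = "")
  a_seqs <- c(A1 = a1, A2 = b1)
  b_seqs <- c(B1 = b1)
  pairs <- reciprocal_best_orthologs(a_seqs, b_seqs)
  expect_equal(pairs$a_id, "A2")
  expect_equal(pairs$b_id, "B1")
  # exact duplicate queries tie for the best hit -> ambiguity, no pair at all
  pairs_tie <- reciprocal_best_orthologs(c(A1 = a1, A2 = a1), c(B1 = a1))
  expect_equal(nrow(pairs_tie), 0)
})

test_that("queries unmatched at precursor level fall back to mature sequences", {
  set.seed(36)
  alph <- c("A", "C", "G", "U")
  # precursors unrelated, matures near-identical outside the seed
  a_pre <- c(X = paste(sample(alph, 80, TRUE), collapse = ""))
  b_pre <- c(Y = paste(sample(alph, 80, TRUE), collapse = ""))
  mat <- paste(sample(alph, 22, TRUE), collapse = "")
  mat_mut <- strsplit(mat, "")[[1]]
  mat_mut[12] <- sample(setdiff(alph, mat_mut[12]), 1)
  pairs <- reciprocal_best_orthologs(
    a_pre, b_pre, a_mature = c(X = mat),
    b_mature = c(Y = paste(mat_mut, collapse = "")))
  if (nrow(pairs) == 1) {
    expect_equal(pairs$level, "mature")
    expect_equal(pairs$a_id, "X")
  } else {
    # the random precursors happened to pass the precursor filter; the
    # mapping must then already be one-to-one at precursor level
    expect_equal(pairs$level, "precursor")
  }
})
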