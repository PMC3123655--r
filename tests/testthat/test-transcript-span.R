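test_that("TSS/TES distance fractions count strand-aware gaps", {
  # 93 of 100 TSSs within 50 kb upstream; TES all within 20 kb
  pre <- gintervals("chr1", seq(100000, by = 200000, length.out = 100),
                    seq(100000, by = 200000, length.out = 100) + 80,
                    strand = "+", id = sprintf("m%03d", 1:100))
  off_up <- c(rep(40000, 93), rep(60001, 7))
  models <- data.frame(mirna_id = pre$id, chrom = "chr1",
                       start = pre$start - off_up, end = pre$end + 5000)
  expect_equal(unname(distance_fractions(models, pre)["tss_within"]), 0.93)
  expect_equal(unname(distance_fractions(models, pre)["tes_within"]), 1.0)

  # a TSS inside the pre-miRNA has distance 0
  one <- pre[1, , drop = FALSE]
  inside <- data.frame(mirna_id = one$id, chrom = "chr1",
                       start = one$start + 10, end = one$end + 100)
  expect_equal(unname(distance_fractions(inside, one)["tss_within"]), 1.0)

  # minus strand mirrors the arithmetic
  mone <- one
  mone$strand <- "-"
  mmod <- data.frame(mirna_id = mone$id, chrom = "chr1",
                     start = mone$start - 15000, end = mone$end + 40000)
  expect_equal(unname(distance_fractions(mmod, mone, d_up = 50000,
                                         d_down = 20000)["tss_within"]), 1.0)
  expect_equal(unname(distance_fractions(mmod, mone)["tes_within"]), 1.0)

  expect_error(distance_fractions(models[0, ], pre), "no transcript models")
})

sizes1 <- c(chr1 = 1e6)
no_genes <- gintervals(character(), numeric(), numeric(), strand = character(),
                       id = character(), biotype = character())

test_that("promoter windows are strand-aware and clipped at chromosome ends", {
  minus <- gintervals("chr1", 1000, 1100, strand = "-", id = "m1")
  w <- build_search_window(minus, "promoter", no_genes, sizes1)
  expect_equal(w$raw, c(1100, 51100))
  expect_equal(w$segments$start, 1100)
  expect_equal(w$segments$end, 51100)

  plus_at_start <- gintervals("chr1", 2000, 2100, strand = "+", id = "m2")
  w2 <- build_search_window(plus_at_start, "promoter", no_genes, sizes1)
  expect_equal(w2$raw, c(0, 2000))    # clipped at the chromosome start

  minus_at_end <- gintervals("chr1", 990000, 990100, strand = "-", id = "m3")
  w3 <- build_search_window(minus_at_end, "full", no_genes, sizes1)
  expect_equal(w3$raw, c(970000, 1e6))  # clipped at the chromosome end
})

test_that("gene bodies plus 1 kb padding truncate windows, keeping remainders", {
  genes <- gintervals("chr1", 20000, 25000, strand = "+", id = "g1",
                      biotype = "protein_coding")
  genes$tss <- gene_tss(genes)
  pre <- gintervals("chr1", 10000, 10080, strand = "+", id = "m1")
  w <- build_search_window(pre, "full", genes, sizes1)
  # downstream segment ends at gene start - pad = 19000; the remainder beyond
  # the padded gene (26000..raw end) is kept
  expect_equal(w$segments$end[1], 19000)
  expect_equal(w$segments$start[2], 26000)
  expect_equal(w$segments$end[2], 30080)   # raw end = 10080 + 20000

  # cut_at_first_gene keeps only the locus-adjacent region
  wc <- build_search_window(pre, "full", genes, sizes1,
                            cut_at_first_gene = TRUE)
  expect_equal(nrow(wc$segments), 1)
  expect_equal(wc$segments$end, 19000)

  # the locus's own host gene never truncates its window
  host <- gintervals("chr1", 9000, 12000, strand = "+", id = "ghost",
                     biotype = "protein_coding")
  host$tss <- gene_tss(host)
  pre_in <- pre
  pre_in$host_gene <- "ghost"
  wh <- build_search_window(pre_in, "full", host, sizes1)
  expect_equal(nrow(wh$segments), 1)
  expect_equal(wh$segments$start, wh$raw[1])

  # fully covered window comes back empty but flagged, not an error
  big_gene <- gintervals("chr1", 0, 900000, strand = "+", id = "gbig",
                         biotype = "protein_coding")
  big_gene$tss <- gene_tss(big_gene)
  we <- build_search_window(pre, "promoter", big_gene, sizes1)
  expect_true(we$empty)
  expect_equal(nrow(we$segments), 0)
})

test_that("annotated mode uses the transcript model minus truncations", {
  genes <- gintervals("chr1", 40000, 45000, strand = "+", id = "g1",
                      biotype = "protein_coding")
  genes$tss <- gene_tss(genes)
  pre <- gintervals("chr1", 30000, 30080, strand = "+", id = "m1")
  tr <- gintervals("chr1", 25000, 60000)
  w <- build_search_window(pre, "annotated", genes, sizes1, transcript = tr)
  expect_equal(w$raw, c(25000, 60000))
  expect_equal(w$segments$start, c(25000, 46000))
  expect_equal(w$segments$end, c(39000, 60000))
  expect_error(build_search_window(pre, "annotated", genes, sizes1),
               "transcript")
})

test_that("window segments never intersect protein-coding genes +/- pad", {
  set.seed(51)
  for (rep in 1:5) {
    gstart <- sort(floor(runif(12) * 9e5))
    genes <- gintervals("chr1", gstart, gstart + 5000,
                        strand = sample(c("+", "-"), 12, TRUE),
                        id = sprintf("g%02d", 1:12),
                        biotype = "protein_coding")
    genes$tss <- gene_tss(genes)
    pre <- gintervals("chr1", 450000, 450080,
                      strand = sample(c("+", "-"), 1), id = "m")
    w <- build_search_window(pre, "full", genes, sizes1)
    for (i in seq_len(nrow(w$segments))) {
      seg <- w$segments[i, ]
      expect_true(seg$start >= w$raw[1] && seg$end <= w$raw[2])
      ov <- pmin(genes$end + 1000, seg$end) - pmax(genes$start - 1000,
                                                   seg$start)
      expect_true(all(ov <= 0))
    }
  }
})

test_that("swapping strand mirrors the raw window around the locus", {
  size_sym <- c(chr1 = 1e6)
  mid_lo <- 499950
  mid_hi <- 500050   # locus symmetric around 500000
  plus <- gintervals("chr1", mid_lo, mid_hi, strand = "+", id = "p")
  minus <- gintervals("chr1", mid_lo, mid_hi, strand = "-", id = "q")
  wp <- build_search_window(plus, "full", no_genes, size_sym)
  wm <- build_search_window(minus, "full", no_genes, size_sym)
  expect_equal(1e6 - rev(wm$raw), wp$raw)
})
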