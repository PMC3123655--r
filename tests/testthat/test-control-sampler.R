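make_genome <- function(seed = 71, n_genes = 60, size = 5e6) {
  set.seed(seed)
  g <- numeric(0)
  while (length(g) < n_genes) {
    cand <- sort(floor(runif(2 * n_genes) * (size - 30000)))
    keep <- c(TRUE, diff(cand) > 30000)
    g <- cand[keep][seq_len(min(n_genes, sum(keep)))]
  }
  genes <- gintervals("chr1", g, g + 10000 + floor(runif(length(g)) * 15000),
                      strand = "+", id = sprintf("g%03d", seq_along(g)),
                      biotype = "protein_coding")
  genes$tss <- gene_tss(genes)
  genes
}

test_that("gene density equals a brute-force overlap count", {
  genes <- make_genome()
  anchors <- floor(runif(40) * 5e6)
  got <- gene_density(rep("chr1", 40), anchors, genes)
  want <- vapply(anchors, function(a) {
    ws <- max(0, a - 150000); we <- a + 150000
    sum(genes$start < we & genes$end > ws)
  }, numeric(1))
  expect_equal(as.numeric(got), want)
  expect_equal(gene_density(character(), numeric(), genes), integer())
  # binning caps at 10
  expect_equal(gene_density_bin(c(0, 3, 9, 10, 25)), c(0L, 3L, 9L, 10L, 10L))
})

test_that("matched controls copy length, context class and density bin exactly", {
  genes <- make_genome()
  sizes <- c(chr1 = 5e6)
  bundle <- list(genes = genes, chrom_sizes = sizes)
  set.seed(72)
  # reference: 6 intergenic + 2 intragenic synthetic loci
  inter <- numeric(0)
  while (length(inter) < 6) {
    cand <- floor(runif(50) * (5e6 - 100))
    ok <- !vapply(cand, function(s) any(genes$start < s + 100 &
                                          genes$end > s), logical(1))
    inter <- c(inter, cand[ok])[seq_len(min(6, length(inter) + sum(ok)))]
  }
  hosts <- genes[sample.int(nrow(genes), 2), ]
  ref <- gintervals("chr1", c(inter, hosts$start + 200),
                    c(inter + 60 + seq_len(6) * 5, hosts$start + 280),
                    strand = "+", id = sprintf("r%d", 1:8))
  ref$class_label <- c(rep("intergenic", 6), rep("intragenic", 2))

  ctl <- sample_matched_sets(ref, bundle, n_sets = 25, seed = 5)
  expect_equal(nrow(ctl), 25 * 8)
  ref_bin <- gene_density_bin(gene_density(ref$chrom, anchor_point(ref),
                                           genes))
  for (r in unique(ctl$replicate)) {
    cr <- ctl[ctl$replicate == r, ]
    # length multiset exact (per feature, in fact)
    expect_equal(cr$end - cr$start,
                 (ref$end - ref$start)[match(cr$ref_id, ref$id)])
    expect_equal(cr$class_label, ref$class_label[match(cr$ref_id, ref$id)])
    expect_equal(cr$density_bin, ref_bin[match(cr$ref_id, ref$id)])
  }
  # realized classes verified independently against the gene layout
  cls <- vapply(seq_len(nrow(ctl)), function(i) {
    ov <- genes$start < ctl$end[i] & genes$end > ctl$start[i]
    if (!any(ov)) "intergenic"
    else if (any(genes$start <= ctl$start[i] & genes$end >= ctl$end[i]))
      "intragenic" else "boundary"
  }, "")
  expect_equal(cls, ctl$class_label)
})

test_that("control sampling is reproducible from its seed", {
  genes <- make_genome()
  bundle <- list(genes = genes, chrom_sizes = c(chr1 = 5e6))
  ref <- gintervals("chr1", c(101000, 2050000), c(101080, 2050080),
                    strand = "+", id = c("a", "b"))
  ref$class_label <- vapply(seq_len(nrow(ref)), function(i) {
    ov <- genes$start < ref$end[i] & genes$end > ref$start[i]
    if (!any(ov)) "intergenic"
    else if (any(genes$start <= ref$start[i] & genes$end >= ref$end[i]))
      "intragenic" else "boundary"
  }, "")
  ref <- ref[ref$class_label != "boundary", , drop = FALSE]
  s1 <- sample_matched_sets(ref, bundle, n_sets = 4, seed = 9)
  s2 <- sample_matched_sets(ref, bundle, n_sets = 4, seed = 9)
  s3 <- sample_matched_sets(ref, bundle, n_sets = 4, seed = 10)
  expect_identical(s1, s2)
  expect_false(identical(s1$start, s3$start))
})

test_that("protein-coding controls are TSS anchors matched on density bin", {
  genes <- make_genome()
  bundle <- list(genes = genes, chrom_sizes = c(chr1 = 5e6))
  ref <- gintervals("chr1", c(101000, 2050000), c(101080, 2050080),
                    strand = "+", id = c("a", "b"))
  ref$class_label <- "intergenic"
  ctl <- sample_matched_sets(ref, bundle, n_sets = 10,
                             category = "protein_coding", seed = 3)
  expect_true(all(ctl$class_label == "protein_coding"))
  expect_true(all(ctl$anchor %in% genes$tss))
  ref_bin <- gene_density_bin(gene_density(ref$chrom, anchor_point(ref),
                                           genes))
  expect_equal(ctl$density_bin, ref_bin[match(ctl$ref_id, ref$id)])
})

test_that("an unsatisfiable stratum errors naming the feature", {
  # intragenic reference on a gene-free genome can never be matched
  bundle <- list(genes = gintervals(character(), numeric(), numeric(),
                                    strand = character(), id = character(),
                                    biotype = character(), tss = numeric()),
                 chrom_sizes = c(chr1 = 1e6))
  ref <- gintervals("chr1", 1000, 1080, strand = "+", id = "stuck")
  ref$class_label <- "intragenic"
  expect_error(sample_matched_sets(ref, bundle, n_sets = 1, seed = 1,
                                   max_attempts = 200),
               "stuck")
})

test_that("GRB overlap flags use the 300 kb window with 1 bp sensitivity", {
  sizes <- c(chr1 = 1e6)
  feats <- gintervals("chr1", c(500000, 500000), c(500100, 500100),
                      id = c("in", "out"))
  # window of both features: [350050, 650050)
  grbs <- gintervals("chr1", c(650049, 0), c(700000, 100))
  f1 <- flag_grb_overlaps(feats[1, ], grbs[1, , drop = FALSE], sizes)
  expect_true(f1)              # 1 bp overlap at the window edge
  f2 <- flag_grb_overlaps(feats[1, ], gintervals("chr1", 650050, 700000),
                          sizes)
  expect_false(f2)             # just outside
  expect_equal(flag_grb_overlaps(feats, gintervals(character(), numeric(),
                                                   numeric()), sizes),
               c(FALSE, FALSE))
})
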