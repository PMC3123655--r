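test_that("bundles are byte-identical under one seed and differ across seeds", {
  b1 <- generate_bundle(small_config(seed = 3))
  b2 <- generate_bundle(small_config(seed = 3))
  expect_identical(b1, b2)
  b3 <- generate_bundle(small_config(seed = 4))
  expect_false(identical(b1$hcnes[[1]], b3$hcnes[[1]]))
})

test_that("all generated intervals respect chromosome bounds and invariants", {
  b <- generate_bundle(small_config(seed = 5))
  expect_true(validate_bundle(b))
  expect_true(all(b$pre_mirnas$strand %in% c("+", "-")))
  expect_equal(nchar(b$pre_mirnas$sequence),
               b$pre_mirnas$end - b$pre_mirnas$start)
  expect_true(all(b$hcnes[[1]]$identity_pct >= 90 &
                    b$hcnes[[1]]$identity_pct <= 100))
  expect_true(all(nzchar(b$bivalent_domains$cell_type)))
  # transcripts contain their pre-miRNA
  tr <- b$transcript_models
  px <- b$pre_mirnas[match(tr$mirna_id, b$pre_mirnas$id), ]
  expect_true(all(tr$start <= px$start & tr$end >= px$end))
})

test_that("the ST count and planted composition follow the configured plan", {
  cfg <- small_config(seed = 6)
  b <- generate_bundle(cfg)
  h <- classify_mirnas(b$pre_mirnas, b$genes)
  # placement guarantees the planned classes
  expect_equal(sum(h$class_label == "intergenic"), cfg$n_intergenic)
  z <- classify_mirnas(b$zebrafish$pre_mirnas, b$zebrafish$genes)
  st <- define_st_mirnas(h, z, b$ortholog_map, b$pol3_ids)
  want_st <- cfg$n_intergenic - cfg$n_pol3 + cfg$n_intragenic_zf_intergenic
  expect_equal(nrow(st), want_st)
  planted <- b$truth$id[b$truth$planted]
  expect_equal(length(planted), cfg$n_planted_targets)
  expect_true(all(planted %in% st$id))
  # the miR-9-style case: intragenic in human, intergenic ortholog, planted
  mir9 <- b$truth$id[b$truth$planted & b$truth$class_plan == "intragenic"]
  expect_equal(length(mir9), 1)
  expect_equal(h$class_label[h$id == mir9], "intragenic")
  zid <- b$ortholog_map$other_id[b$ortholog_map$human_id == mir9 &
                                   b$ortholog_map$lineage == "human:zebrafish"]
  expect_equal(z$class_label[z$id == zid], "intergenic")
})

test_that("planted loci carry the configured HCNE density contrast", {
  cfg <- simulation_config(seed = 8)
  b <- generate_bundle(cfg)
  planted <- b$truth$id[b$truth$planted]
  px <- b$pre_mirnas[match(planted, b$pre_mirnas$id), ]
  d_planted <- densities_at_anchors(px$chrom, anchor_point(px),
                                    b$hcnes[[1]], b$chrom_sizes)
  # background measured at positions far from any planted locus
  set.seed(1)
  bg_pos <- floor(runif(300) * (cfg$chrom_length - 1))
  bg_chrom <- sample(names(b$chrom_sizes), 300, TRUE)
  near <- vapply(seq_along(bg_pos), function(i) {
    any(px$chrom == bg_chrom[i] &
          abs(anchor_point(px) - bg_pos[i]) < 3.5e5)
  }, logical(1))
  d_bg <- densities_at_anchors(bg_chrom[!near], bg_pos[!near], b$hcnes[[1]],
                               b$chrom_sizes)
  fold <- mean(d_planted) / mean(d_bg)
  expect_gt(fold, cfg$hcne_target_fold * 0.8)
  expect_lt(fold, cfg$hcne_target_fold * 1.2)
})

test_that("transcript TSS distances hit the configured within-50kb fraction", {
  # a larger genome so the binomial error on the fraction is small
  cfg <- simulation_config(n_chroms = 6, chrom_length = 30e6, n_genes = 1200,
                           n_mirnas = 600, n_intergenic = 510,
                           n_planted_targets = 20, n_pol3 = 4,
                           n_intragenic_zf_intergenic = 5,
                           transcript_fraction = 0.9, seed = 9)
  b <- generate_bundle(cfg)
  fr <- distance_fractions(b$transcript_models, b$pre_mirnas)
  n <- nrow(b$transcript_models)
  tol_tss <- 3 * sqrt(0.93 * 0.07 / n)
  tol_tes <- 3 * sqrt(0.90 * 0.10 / n)
  expect_lt(abs(fr[["tss_within"]] - 0.93), tol_tss)
  expect_lt(abs(fr[["tes_within"]] - 0.90), tol_tes)
})

test_that("fixture suites round-trip through the standard readers", {
  b <- generate_bundle(small_config(seed = 10))
  dir <- withr::local_tempdir()
  write_fixture_suite(b, dir)
  r <- read_fixture_suite(dir)
  expect_equal(r$chrom_sizes, b$chrom_sizes)
  key <- c("chrom", "start", "end", "strand", "id")
  expect_equal(r$pre_mirnas[, key], b$pre_mirnas[, key])
  expect_equal(chartr("T", "U", r$pre_mirnas$sequence),
               chartr("T", "U", b$pre_mirnas$sequence))
  expect_equal(r$genes[, c(key, "biotype", "tss")],
               b$genes[, c(key, "biotype", "tss")])
  expect_setequal(names(r$hcnes), names(b$hcnes))
  for (lin in names(b$hcnes)) {
    expect_equal(r$hcnes[[lin]][, c("chrom", "start", "end", "identity_pct")],
                 b$hcnes[[lin]][, c("chrom", "start", "end", "identity_pct")])
  }
  expect_equal(r$bivalent_domains[, c("chrom", "start", "end", "cell_type")],
               b$bivalent_domains[, c("chrom", "start", "end", "cell_type")])
  expect_equal(r$cgis[, c("chrom", "start", "end")],
               b$cgis[, c("chrom", "start", "end")])
  expect_equal(r$ortholog_map, b$ortholog_map)
  expect_equal(sort(r$pol3_ids), sort(b$pol3_ids))
  expect_equal(r$transcript_models[, c("mirna_id", "chrom", "start", "end")],
               b$transcript_models[, c("mirna_id", "chrom", "start", "end")])
  expect_equal(r$zebrafish$pre_mirnas[, key], b$zebrafish$pre_mirnas[, key])
})

test_that("empty tracks write and read back as valid empty files", {
  cfg <- small_config(seed = 11, p300_background_rate = 0,
                      p300_target_fold = 1, n_grbs = 0)
  b <- generate_bundle(cfg)
  expect_equal(nrow(b$peaks), 0)
  expect_equal(nrow(b$grbs), 0)
  dir <- withr::local_tempdir()
  write_fixture_suite(b, dir)
  r <- read_fixture_suite(dir)
  expect_equal(nrow(r$peaks), 0)
  expect_equal(nrow(r$grbs), 0)
})
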