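# Synthetic annotation bundles with planted GRB-target structure.
#
# The generator emulates the statistical structure the analysis relies on:
# a background Poisson field of HCNEs/p300 peaks multiplied by a fold factor
# around planted target loci, bivalent domains co-occurring with planted
# promoters, primary-transcript TSS/TES distances calibrated to stated
# within-cutoff fractions, and a small "zebrafish" genome so the
# self-transcribed definition (intragenic human miRNA, intergenic zebrafish
# ortholog) is exercised end to end. One global seed drives independent
# per-track substreams, so adding a track never perturbs the others.

#' Simulation configuration
#'
#' Defaults are the study conditions of the planted-target validation:
#' 4 x 30 Mb chromosomes, 900 protein-coding genes, 140 miRNAs arranged so
#' that exactly 120 qualify as self-transcribed (119 intergenic − 4 Pol III
#' + 5 intragenic loci with an intergenic zebrafish ortholog, one of which
#' is the planted miR-9-style case), 20 planted targets, a 5-fold HCNE
#' density contrast within ±150 kb of planted loci, bivalent-domain
#' sensitivity 0.8 at planted promoters vs background rate 0.1 elsewhere,
#' and 93% / 90% of transcript TSSs / TESs within 50 kb / 20 kb.
#'
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Protein-coding gene count (placed without overlap).
#' @param gene_length_range Gene length range, bp.
#' @param n_mirnas Total miRNA count.
#' @param n_intergenic Number of intergenic miRNAs.
#' @param n_planted_targets Planted GRB-target loci (one of them the
#'   intragenic miR-9-style case, the rest intergenic).
#' @param n_pol3 Intergenic (non-planted) loci marked Pol III-transcribed.
#' @param n_intragenic_zf_intergenic Intragenic human loci whose zebrafish
#'   ortholog is intergenic (counted into the ST set).
#' @param pre_length_range Pre-miRNA length range, bp.
#' @param mature_length Mature miRNA length, nt.
#' @param hcne_lineages Lineage labels, one HCNE track each.
#' @param hcne_background_rate HCNE background intensity, elements per Mb.
#' @param hcne_target_fold Density fold around planted loci (>= 1).
#' @param hcne_length_range,hcne_identity_range HCNE length (bp) and percent
#'   identity ranges.
#' @param hcne_target_halfwidth Half-width of the boosted region, bp.
#' @param p300_background_rate,p300_target_fold,p300_length_range p300 peak
#'   track analogues.
#' @param bivalent_cell_types Cell-type labels for bivalent domains.
#' @param bivalent_sensitivity Probability a planted promoter carries a
#'   bivalent domain.
#' @param bivalent_background_rate Probability a non-planted promoter does.
#' @param bivalent_length_range Domain length range, bp.
#' @param n_random_bivalent Additional domains placed anywhere.
#' @param cgi_background_rate CGI background intensity per Mb.
#' @param cgi_length_range CGI length range, bp.
#' @param cgi_target_count_range CGIs planted inside each target window.
#' @param transcript_fraction Fraction of miRNAs with a primary-transcript
#'   model.
#' @param tss_within_50kb_fraction,tes_within_20kb_fraction Calibrated
#'   fractions of TSS/TES distances within the 50 kb / 20 kb cutoffs.
#' @param n_grbs,grb_length_range Synteny-block track shape.
#' @param mouse_ortholog_rate Probability a human miRNA has a mouse ortholog
#'   (planted loci always do).
#' @param zf_intergenic_ortholog_rate Probability an intergenic human miRNA
#'   has a zebrafish ortholog.
#' @param substitution_rate,indel_rate Per-base mutation rates used to derive
#'   ortholog sequences from the human ones.
#' @param min_mirna_spacing Minimum distance between placed miRNA loci, bp.
#'   The default keeps 50 kb promoter windows of distinct loci disjoint, so
#'   the realized bivalent background rate equals the configured one.
#' @param seed Global seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_chroms = 4, chrom_length = 30e6,
    n_genes = 900, gene_length_range = c(2000, 50000),
    n_mirnas = 140, n_intergenic = 119, n_planted_targets = 20,
    n_pol3 = 4, n_intragenic_zf_intergenic = 5,
    pre_length_range = c(60, 110), mature_length = 22,
    hcne_lineages = c("human:mouse", "human:zebrafish"),
    hcne_background_rate = 15, hcne_target_fold = 5,
    hcne_length_range = c(50, 300), hcne_identity_range = c(90, 100),
    hcne_target_halfwidth = 150000,
    p300_background_rate = 8, p300_target_fold = 5,
    p300_length_range = c(200, 1500),
    bivalent_cell_types = c("hES", "mES"),
    bivalent_sensitivity = 0.8, bivalent_background_rate = 0.1,
    bivalent_length_range = c(1000, 5000), n_random_bivalent = 50,
    cgi_background_rate = 3, cgi_length_range = c(300, 2000),
    cgi_target_count_range = c(1, 3),
    transcript_fraction = 0.45,
    tss_within_50kb_fraction = 0.93, tes_within_20kb_fraction = 0.90,
    n_grbs = 5, grb_length_range = c(5e5, 2e6),
    mouse_ortholog_rate = 0.95, zf_intergenic_ortholog_rate = 0.6,
    substitution_rate = 0.08, indel_rate = 0.02,
    min_mirna_spacing = 60000,
    seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_intergenic <= cfg$n_mirnas,
    cfg$n_planted_targets <= cfg$n_mirnas,
    cfg$n_pol3 + cfg$n_planted_targets - 1 <= cfg$n_intergenic,
    cfg$n_intragenic_zf_intergenic <= cfg$n_mirnas - cfg$n_intergenic,
    cfg$hcne_target_fold >= 1, cfg$p300_target_fold >= 1,
    cfg$bivalent_sensitivity >= 0 && cfg$bivalent_sensitivity <= 1,
    cfg$bivalent_background_rate >= 0 && cfg$bivalent_background_rate <= 1,
    cfg$tss_within_50kb_fraction > 0 && cfg$tss_within_50kb_fraction < 1,
    cfg$tes_within_20kb_fraction > 0 && cfg$tes_within_20kb_fraction < 1)
  structure(cfg, class = "simulation_config")
}

#' @keywords internal
rand_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  vapply(n, function(len) paste(sample(alphabet, len, replace = TRUE),
                                collapse = ""), "")
}

#' @keywords internal
mutate_seq <- function(seq, substitution_rate, indel_rate,
                       protect = integer()) {
  b <- strsplit(seq, "")[[1]]
  alphabet <- c("A", "C", "G", "U")
  out <- character(0)
  for (i in seq_along(b)) {
    if (i %in% protect) { out <- c(out, b[i]); next }
    r <- stats::runif(1)
    if (r < indel_rate / 2) next                       # deletion
    base <- if (r < indel_rate / 2 + substitution_rate) {
      sample(setdiff(alphabet, b[i]), 1)
    } else b[i]
    out <- c(out, base)
    if (r > 1 - indel_rate / 2) out <- c(out, sample(alphabet, 1))  # insertion
  }
  paste(out, collapse = "")
}

#' @keywords internal
place_nonoverlapping <- function(n, sizes, len_range, max_rounds = 60) {
  chroms <- names(sizes)
  per <- table(sample(rep(chroms, length.out = n)))
  out <- list()
  for (ch in chroms) {
    need <- if (ch %in% names(per)) per[[ch]] else 0
    if (need == 0) next
    placed <- data.frame(start = numeric(), end = numeric())
    rounds <- 0
    while (nrow(placed) < need) {
      rounds <- rounds + 1
      if (rounds > max_rounds) {
        stop("infeasible placement: genome too small for requested features",
             call. = FALSE)
      }
      k <- 2 * (need - nrow(placed)) + 5
      lens <- floor(stats::runif(k, len_range[1], len_range[2] + 1))
      starts <- floor(stats::runif(k) * (sizes[[ch]] - lens))
      cand <- rbind(placed, data.frame(start = starts, end = starts + lens))
      cand <- cand[order(cand$start, cand$end), , drop = FALSE]
      keep <- rep(TRUE, nrow(cand))
      last_end <- -1
      for (i in seq_len(nrow(cand))) {
        if (cand$start[i] >= last_end) last_end <- cand$end[i]
        else keep[i] <- FALSE
      }
      placed <- cand[keep, , drop = FALSE]
      if (nrow(placed) > need) placed <- placed[seq_len(need), , drop = FALSE]
    }
    out[[ch]] <- data.frame(chrom = ch, placed, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @keywords internal
poisson_track <- function(rate_per_mb, sizes, len_range) {
  out <- lapply(names(sizes), function(ch) {
    n <- stats::rpois(1, rate_per_mb * sizes[[ch]] / 1e6)
    if (n == 0) return(NULL)
    lens <- floor(stats::runif(n, len_range[1], len_range[2] + 1))
    starts <- floor(stats::runif(n) * (sizes[[ch]] - lens))
    data.frame(chrom = ch, start = starts, end = starts + lens,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic annotation bundle
#'
#' See [simulation_config()] for the knobs. Returns an `annotation_bundle`
#' carrying every input track of the analysis plus generator truth labels.
#' Reproducible: the same config (same seed) gives byte-identical bundles.
#'
#' @param config A `simulation_config`.
#' @return An `annotation_bundle` list: chrom_sizes, genes, pre_mirnas,
#'   mature_mirnas, hcnes (list per lineage), peaks, bivalent_domains, cgis,
#'   grbs, transcript_models, ortholog_map, pol3_ids, zebrafish (sub-bundle),
#'   truth (id, planted, role), config.
#' @export
generate_bundle <- function(config = simulation_config()) {
  cfg <- config
  sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                           paste0("chr", seq_len(cfg$n_chroms)))

  genes <- with_rng_seed(substream_seed(cfg$seed, 1), {
    g <- place_nonoverlapping(cfg$n_genes, sizes, cfg$gene_length_range)
    g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
    g$id <- sprintf("gene%04d", seq_len(nrow(g)))
    g$biotype <- "protein_coding"
    g$tss <- gene_tss(g)
    g
  })

  mir <- with_rng_seed(substream_seed(cfg$seed, 2), {
    place_mirnas(cfg, sizes, genes)
  })
  pre <- mir$pre
  truth <- mir$truth

  seqs <- with_rng_seed(substream_seed(cfg$seed, 3), {
    pre_seq <- rand_seq(pre$end - pre$start)
    mat_off <- pmax(1, floor(stats::runif(nrow(pre)) *
                               (pre$end - pre$start - cfg$mature_length)))
    mat_seq <- substr(pre_seq, mat_off, mat_off + cfg$mature_length - 1)
    list(pre = pre_seq, mature = mat_seq)
  })
  pre$sequence <- seqs$pre
  mature <- data.frame(id = paste0(pre$id, "-mat"), mirna_id = pre$id,
                       sequence = seqs$mature, stringsAsFactors = FALSE)

  planted <- truth$id[truth$planted]
  planted_mid <- anchor_point(pre[match(planted, pre$id), , drop = FALSE])
  planted_chrom <- pre$chrom[match(planted, pre$id)]

  hcnes <- stats::setNames(lapply(seq_along(cfg$hcne_lineages), function(li) {
    with_rng_seed(substream_seed(cfg$seed, 10 + li), {
      bg <- poisson_track(cfg$hcne_background_rate, sizes,
                          cfg$hcne_length_range)
      extra <- boosted_track(cfg$hcne_background_rate,
                             cfg$hcne_target_fold, cfg$hcne_target_halfwidth,
                             planted_chrom, planted_mid, sizes,
                             cfg$hcne_length_range)
      tr <- rbind(bg, extra)
      tr$identity_pct <- round(stats::runif(nrow(tr),
                                            cfg$hcne_identity_range[1],
                                            cfg$hcne_identity_range[2]), 1)
      tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
      rownames(tr) <- NULL
      tr
    })
  }), cfg$hcne_lineages)

  peaks <- with_rng_seed(substream_seed(cfg$seed, 20), {
    bg <- poisson_track(cfg$p300_background_rate, sizes, cfg$p300_length_range)
    extra <- boosted_track(cfg$p300_background_rate, cfg$p300_target_fold,
                           cfg$hcne_target_halfwidth, planted_chrom,
                           planted_mid, sizes, cfg$p300_length_range)
    tr <- rbind(bg, extra)
    tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
    rownames(tr) <- NULL
    tr
  })

  bivalent <- with_rng_seed(substream_seed(cfg$seed, 30), {
    place_bivalent(cfg, sizes, pre, truth)
  })

  cgis <- with_rng_seed(substream_seed(cfg$seed, 40), {
    bg <- poisson_track(cfg$cgi_background_rate, sizes, cfg$cgi_length_range)
    planted_rows <- lapply(seq_along(planted), function(i) {
      k <- sample(seq(cfg$cgi_target_count_range[1],
                      cfg$cgi_target_count_range[2]), 1)
      lens <- floor(stats::runif(k, cfg$cgi_length_range[1],
                                 cfg$cgi_length_range[2] + 1))
      lo <- max(0, planted_mid[i] - 20000)
      hi <- min(sizes[[planted_chrom[i]]], planted_mid[i] + 10000)
      starts <- floor(stats::runif(k, lo, pmax(lo + 1, hi - lens)))
      data.frame(chrom = planted_chrom[i], start = starts, end = starts + lens,
                 stringsAsFactors = FALSE)
    })
    tr <- rbind(bg, do.call(rbind, planted_rows))
    tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
    rownames(tr) <- NULL
    tr
  })

  transcripts <- with_rng_seed(substream_seed(cfg$seed, 50), {
    n_tr <- round(cfg$transcript_fraction * nrow(pre))
    ids <- sort(sample(pre$id, n_tr))
    px <- pre[match(ids, pre$id), , drop = FALSE]
    rate_up <- -log(1 - cfg$tss_within_50kb_fraction) / 50000
    rate_down <- -log(1 - cfg$tes_within_20kb_fraction) / 20000
    up <- floor(stats::rexp(n_tr, rate_up))
    down <- floor(stats::rexp(n_tr, rate_down))
    plus <- px$strand == "+"
    st <- ifelse(plus, px$start - up, px$start - down)
    en <- ifelse(plus, px$end + down, px$end + up)
    data.frame(mirna_id = ids, chrom = px$chrom,
               start = pmax(0, st), end = pmin(unname(sizes[px$chrom]), en),
               strand = px$strand, source = "synthetic",
               stringsAsFactors = FALSE)
  })

  grbs <- with_rng_seed(substream_seed(cfg$seed, 60), {
    poisson_track(cfg$n_grbs / (sum(sizes) / 1e6), sizes, cfg$grb_length_range)
  })

  zf <- with_rng_seed(substream_seed(cfg$seed, 70), {
    make_zebrafish(cfg, pre, mature, truth)
  })

  bundle <- structure(list(
    chrom_sizes = sizes, genes = genes, pre_mirnas = pre,
    mature_mirnas = mature, hcnes = hcnes, peaks = peaks,
    bivalent_domains = bivalent, cgis = cgis, grbs = grbs,
    transcript_models = transcripts, ortholog_map = zf$ortholog_map,
    pol3_ids = truth$id[truth$pol3], zebrafish = zf$bundle, truth = truth,
    config = cfg), class = "annotation_bundle")
  validate_bundle(bundle)
  bundle
}

#' @keywords internal
boosted_track <- function(rate_per_mb, fold, halfwidth, chroms, mids, sizes,
                          len_range) {
  if (fold <= 1 || length(mids) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(mids), function(i) {
    lo <- max(0, mids[i] - halfwidth)
    hi <- min(sizes[[chroms[i]]], mids[i] + halfwidth)
    n <- stats::rpois(1, rate_per_mb * (fold - 1) * (hi - lo) / 1e6)
    if (n == 0) return(NULL)
    lens <- floor(stats::runif(n, len_range[1], len_range[2] + 1))
    starts <- floor(stats::runif(n, lo, pmax(lo + 1, hi - lens)))
    data.frame(chrom = chroms[i], start = starts, end = starts + lens,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), stringsAsFactors = FALSE)
  out
}

#' @keywords internal
place_mirnas <- function(cfg, sizes, genes) {
  n_intra <- cfg$n_mirnas - cfg$n_intergenic
  n_planted_inter <- cfg$n_planted_targets - 1   # one planted locus is the
                                                 # intragenic miR-9-style case
  gene_by_chrom <- split(genes[, c("start", "end")], genes$chrom)
  chrom_names <- names(sizes)
  chrom_prob <- sizes / sum(sizes)
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  draw_intergenic <- function(len, upstream_clear = 0) {
    for (attempt in seq_len(5000)) {
      ch <- sample(chrom_names, 1, prob = chrom_prob)
      st <- floor(stats::runif(1, upstream_clear + 1000,
                               sizes[[ch]] - len - 1000))
      # clearance region: the pre-miRNA itself plus any required gene-free
      # upstream zone (strand assigned later for planted: use both sides)
      g <- gene_by_chrom[[ch]]
      if (!is.null(g) && any(g$start < st + len + upstream_clear &
                               g$end > st - upstream_clear)) next
      if (nrow(placed)) {
        near <- placed$chrom == ch &
          placed$start < st + len + cfg$min_mirna_spacing &
          placed$end > st - cfg$min_mirna_spacing
        if (any(near)) next
      }
      return(c(ch = ch, st = st))
    }
    stop("infeasible placement: could not place intergenic miRNA",
         call. = FALSE)
  }
  rows <- vector("list", cfg$n_mirnas)
  lens <- floor(stats::runif(cfg$n_mirnas, cfg$pre_length_range[1],
                             cfg$pre_length_range[2] + 1))
  strands <- sample(c("+", "-"), cfg$n_mirnas, replace = TRUE)
  planted_flag <- rep(FALSE, cfg$n_mirnas)
  class_plan <- rep("intergenic", cfg$n_mirnas)
  # order: planted intergenic, other intergenic, miR-9-style, other intragenic
  for (i in seq_len(cfg$n_intergenic)) {
    clear <- if (i <= n_planted_inter) 8000 else 0
    hit <- draw_intergenic(lens[i], upstream_clear = clear)
    rows[[i]] <- data.frame(chrom = hit[["ch"]],
                            start = as.numeric(hit[["st"]]),
                            end = as.numeric(hit[["st"]]) + lens[i],
                            stringsAsFactors = FALSE)
    placed <- rbind(placed, rows[[i]])
    if (i <= n_planted_inter) planted_flag[i] <- TRUE
  }
  # intragenic loci: inside a gene body, away from other miRNAs
  host_pool <- genes[genes$end - genes$start > 3 * max(cfg$pre_length_range), ]
  hosts <- host_pool[sample.int(nrow(host_pool), n_intra), , drop = FALSE]
  for (j in seq_len(n_intra)) {
    i <- cfg$n_intergenic + j
    g <- hosts[j, ]
    st <- floor(stats::runif(1, g$start + 100, g$end - lens[i] - 100))
    rows[[i]] <- data.frame(chrom = g$chrom, start = st, end = st + lens[i],
                            stringsAsFactors = FALSE)
    class_plan[i] <- "intragenic"
    strands[i] <- g$strand   # co-transcribed orientation
    if (j == 1) planted_flag[i] <- TRUE   # the miR-9-style case
  }
  pre <- do.call(rbind, rows)
  pre$strand <- strands
  pre$id <- sprintf("hsa-mir-%03d", seq_len(cfg$n_mirnas))
  pre <- pre[, c("chrom", "start", "end", "strand", "id")]
  # Pol III loci: intergenic, never planted
  pol3_pool <- which(class_plan == "intergenic" & !planted_flag)
  pol3 <- rep(FALSE, cfg$n_mirnas)
  pol3[sample(pol3_pool, cfg$n_pol3)] <- TRUE
  # zebrafish context plan: which intragenic loci are zebrafish-intergenic
  zf_inter <- rep(NA, cfg$n_mirnas)
  intra_idx <- which(class_plan == "intragenic")
  mir9_idx <- intra_idx[1]
  others <- sample(setdiff(intra_idx, mir9_idx),
                   cfg$n_intragenic_zf_intergenic - 1)
  zf_inter[c(mir9_idx, others)] <- TRUE
  zf_inter[setdiff(intra_idx, c(mir9_idx, others))] <- FALSE
  truth <- data.frame(id = pre$id, planted = planted_flag, pol3 = pol3,
                      class_plan = class_plan, zf_intergenic = zf_inter,
                      stringsAsFactors = FALSE)
  list(pre = pre, truth = truth)
}

#' @keywords internal
place_bivalent <- function(cfg, sizes, pre, truth) {
  cts <- cfg$bivalent_cell_types
  rows <- list()
  five_prime_up <- function(p, off_lo, off_hi) {
    # an interval within [off_lo, off_hi] bp upstream of the 5' end
    len <- floor(stats::runif(1, cfg$bivalent_length_range[1],
                              cfg$bivalent_length_range[2] + 1))
    off <- floor(stats::runif(1, off_lo, off_hi))
    if (p$strand == "+") c(max(0, p$start - off - len), max(1, p$start - off))
    else c(min(sizes[[p$chrom]] - 1, p$end + off),
           min(sizes[[p$chrom]], p$end + off + len))
  }
  mir9 <- truth$planted & truth$class_plan == "intragenic"
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, ]
    if (mir9[i]) {
      # the miR-9-style worked case always carries domains in every cell type
      for (ct in cts) {
        iv <- five_prime_up(p, 0, 4000)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = p$chrom, start = iv[1], end = iv[2], cell_type = ct,
          stringsAsFactors = FALSE)
      }
    } else if (truth$planted[i]) {
      if (stats::runif(1) < cfg$bivalent_sensitivity) {
        n_ct <- sample(seq_along(cts), 1)
        for (ct in sample(cts, n_ct)) {
          iv <- five_prime_up(p, 0, 4000)
          rows[[length(rows) + 1]] <- data.frame(
            chrom = p$chrom, start = iv[1], end = iv[2], cell_type = ct,
            stringsAsFactors = FALSE)
        }
      }
    } else if (stats::runif(1) < cfg$bivalent_background_rate) {
      iv <- five_prime_up(p, 0, 4000)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = p$chrom, start = iv[1], end = iv[2],
        cell_type = sample(cts, 1), stringsAsFactors = FALSE)
    }
  }
  # unrelated domains scattered over the genome, kept clear of miRNA promoter
  # zones so the realized promoter-association rate stays at the configured
  # background rate
  bg <- poisson_track(cfg$n_random_bivalent / (sum(sizes) / 1e6), sizes,
                      cfg$bivalent_length_range)
  if (nrow(bg)) {
    zone_s <- ifelse(pre$strand == "+", pre$start - 51000, pre$start)
    zone_e <- ifelse(pre$strand == "+", pre$end, pre$end + 51000)
    clear <- vapply(seq_len(nrow(bg)), function(i) {
      !any(pre$chrom == bg$chrom[i] & zone_s < bg$end[i] & zone_e > bg$start[i])
    }, logical(1))
    bg <- bg[clear, , drop = FALSE]
    if (nrow(bg)) bg$cell_type <- sample(cts, nrow(bg), replace = TRUE)
  }
  out <- rbind(do.call(rbind, rows), bg)
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric(),
                                      cell_type = character(),
                                      stringsAsFactors = FALSE)
  out <- out[out$end > out$start, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
make_zebrafish <- function(cfg, pre, mature, truth) {
  z_sizes <- c(zchr1 = 15e6)
  z_genes <- place_nonoverlapping(100, z_sizes, cfg$gene_length_range)
  z_genes$strand <- sample(c("+", "-"), nrow(z_genes), replace = TRUE)
  z_genes$id <- sprintf("zgene%03d", seq_len(nrow(z_genes)))
  z_genes$biotype <- "protein_coding"
  z_genes$tss <- gene_tss(z_genes)
  # which human loci get a zebrafish ortholog
  has_zf <- ifelse(truth$class_plan == "intergenic",
                   stats::runif(nrow(pre)) < cfg$zf_intergenic_ortholog_rate,
                   !is.na(truth$zf_intergenic))
  zf_rows <- list(); map_rows <- list(); z_pre_seq <- character()
  z_mat_seq <- character()
  gs <- z_genes$start; ge <- z_genes$end
  for (i in which(has_zf)) {
    zid <- sub("hsa", "dre", pre$id[i])
    len <- pre$end[i] - pre$start[i]
    want_intergenic <- if (truth$class_plan[i] == "intragenic")
      isTRUE(truth$zf_intergenic[i]) else TRUE
    st <- NA
    for (att in seq_len(2000)) {
      cand <- floor(stats::runif(1, 1000, z_sizes[[1]] - len - 1000))
      touches <- any(gs < cand + len & ge > cand)
      inside <- any(gs <= cand & ge >= cand + len)
      if (want_intergenic && !touches) { st <- cand; break }
      if (!want_intergenic && inside) { st <- cand; break }
    }
    if (is.na(st)) stop("infeasible placement: zebrafish ortholog",
                        call. = FALSE)
    zf_rows[[length(zf_rows) + 1]] <- data.frame(
      chrom = "zchr1", start = st, end = st + len,
      strand = sample(c("+", "-"), 1), id = zid, stringsAsFactors = FALSE)
    map_rows[[length(map_rows) + 1]] <- data.frame(
      human_id = pre$id[i], other_id = zid, lineage = "human:zebrafish",
      stringsAsFactors = FALSE)
    z_pre_seq <- c(z_pre_seq, mutate_seq(pre$sequence[i],
                                         cfg$substitution_rate,
                                         cfg$indel_rate))
    mseq <- mature$sequence[mature$mirna_id == pre$id[i]][1]
    z_mat_seq <- c(z_mat_seq, mutate_seq(mseq, cfg$substitution_rate / 2, 0,
                                         protect = 1:8))
  }
  z_pre <- do.call(rbind, zf_rows)
  z_pre$sequence <- z_pre_seq
  z_mature <- data.frame(id = paste0(z_pre$id, "-mat"), mirna_id = z_pre$id,
                         sequence = z_mat_seq, stringsAsFactors = FALSE)
  # mouse orthologs: map entries only (no mouse genome is materialized)
  has_mouse <- stats::runif(nrow(pre)) < cfg$mouse_ortholog_rate
  has_mouse[truth$planted] <- TRUE
  mouse_map <- data.frame(human_id = pre$id[has_mouse],
                          other_id = sub("hsa", "mmu", pre$id[has_mouse]),
                          lineage = "human:mouse", stringsAsFactors = FALSE)
  map <- rbind(do.call(rbind, map_rows), mouse_map)
  list(bundle = list(chrom_sizes = z_sizes, genes = z_genes,
                     pre_mirnas = z_pre, mature_mirnas = z_mature),
       ortholog_map = map)
}

#' Validate all bundle intervals against chromosome bounds
#' @param bundle An `annotation_bundle`.
#' @return Invisibly TRUE; errors on violation.
#' @export
validate_bundle <- function(bundle) {
  sz <- bundle$chrom_sizes
  check_bounds(bundle$genes, sz, "genes")
  check_bounds(bundle$pre_mirnas, sz, "pre_mirnas")
  for (lin in names(bundle$hcnes)) check_bounds(bundle$hcnes[[lin]], sz,
                                                paste0("hcnes:", lin))
  check_bounds(bundle$peaks, sz, "peaks")
  check_bounds(bundle$bivalent_domains, sz, "bivalent_domains")
  check_bounds(bundle$cgis, sz, "cgis")
  check_bounds(bundle$grbs, sz, "grbs")
  check_bounds(bundle$transcript_models, sz, "transcript_models")
  if (!is.null(bundle$zebrafish)) {
    check_bounds(bundle$zebrafish$genes, bundle$zebrafish$chrom_sizes,
                 "zebrafish genes")
    check_bounds(bundle$zebrafish$pre_mirnas, bundle$zebrafish$chrom_sizes,
                 "zebrafish pre_mirnas")
  }
  invisible(TRUE)
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf(
    "<annotation_bundle> %d chroms (%.0f Mb), %d genes, %d miRNAs, %s HCNE tracks\n",
    length(x$chrom_sizes), sum(x$chrom_sizes) / 1e6, nrow(x$genes),
    nrow(x$pre_mirnas), length(x$hcnes)))
  invisible(x)
}
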