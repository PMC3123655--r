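# End-to-end orchestration: from an annotation bundle to the predicted
# GRB-target miRNA table. Every stage is a package function; this wires them
# together, optionally writing the per-stage TSV outputs and a JSON run
# manifest. The analysis/ scripts are thin narrative drivers over this.

#' Run the full GRB-target miRNA analysis on a bundle
#'
#' Stages: classify miRNAs (human and zebrafish), derive the self-transcribed
#' (ST) set, cluster it, compute per-lineage HCNE densities at cluster
#' representatives, draw matched random control sets and test enrichment with
#' the bootstrapped KS test, median-split loci into enriched/poor per
#' lineage, associate bivalent domains with promoter windows, count CGIs in
#' the full windows, flag GRB overlaps, and combine everything into the final
#' prediction table. When the bundle carries generator truth labels the
#' result includes precision/recall against the planted targets.
#'
#' @param bundle An `annotation_bundle` ([generate_bundle()] or
#'   [read_fixture_suite()]).
#' @param n_control_sets Matched control replicates per lineage.
#' @param nboot Bootstrap replicates for the KS test.
#' @param seed Integer seed driving control sampling and the bootstrap.
#' @param min_lineages Enrichment quorum for prediction (default 1).
#' @param window_size Density window, bp.
#' @param outdir Optional directory for TSV outputs + manifest.json.
#' @return List: st_mirnas, clusters, densities (long data frame),
#'   enrichment (per-lineage KS results), splits, bivalent_flags,
#'   contingency (Fisher analysis on intergenic loci, first lineage),
#'   predictions, performance (if truth available), manifest.
#' @export
run_pipeline <- function(bundle, n_control_sets = 100, nboot = 1000,
                         seed = 1, min_lineages = 1, window_size = 300000,
                         outdir = NULL) {
  genes <- bundle$genes
  sizes <- bundle$chrom_sizes

  human <- classify_mirnas(bundle$pre_mirnas, genes)
  zebrafish <- if (!is.null(bundle$zebrafish)) {
    classify_mirnas(bundle$zebrafish$pre_mirnas, bundle$zebrafish$genes)
  }
  st <- define_st_mirnas(human, zebrafish, bundle$ortholog_map,
                         pol3_exclusions = bundle$pol3_ids)
  clusters <- cluster_st_mirnas(st)
  loci <- cluster_representatives(clusters, st)

  lineages <- names(bundle$hcnes)
  anchors <- anchor_point(loci)
  conserved_in <- function(lin) {
    hsa <- unlist(lapply(strsplit(loci$conserved_lineages, ","), function(x)
      lin %in% x))
    loci$id[hsa]
  }

  densities <- list()
  enrichment <- list()
  splits <- list()
  for (k in seq_along(lineages)) {
    lin <- lineages[k]
    ids <- conserved_in(lin)
    ix <- match(ids, loci$id)
    obs <- densities_at_anchors(loci$chrom[ix], anchors[ix],
                                bundle$hcnes[[lin]], sizes, window_size)
    names(obs) <- ids
    ref <- loci[ix, , drop = FALSE]
    controls <- sample_matched_sets(ref, bundle, n_sets = n_control_sets,
                                    category = "non_coding",
                                    seed = substream_seed(seed, 100 + k))
    ctrl_dens <- densities_at_anchors(controls$chrom, controls$anchor,
                                      bundle$hcnes[[lin]], sizes, window_size)
    ks <- ks_boot_pvalue(obs, ctrl_dens, nboot = nboot,
                         seed = substream_seed(seed, 200 + k))
    densities[[lin]] <- data.frame(lineage = lin, locus_id = ids,
                                   density = unname(obs),
                                   stringsAsFactors = FALSE)
    enrichment[[lin]] <- ks
    splits[[lin]] <- median_split(obs, score_name = paste0("hcne:", lin))
  }
  densities <- do.call(rbind, densities)
  rownames(densities) <- NULL

  promoter_windows <- build_search_windows(loci, "promoter", genes, sizes)
  full_windows <- build_search_windows(loci, "full", genes, sizes)
  biv_all <- lapply(stats::setNames(loci$id, loci$id), function(i) {
    bivalent_association(promoter_windows[[i]], bundle$bivalent_domains,
                         intergenic = loci$class_label[match(i, loci$id)] ==
                           "intergenic",
                         intragenic_na = FALSE)
  })
  # intergenic-only flags for the contingency (Fisher) analysis
  biv_fisher <- vapply(loci$id, function(i) {
    f <- bivalent_association(promoter_windows[[i]], bundle$bivalent_domains,
                              intergenic = loci$class_label[match(i, loci$id)] ==
                                "intergenic",
                              intragenic_na = TRUE)
    if (all(is.na(f))) NA else any(f)
  }, logical(1))
  contingency <- bivalent_contingency(biv_fisher, splits[[1]])

  cgi_counts <- vapply(loci$id, function(i)
    cgi_count_in_window(full_windows[[i]], bundle$cgis), integer(1))
  grb_flags <- stats::setNames(
    flag_grb_overlaps(loci, bundle$grbs, sizes, window_size), loci$id)

  predictions <- predict_targets(loci, splits, biv_all,
                                 cgi_counts = cgi_counts,
                                 grb_flags = grb_flags,
                                 min_lineages = min_lineages)
  performance <- if (!is.null(bundle$truth)) {
    prediction_performance(predictions, clusters,
                           bundle$truth$id[bundle$truth$planted])
  }

  manifest <- list(
    n_st_mirnas = nrow(st), n_clusters = nrow(clusters),
    lineages = lineages, n_control_sets = n_control_sets, nboot = nboot,
    seed = seed, min_lineages = min_lineages, window_size = window_size,
    ks = lapply(enrichment, function(e)
      list(D = e$D, p_boot = e$p_boot, nboot = e$nboot, seed = e$seed)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  res <- list(st_mirnas = st, clusters = clusters, loci = loci,
              densities = densities, enrichment = enrichment,
              splits = splits, bivalent_flags = biv_all,
              contingency = contingency, predictions = predictions,
              performance = performance, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' @keywords internal
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(res$st_mirnas[, setdiff(names(res$st_mirnas), "sequence")],
                 file.path(outdir, "st_mirnas.tsv"))
  write_tsv_file(res$clusters, file.path(outdir, "clusters.tsv"))
  write_tsv_file(res$densities, file.path(outdir, "densities.tsv"))
  enr <- do.call(rbind, lapply(names(res$enrichment), function(lin) {
    e <- res$enrichment[[lin]]
    data.frame(lineage = lin, n_obs = e$n_x, n_control = e$n_y, D = e$D,
               p_boot = e$p_boot, nboot = e$nboot, seed = e$seed,
               stringsAsFactors = FALSE)
  }))
  write_tsv_file(enr, file.path(outdir, "enrichment.tsv"))
  write_tsv_file(res$predictions, file.path(outdir, "predictions.tsv"))
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
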