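# Final prediction of GRB-target miRNA loci.

#' Predict GRB-target miRNA loci
#'
#' A locus is predicted as a GRB target iff it is HCNE-enriched (top half of
#' the density split) in at least `min_lineages` lineage comparisons AND its
#' promoter is associated with a bivalent domain in at least one
#' developmental cell type. CGI counts and GRB-overlap flags are carried
#' along as annotation but are never used as prediction criteria. A locus
#' missing from a lineage split is treated as not enriched in that lineage.
#'
#' @param loci Locus table (cluster representatives) with `id` and
#'   `class_label` (and optional `host_gene`).
#' @param splits Named list of `split_result`s, one per lineage.
#' @param bivalent_flags Named list (by locus id) of named logical vectors
#'   (by cell type), as returned by [bivalent_association()].
#' @param cgi_counts Optional named integer vector by locus id (NA allowed).
#' @param grb_flags Optional named logical vector by locus id.
#' @param min_lineages Minimum number of supporting lineage comparisons.
#' @return Data frame of prediction records, one row per locus, sorted by
#'   number of supporting lineages then id; column `predicted` marks the
#'   final calls.
#' @export
predict_targets <- function(loci, splits, bivalent_flags,
                            cgi_counts = NULL, grb_flags = NULL,
                            min_lineages = 1) {
  stopifnot(length(splits) >= 1)
  ids <- loci$id
  enr <- vapply(ids, function(i) {
    paste(names(splits)[vapply(splits, function(s) i %in% s$enriched,
                               logical(1))], collapse = ",")
  }, "")
  n_lin <- ifelse(nzchar(enr), lengths(strsplit(enr, ",")), 0L)
  biv <- vapply(ids, function(i) {
    f <- bivalent_flags[[i]]
    if (is.null(f)) "" else paste(names(f)[!is.na(f) & f], collapse = ",")
  }, "")
  location <- ifelse(loci$class_label == "intergenic", "intergenic",
                     paste0("intron-of-", loci$host_gene))
  out <- data.frame(
    locus_id = ids,
    location_class = location,
    enriched_lineages = enr,
    n_enriched_lineages = as.integer(n_lin),
    bivalent_cell_types = biv,
    cgi_count = if (is.null(cgi_counts)) NA_integer_
                else as.integer(cgi_counts[ids]),
    grb_overlap = if (is.null(grb_flags)) NA else grb_flags[ids],
    stringsAsFactors = FALSE)
  out$predicted <- out$n_enriched_lineages >= min_lineages & nzchar(out$bivalent_cell_types)
  out <- out[order(-out$n_enriched_lineages, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision and recall of predictions against generator truth
#'
#' Predicted loci are expanded to their member miRNAs (a predicted cluster
#' recovers each of its planted members).
#'
#' @param predictions Output of [predict_targets()].
#' @param clusters Cluster table ([cluster_st_mirnas()]).
#' @param truth_planted Character vector of planted target miRNA ids.
#' @return List: precision, recall, n_predicted, true_positives.
#' @export
prediction_performance <- function(predictions, clusters, truth_planted) {
  pred <- predictions$locus_id[predictions$predicted]
  members <- strsplit(clusters$members, ",")
  names(members) <- clusters$cluster_id
  pred_ids <- unique(unlist(members[pred], use.names = FALSE))
  tp <- intersect(pred_ids, truth_planted)
  list(precision = if (length(pred_ids)) length(tp) / length(pred_ids) else NA_real_,
       recall = length(tp) / length(truth_planted),
       n_predicted = length(pred_ids), true_positives = length(tp))
}
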