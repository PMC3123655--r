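# miRNA classification, the self-transcribed (ST) set, and genomic clustering.

#' Classify pre-miRNAs as intergenic or intragenic
#'
#' A pre-miRNA is intragenic iff it shares at least 1 bp with the body of a
#' protein-coding gene; the host gene is the gene with maximal overlap (ties
#' broken by lexicographically smallest gene id, for determinism).
#'
#' @param mirnas Pre-miRNA table (chrom, start, end, strand, id, ...).
#' @param genes Gene table; only `biotype == "protein_coding"` rows are used.
#' @return `mirnas` with `class_label` ("intergenic"/"intragenic") and
#'   `host_gene` (gene id or NA) columns.
#' @export
classify_mirnas <- function(mirnas, genes) {
  mirnas$class_label <- rep("intergenic", nrow(mirnas))
  mirnas$host_gene <- rep(NA_character_, nrow(mirnas))
  pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  if (nrow(mirnas) == 0 || nrow(pc) == 0) return(mirnas)
  hits <- GenomicRanges::findOverlaps(as_granges(mirnas), as_granges(pc))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- pmin(mirnas$end[q], pc$end[s]) - pmax(mirnas$start[q], pc$start[s])
    # per miRNA: host = max overlap, tie -> smallest gene id
    ord <- order(q, -ov, pc$id[s])
    first <- !duplicated(q[ord])
    mirnas$class_label[q[ord][first]] <- "intragenic"
    mirnas$host_gene[q[ord][first]] <- pc$id[s[ord]][first]
  }
  mirnas
}

#' Derive the self-transcribed (ST) miRNA set
#'
#' ST miRNAs are presumed to be transcribed from their own promoter: all
#' intergenic miRNAs, plus intragenic miRNAs whose zebrafish ortholog is
#' intergenic (the mir-9-1 pattern, where the fate after the teleost
#' whole-genome duplication shows the host gene is dispensable), minus
#' Pol III-transcribed loci.
#'
#' @param human Classified human pre-miRNA table (see [classify_mirnas()]).
#' @param zebrafish Classified zebrafish pre-miRNA table, or NULL.
#' @param ortholog_map Data frame with columns `human_id`, `other_id`,
#'   `lineage` (e.g. "human:zebrafish"); may cover several lineages.
#' @param pol3_exclusions Character vector of Pol III-transcribed miRNA ids.
#' @return Subset of `human` that qualifies as ST, with a `conserved_lineages`
#'   column (comma-separated lineages in which an ortholog exists).
#' @export
define_st_mirnas <- function(human, zebrafish = NULL, ortholog_map = NULL,
                             pol3_exclusions = character()) {
  st <- human$class_label == "intergenic"
  if (!is.null(zebrafish) && !is.null(ortholog_map)) {
    zmap <- ortholog_map[ortholog_map$lineage == "human:zebrafish", , drop = FALSE]
    z_class <- stats::setNames(zebrafish$class_label, zebrafish$id)
    z_of <- stats::setNames(zmap$other_id, zmap$human_id)
    intra <- which(human$class_label == "intragenic")
    zid <- z_of[human$id[intra]]
    st[intra] <- !is.na(zid) & z_class[zid] %in% "intergenic"
  }
  st <- st & !(human$id %in% pol3_exclusions)
  out <- human[st, , drop = FALSE]
  if (!is.null(ortholog_map) && nrow(out)) {
    lin <- vapply(out$id, function(i) {
      paste(sort(unique(ortholog_map$lineage[ortholog_map$human_id == i])),
            collapse = ",")
    }, "")
    out$conserved_lineages <- lin
  } else {
    out$conserved_lineages <- rep("", nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Cluster ST miRNAs sharing a putative promoter
#'
#' Single-linkage clustering of co-stranded miRNAs on the same chromosome:
#' consecutive loci join a cluster when the gap between interval boundaries
#' (`next start - previous end`) is strictly less than `max_gap`. The cluster
#' representative is the 5'-most member by cluster strand (the member whose
#' promoter the cluster is presumed to share).
#'
#' @param mirnas ST miRNA table (stranded).
#' @param max_gap Maximum gap in bp (exclusive); default 10 kb.
#' @return Cluster table: cluster_id, chrom, start, end, strand, members
#'   (comma-separated ids in genomic order), representative id, n_members.
#' @export
cluster_st_mirnas <- function(mirnas, max_gap = 10000) {
  if (nrow(mirnas) == 0) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      members = character(), representative = character(),
                      n_members = integer(), stringsAsFactors = FALSE))
  }
  stopifnot(all(mirnas$strand %in% c("+", "-")))
  ord <- order(mirnas$chrom, mirnas$strand, mirnas$start, mirnas$end)
  m <- mirnas[ord, , drop = FALSE]
  key <- paste(m$chrom, m$strand)
  new_cluster <- c(TRUE, key[-1] != key[-nrow(m)] |
                     (m$start[-1] - m$end[-nrow(m)]) >= max_gap)
  grp <- cumsum(new_cluster)
  out <- do.call(rbind, lapply(split(seq_len(nrow(m)), grp), function(ix) {
    mm <- m[ix, , drop = FALSE]
    rep_id <- if (mm$strand[1] == "+") mm$id[which.min(mm$start)]
              else mm$id[which.max(mm$end)]
    data.frame(cluster_id = NA_character_, chrom = mm$chrom[1],
               start = min(mm$start), end = max(mm$end), strand = mm$strand[1],
               members = paste(mm$id, collapse = ","), representative = rep_id,
               n_members = nrow(mm), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$cluster_id <- ifelse(
    out$n_members == 1, out$representative,
    vapply(strsplit(out$members, ","),
           function(ms) paste0(ms[1], "~", ms[length(ms)]), ""))
  rownames(out) <- NULL
  out
}

#' Representative locus coordinates of each cluster
#'
#' Returns one interval row per cluster: the representative member's
#' pre-miRNA interval (the paper's "one promoter per cluster" convention).
#'
#' @param clusters Cluster table from [cluster_st_mirnas()].
#' @param mirnas The miRNA table the clusters were built from.
#' @return Interval table with cluster_id as `id`.
#' @export
cluster_representatives <- function(clusters, mirnas) {
  ix <- match(clusters$representative, mirnas$id)
  out <- mirnas[ix, , drop = FALSE]
  out$mirna_id <- out$id
  out$id <- clusters$cluster_id
  rownames(out) <- NULL
  out
}
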