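#!/usr/bin/env Rscript
# Stage 5: bivalent promoters and CGI features of enriched vs poor loci.
#
# ST clusters are median-split by HCNE density (top half "enriched"); for
# intergenic loci the 50 kb upstream promoter window (gene-truncated) is
# intersected with bivalent domains per cell type and the association rates
# are compared with a one-sided Fisher exact test. CpG-to-gene ratios
# (clipped CGI bases over transcript length) are compared between groups
# with a one-sided Wilcoxon rank-sum test.

suppressPackageStartupMessages(library(mirgrb))

bundle <- read_fixture_suite("results/bundle")
human <- classify_mirnas(bundle$pre_mirnas, bundle$genes)
zebrafish <- classify_mirnas(bundle$zebrafish$pre_mirnas,
                             bundle$zebrafish$genes)
st <- define_st_mirnas(human, zebrafish, bundle$ortholog_map, bundle$pol3_ids)
loci <- cluster_representatives(cluster_st_mirnas(st), st)

lin1 <- names(bundle$hcnes)[1]
dens <- densities_at_anchors(loci$chrom, anchor_point(loci),
                             bundle$hcnes[[lin1]], bundle$chrom_sizes)
split <- median_split(stats::setNames(dens, loci$id),
                      score_name = paste0("hcne:", lin1))

proms <- build_search_windows(loci, "promoter", bundle$genes,
                              bundle$chrom_sizes)
flags <- vapply(loci$id, function(i) {
  f <- bivalent_association(proms[[i]], bundle$bivalent_domains,
                            intergenic = loci$class_label[loci$id == i] ==
                              "intergenic")
  if (all(is.na(f))) NA else any(f)
}, logical(1))
ct <- bivalent_contingency(flags, split)
cat(sprintf("bivalent association: %d%% (%d/%d) of enriched vs %d%% (%d/%d) of poor loci\n",
            ct$pct_enriched, ct$table["enriched", "bivalent"], ct$n_enriched,
            ct$pct_poor, ct$table["poor", "bivalent"], ct$n_poor))
cat(sprintf("one-sided Fisher p = %.4g (two-sided %.4g)\n", ct$p_one_sided,
            ct$p_two_sided))

# CpG-to-gene ratios, only for loci with a primary-transcript model
tr <- bundle$transcript_models
ratios <- vapply(loci$mirna_id, function(m) {
  t1 <- tr[tr$mirna_id == m, , drop = FALSE]
  if (nrow(t1) == 0) return(NA_real_)
  cgi_features(t1[1, ], bundle$cgis)$cpg_to_gene_ratio
}, numeric(1))
names(ratios) <- loci$id
re <- ratios[split$enriched]; rp <- ratios[split$poor]
re <- re[!is.na(re)]; rp <- rp[!is.na(rp)]
p_w <- wilcoxon_one_sided(rp, re, "x<y")
cat(sprintf("median CpG-to-gene ratio: enriched %.4f (n=%d) vs poor %.4f (n=%d)\n",
            stats::median(re), length(re), stats::median(rp), length(rp)))
cat(sprintf("one-sided Wilcoxon p (poor < enriched) = %.4g\n", p_w))

feat <- data.frame(locus_id = loci$id, class_label = loci$class_label,
                   hcne_density = dens,
                   enriched = loci$id %in% split$enriched,
                   bivalent = flags, cpg_to_gene_ratio = ratios[loci$id])
utils::write.table(feat, "results/epigenome_features.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
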