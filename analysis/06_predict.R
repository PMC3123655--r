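#!/usr/bin/env Rscript
# Stage 6: the final predicted GRB-target miRNA table, evaluated against the
# generator's planted truth.
#
# A cluster is called a putative GRB target when it is HCNE-enriched in at
# least one lineage comparison and its promoter carries a bivalent domain in
# at least one developmental cell type. CGI counts in the full -50 kb/+20 kb
# window and GRB overlaps are reported as annotation only.

suppressPackageStartupMessages(library(mirgrb))

seed <- 101
bundle <- read_fixture_suite("results/bundle")
res <- run_pipeline(bundle, n_control_sets = 100, nboot = 1000, seed = seed,
                    outdir = "results/pipeline")

pred <- res$predictions[res$predictions$predicted, ]
cat(sprintf("predicted GRB-target loci: %d of %d ST clusters\n", nrow(pred),
            nrow(res$predictions)))
print(utils::head(pred[, c("locus_id", "location_class", "enriched_lineages",
                           "bivalent_cell_types", "cgi_count")], 10))
perf <- res$performance
cat(sprintf("against planted truth: precision %.2f, recall %.2f (%d predicted, %d true)\n",
            perf$precision, perf$recall, perf$n_predicted,
            perf$true_positives))
utils::write.table(res$predictions, "results/predictions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
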