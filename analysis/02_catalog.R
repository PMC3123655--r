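#!/usr/bin/env Rscript
# Stage 2: classify miRNAs, derive the self-transcribed (ST) set, cluster it.
#
# A miRNA is intragenic when its precursor shares >= 1 bp with a
# protein-coding gene body. ST miRNAs (presumed to own their promoter) are
# the intergenic loci plus intragenic loci whose zebrafish ortholog is
# intergenic, minus Pol III-transcribed cases; ST loci under 10 kb apart on
# one strand are clustered and represented by their 5'-most member.

suppressPackageStartupMessages(library(mirgrb))

bundle <- read_fixture_suite("results/bundle")
human <- classify_mirnas(bundle$pre_mirnas, bundle$genes)
zebrafish <- classify_mirnas(bundle$zebrafish$pre_mirnas,
                             bundle$zebrafish$genes)
st <- define_st_mirnas(human, zebrafish, bundle$ortholog_map,
                       pol3_exclusions = bundle$pol3_ids)
clusters <- cluster_st_mirnas(st)

utils::write.table(human[, setdiff(names(human), "sequence")],
                   "results/catalog.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(clusters, "results/clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("miRNAs: %d (%d intergenic / %d intragenic)\n", nrow(human),
            sum(human$class_label == "intergenic"),
            sum(human$class_label == "intragenic")))
cat(sprintf("ST miRNAs: %d (Pol III excluded: %d; intragenic rescued via zebrafish: %d)\n",
            nrow(st), length(bundle$pol3_ids),
            sum(st$class_label == "intragenic")))
cat(sprintf("clusters: %d (%d multi-member)\n", nrow(clusters),
            sum(clusters$n_members > 1)))
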