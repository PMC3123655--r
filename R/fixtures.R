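# Plain-text fixture suite: write a bundle as BED/GFF/FASTA/TSV files and
# read it back. The files are the same formats the real data arrive in, so a
# written bundle round-trips through the standard readers.

#' Write an annotation bundle as a directory of standard-format files
#'
#' Emits genes.gff3, pre_mirnas.bed (+ pre_mirnas.fa / mature.fa),
#' hcne_<lineage>.bed (identity in the score column), p300.bed,
#' bivalent.bed (cell type in the name column), cgi.bed, grb.bed,
#' transcripts.bed, chrom.sizes, ortholog_map.tsv, truth.tsv, and a
#' zebrafish/ subdirectory with the same layout.
#'
#' @param bundle An `annotation_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_suite <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_chrom_sizes(bundle$chrom_sizes, p("chrom.sizes"))
  write_gff_genes(bundle$genes, p("genes.gff3"))
  write_bed(bundle$pre_mirnas[, c("chrom", "start", "end", "strand")] |>
              transform(name = bundle$pre_mirnas$id, score = 0),
            p("pre_mirnas.bed"))
  write_fasta_seqs(bundle$pre_mirnas$sequence, bundle$pre_mirnas$id,
                   p("pre_mirnas.fa"))
  write_fasta_seqs(bundle$mature_mirnas$sequence, bundle$mature_mirnas$id,
                   p("mature.fa"))
  for (lin in names(bundle$hcnes)) {
    h <- bundle$hcnes[[lin]]
    h$name <- sprintf("hcne%05d", seq_len(nrow(h)))
    write_bed(h, p(paste0("hcne_", gsub("[^a-z]", "_", lin), ".bed")),
              extra_as = c(score = "identity_pct"))
  }
  write_bed(bundle$peaks, p("p300.bed"))
  write_bed(bundle$bivalent_domains, p("bivalent.bed"),
            extra_as = c(name = "cell_type"))
  write_bed(bundle$cgis, p("cgi.bed"))
  write_bed(bundle$grbs, p("grb.bed"))
  tr <- bundle$transcript_models
  write_bed(data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                       name = tr$mirna_id, score = 0, strand = tr$strand),
            p("transcripts.bed"))
  write_tsv_file(bundle$ortholog_map, p("ortholog_map.tsv"))
  write_tsv_file(bundle$truth, p("truth.tsv"))
  writeLines(bundle$pol3_ids, p("pol3_exclusions.txt"))
  zdir <- file.path(dir, "zebrafish")
  dir.create(zdir, showWarnings = FALSE)
  z <- bundle$zebrafish
  write_chrom_sizes(z$chrom_sizes, file.path(zdir, "chrom.sizes"))
  write_gff_genes(z$genes, file.path(zdir, "genes.gff3"))
  write_bed(data.frame(chrom = z$pre_mirnas$chrom, start = z$pre_mirnas$start,
                       end = z$pre_mirnas$end, name = z$pre_mirnas$id,
                       score = 0, strand = z$pre_mirnas$strand),
            file.path(zdir, "pre_mirnas.bed"))
  write_fasta_seqs(z$pre_mirnas$sequence, z$pre_mirnas$id,
                   file.path(zdir, "pre_mirnas.fa"))
  write_fasta_seqs(z$mature_mirnas$sequence, z$mature_mirnas$id,
                   file.path(zdir, "mature.fa"))
  invisible(dir)
}

#' @keywords internal
write_fasta_seqs <- function(seqs, ids, path) {
  x <- Biostrings::RNAStringSet(chartr("T", "U", seqs))
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @keywords internal
read_fasta_seqs <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a fixture suite back into an annotation bundle
#'
#' Inverse of [write_fixture_suite()] for the coordinate and sequence content
#' (generator truth labels and config are re-attached from truth.tsv).
#'
#' @param dir Directory written by [write_fixture_suite()].
#' @return An `annotation_bundle` (without a `config` entry).
#' @export
read_fixture_suite <- function(dir) {
  p <- function(f) file.path(dir, f)
  sizes <- read_chrom_sizes(p("chrom.sizes"))
  genes <- read_gff_genes(p("genes.gff3"))
  pre <- read_bed(p("pre_mirnas.bed"), col_names = c(name = "id"))
  pre$score <- NULL
  pre_seq <- read_fasta_seqs(p("pre_mirnas.fa"))
  pre$sequence <- unname(pre_seq[pre$id])
  mat_seq <- read_fasta_seqs(p("mature.fa"))
  mature <- data.frame(id = names(mat_seq),
                       mirna_id = sub("-mat$", "", names(mat_seq)),
                       sequence = unname(mat_seq), stringsAsFactors = FALSE)
  hcne_files <- list.files(dir, pattern = "^hcne_.*\\.bed$")
  hcnes <- stats::setNames(lapply(hcne_files, function(f) {
    h <- read_bed(p(f), col_names = c(score = "identity_pct"))
    h$name <- NULL
    h
  }), sub("^hcne_(.*)\\.bed$", "\\1", hcne_files))
  names(hcnes) <- sub("human_", "human:", names(hcnes))
  bivalent <- read_bed(p("bivalent.bed"), col_names = c(name = "cell_type"))
  bivalent$score <- NULL
  tr <- read_bed(p("transcripts.bed"), col_names = c(name = "mirna_id"))
  tr$score <- NULL
  truth <- utils::read.table(p("truth.tsv"), header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  zdir <- file.path(dir, "zebrafish")
  z_pre <- read_bed(file.path(zdir, "pre_mirnas.bed"),
                    col_names = c(name = "id"))
  z_pre$score <- NULL
  z_pre_seq <- read_fasta_seqs(file.path(zdir, "pre_mirnas.fa"))
  z_pre$sequence <- unname(z_pre_seq[z_pre$id])
  z_mat_seq <- read_fasta_seqs(file.path(zdir, "mature.fa"))
  structure(list(
    chrom_sizes = sizes, genes = genes, pre_mirnas = pre,
    mature_mirnas = mature, hcnes = hcnes, peaks = read_bed(p("p300.bed")),
    bivalent_domains = bivalent, cgis = read_bed(p("cgi.bed")),
    grbs = read_bed(p("grb.bed")),
    transcript_models = data.frame(
      mirna_id = tr$mirna_id, chrom = tr$chrom, start = tr$start,
      end = tr$end, strand = tr$strand, source = "synthetic",
      stringsAsFactors = FALSE),
    ortholog_map = utils::read.table(p("ortholog_map.tsv"), header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE),
    pol3_ids = readLines(p("pol3_exclusions.txt")),
    zebrafish = list(
      chrom_sizes = read_chrom_sizes(file.path(zdir, "chrom.sizes")),
      genes = read_gff_genes(file.path(zdir, "genes.gff3")),
      pre_mirnas = z_pre,
      mature_mirnas = data.frame(id = names(z_mat_seq),
                                 mirna_id = sub("-mat$", "", names(z_mat_seq)),
                                 sequence = unname(z_mat_seq),
                                 stringsAsFactors = FALSE)),
    truth = truth), class = "annotation_bundle")
}
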