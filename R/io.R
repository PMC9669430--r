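#' Convert an exon table to GRanges
#'
#' @param exons Exon tibble (`transcript_id`, `chrom`, `strand`, `start`,
#'   `end`, optional `gene_id`, `exon_number`, `biotype`).
#' @return A `GRanges` with GTF-style metadata columns.
#' @export
exons_to_granges <- function(exons) {
  exons <- as_tibble(exons)
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    strand = exons$strand
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id %||% exons$transcript_id
  S4Vectors::mcols(gr)$transcript_id <- exons$transcript_id
  if ("exon_number" %in% names(exons)) {
    S4Vectors::mcols(gr)$exon_number <- as.character(exons$exon_number)
  }
  if ("biotype" %in% names(exons)) {
    S4Vectors::mcols(gr)$gene_biotype <- exons$biotype
  }
  gr
}

#' Write an exon table as GTF
#'
#' @inheritParams exons_to_granges
#' @param path Output path.
#' @export
write_gtf <- function(exons, path) {
  rtracklayer::export(exons_to_granges(exons), path, format = "gtf")
  invisible(path)
}

#' Read a GTF into an exon table
#'
#' Imports exon records (feature type `exon`; when a file carries no typed
#' exon rows, all rows are used) into the package's tidy exon layout.
#'
#' @param path GTF path.
#' @return Exon tibble: `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `exon_number`, `biotype` (`NA` when the file has no
#'   biotype attribute).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "exon")) gr <- gr[md$type == "exon"]
  md <- S4Vectors::mcols(gr)
  bio <- if ("gene_biotype" %in% names(md)) as.character(md$gene_biotype) else NA_character_
  exno <- if ("exon_number" %in% names(md)) suppressWarnings(as.integer(md$exon_number)) else NA_integer_
  tibble(
    transcript_id = as.character(md$transcript_id),
    gene_id = if ("gene_id" %in% names(md)) as.character(md$gene_id) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    exon_number = exno,
    biotype = bio
  )
}

#' @noRd
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}

#' @noRd
read_fasta <- function(path) {
  as_seq_vector(Biostrings::readDNAStringSet(path))
}

#' Write the simulated dataset to a directory
#'
#' @param ds Output of [simulate_dataset()].
#' @param dir Target directory (created if needed).
#' @return Named character vector of written file paths.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- c(
    reference_gtf = p("reference.gtf"), genome_fa = p("genome.fa"),
    assembly_gtf = p("assembly.gtf"), transcripts_fa = p("transcripts.fa"),
    counts_tsv = p("counts.tsv"), groups_tsv = p("groups.tsv"),
    lengths_tsv = p("feature_lengths.tsv"), precursors_fa = p("precursors.fa"),
    gene_sets_gmt = p("gene_sets.gmt"),
    truth_de = p("truth_de_features.tsv"),
    truth_classes = p("truth_class_labels.tsv"),
    truth_cis = p("truth_cis_pairs.tsv"),
    truth_precursors = p("truth_precursors.tsv"),
    truth_loci = p("truth_loci.tsv")
  )
  write_gtf(ds$annotation, files["reference_gtf"])
  write_fasta(ds$genome, files["genome_fa"])
  write_gtf(ds$candidates, files["assembly_gtf"])
  write_fasta(ds$seqs, files["transcripts_fa"])
  readr::write_tsv(ds$counts, files["counts_tsv"])
  readr::write_tsv(ds$groups, files["groups_tsv"])
  readr::write_tsv(ds$lengths, files["lengths_tsv"])
  db <- ds$truth$precursor_db
  write_fasta(setNames(db$seq, db$precursor_id), files["precursors_fa"])
  write_gmt(ds$gene_sets, files["gene_sets_gmt"])
  readr::write_tsv(ds$truth$de_features, files["truth_de"])
  readr::write_tsv(ds$truth$class_labels, files["truth_classes"])
  readr::write_tsv(ds$truth$cis_pairs, files["truth_cis"])
  readr::write_tsv(ds$truth$precursors, files["truth_precursors"])
  readr::write_tsv(ds$truth$loci, files["truth_loci"])
  files
}
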