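DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
check_dna <- function(seq, arg = "seq") {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T} (first offender: element %d)",
      arg, which(bad)[1]
    ))
  }
  invisible(seq)
}

#' @noRd
as_seq_vector <- function(x, arg = "sequences") {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) abort(sprintf("%s must be a character vector or XStringSet", arg))
  if (is.null(names(x)) && length(x) > 0) names(x) <- paste0("seq", seq_along(x))
  toupper(x)
}

#' @noRd
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Remove every occurrence of a motif from a sequence by point substitution
# (last base of each occurrence replaced with `sub`); iterated so overlapping
# occurrences are also removed. Replacement cannot reintroduce the motif as
# long as `sub` differs from the motif's last base.
#' @noRd
scrub_motif <- function(seq, motif = "ATG", sub = "C") {
  stopifnot(nchar(motif) >= 2, substr(motif, nchar(motif), nchar(motif)) != sub)
  repl <- paste0(substr(motif, 1, nchar(motif) - 1), sub)
  while (grepl(motif, seq, fixed = TRUE)) {
    seq <- gsub(motif, repl, seq, fixed = TRUE)
  }
  seq
}

#' Collapse an exon table to one span per transcript
#'
#' @param exons A data frame with one row per exon and columns
#'   `transcript_id`, `chrom`, `strand`, `start`, `end`, and optionally
#'   `gene_id` and `biotype`. Coordinates are 1-based closed (GTF convention).
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `n_exons`, `length` (spliced length,
#'   sum of exon widths) and `biotype` when present in the input.
#' @export
transcript_spans <- function(exons) {
  exons <- as_tibble(exons)
  need <- c("transcript_id", "chrom", "strand", "start", "end")
  missing <- setdiff(need, names(exons))
  if (length(missing)) abort(paste0("exon table lacks column(s): ", paste(missing, collapse = ", ")))
  if (!"gene_id" %in% names(exons)) exons$gene_id <- NA_character_
  keep_bio <- "biotype" %in% names(exons)
  out <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      n_exons = dplyr::n(),
      length = sum(.data$end - .data$start + 1),
      biotype = if (keep_bio) .data$biotype[1] else NA_character_,
      .groups = "drop"
    )
  if (!keep_bio) out$biotype <- NULL
  out
}

# Canonical key for exact structure matching: multi-exon transcripts are keyed
# by chrom/strand/intron chain (terminal exon ends free to differ); single-exon
# transcripts by their exact interval.
#' @noRd
chain_key <- function(exons) {
  exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      key = {
        s <- sort(.data$start)
        e <- sort(.data$end)
        if (length(s) == 1) {
          paste0(.data$chrom[1], "|", .data$strand[1], "|SE:", s, "-", e)
        } else {
          junc <- paste(e[-length(e)], s[-1], sep = "^", collapse = ";")
          paste0(.data$chrom[1], "|", .data$strand[1], "|IC:", junc)
        }
      },
      .groups = "drop"
    )
}

#' @noRd
check_two_groups <- function(groups) {
  groups <- as_tibble(groups)
  if (!all(c("sample", "group") %in% names(groups))) {
    abort("groups must have columns 'sample' and 'group'")
  }
  lv <- unique(as.character(groups$group))
  if (length(lv) != 2) abort(sprintf("exactly two groups required, found %d", length(lv)))
  groups
}

# Derive a stage seed from a global seed; keeps values well inside .Machine's
# 32-bit integer range for any sane user seed.
#' @noRd
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% 2147483647L)
}
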