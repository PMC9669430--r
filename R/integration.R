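#' @noRd
as_span_table <- function(x, id_col) {
  x <- as_tibble(x)
  has_tx <- "transcript_id" %in% names(x)
  if ("exon_number" %in% names(x) || (has_tx && anyDuplicated(x$transcript_id))) {
    x <- transcript_spans(x)
  }
  if (!id_col %in% names(x)) {
    if (id_col == "gene_id" && "transcript_id" %in% names(x)) {
      x$gene_id <- x$transcript_id
    } else if (id_col == "lncrna_id" && "transcript_id" %in% names(x)) {
      x$lncrna_id <- x$transcript_id
    } else {
      abort(sprintf("span table lacks an identifier column usable as '%s'", id_col))
    }
  }
  x
}

#' Predict cis-target genes of lncRNAs by genomic proximity
#'
#' A gene is a cis target of a lncRNA when their genomic spans overlap or lie
#' within `window` bp of each other on the same chromosome (strict `<`,
#' strand-agnostic). The gap is the minimal boundary-to-boundary distance
#' between the closed intervals, 0 when they overlap. Each (lncRNA, gene)
#' pair is emitted once.
#'
#' @param lncrnas Span or exon table of lncRNAs (identifier taken from
#'   `lncrna_id` or `transcript_id`).
#' @param reference Span or exon table of genes; rows with
#'   `biotype == "coding"` are used when a `biotype` column is present.
#'   Gene identity is taken from `gene_id` (falling back to
#'   `transcript_id`); spans are the union per gene.
#' @param window Maximum gap in bp, exclusive. The default 100,000 emits a
#'   99,999-bp gap and rejects a 100,000-bp one.
#' @return A tibble: `lncrna_id`, `gene_id`, `chrom`, `gap_bp`, `relation`
#'   (`"overlap"`, `"upstream"` or `"downstream"`, relative to the gene on
#'   its strand).
#' @export
predict_cis_targets <- function(lncrnas, reference, window = 100000) {
  lnc <- as_span_table(lncrnas, "lncrna_id")
  ref <- as_tibble(reference)
  if ("biotype" %in% names(ref)) ref <- filter(ref, .data$biotype == "coding")
  if (!"gene_id" %in% names(ref) || all(is.na(ref$gene_id))) {
    ref$gene_id <- ref$transcript_id
  }
  genes <- ref %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end), .groups = "drop")
  pairs <- inner_join(
    select(lnc, "lncrna_id", "chrom", l_start = "start", l_end = "end"),
    select(genes, "gene_id", "chrom", g_strand = "strand",
           g_start = "start", g_end = "end"),
    by = "chrom", relationship = "many-to-many"
  )
  if (nrow(pairs) == 0) {
    return(tibble(lncrna_id = character(), gene_id = character(),
                  chrom = character(), gap_bp = integer(), relation = character()))
  }
  overlap <- intervals_overlap(pairs$l_start, pairs$l_end, pairs$g_start, pairs$g_end)
  gap <- ifelse(overlap, 0L,
                ifelse(pairs$l_start > pairs$g_end,
                       pairs$l_start - pairs$g_end - 1L,
                       pairs$g_start - pairs$l_end - 1L))
  # side of the gene, in the gene's own orientation
  lnc_left <- pairs$l_end < pairs$g_start
  relation <- dplyr::case_when(
    overlap ~ "overlap",
    (lnc_left & pairs$g_strand == "+") | (!lnc_left & pairs$g_strand == "-") ~ "upstream",
    TRUE ~ "downstream"
  )
  out <- pairs %>%
    mutate(gap_bp = as.integer(gap), relation = relation) %>%
    filter(.data$gap_bp < window) %>%
    select("lncrna_id", "gene_id", "chrom", "gap_bp", "relation") %>%
    arrange(.data$lncrna_id, .data$gene_id)
  distinct(out, .data$lncrna_id, .data$gene_id, .keep_all = TRUE)
}

#' Smith-Waterman local alignment of two nucleotide sequences
#'
#' Optimal local alignment under match/mismatch scoring with a linear gap
#' penalty, computed by dynamic programming with deterministic tie-breaking
#' (the best cell with the lowest end coordinates wins; traceback prefers
#' substitution over a gap in the subject over a gap in the query).
#'
#' @param query,subject Nucleotide strings over A/C/G/T.
#' @param match Score per matching column (default +2).
#' @param mismatch Score per mismatching column (default -1).
#' @param gap Score per gapped column (default -2, linear).
#' @return A one-row tibble: `score`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (1-based alignment span; 0s for an empty alignment),
#'   `identity` (matches / aligned columns) and `coverage` (aligned subject
#'   span / subject length).
#' @export
#' @examples
#' local_align("ACGT", "ACGT") # perfect 4-match alignment, score 8
local_align <- function(query, subject, match = 2, mismatch = -1, gap = -2) {
  stopifnot(is.character(query), is.character(subject),
            length(query) == 1, length(subject) == 1)
  query <- toupper(query); subject <- toupper(subject)
  if (nchar(query) == 0 || nchar(subject) == 0) abort("sequences must be nonempty")
  check_dna(query, "query"); check_dna(subject, "subject")
  res <- .sw_align(query, subject, match = match, mismatch = mismatch, gap = gap)
  aligned <- res$aligned
  tibble(
    score = res$score,
    q_start = res$q_start, q_end = res$q_end,
    s_start = res$s_start, s_end = res$s_end,
    identity = if (aligned > 0) res$matches / aligned else 0,
    coverage = if (aligned > 0) (res$s_end - res$s_start + 1) / nchar(subject) else 0
  )
}

#' Scan differentially expressed lncRNAs for miRNA-precursor homology
#'
#' Aligns every lncRNA against every precursor in the database with
#' [local_align()] and keeps hits passing the identity and subject-coverage
#' thresholds; a lncRNA carrying a verbatim embedded precursor scores
#' identity 1 and coverage 1.
#'
#' @param del_seqs Named character vector (or `XStringSet`) of lncRNA
#'   sequences (typically the DELs).
#' @param precursor_db Named character vector (or `XStringSet`) of miRNA
#'   precursor sequences.
#' @param min_identity,min_coverage Retention thresholds in (0, 1\].
#' @inheritParams local_align
#' @return A list: `hits` (tibble `del_id`, `precursor_id`, `score`,
#'   `identity`, `coverage`, `best` flagging each lncRNA's best-scoring hit),
#'   and `n_dels_with_hit` (count of lncRNAs with at least one hit).
#' @export
precursor_scan <- function(del_seqs, precursor_db,
                           min_identity = 0.9, min_coverage = 0.9,
                           match = 2, mismatch = -1, gap = -2) {
  if (min_identity <= 0 || min_identity > 1 || min_coverage <= 0 || min_coverage > 1) {
    abort("min_identity and min_coverage must be in (0, 1]")
  }
  del_seqs <- as_seq_vector(del_seqs, "del_seqs")
  precursor_db <- as_seq_vector(precursor_db, "precursor_db")
  empty <- tibble(del_id = character(), precursor_id = character(),
                  score = numeric(), identity = numeric(), coverage = numeric(),
                  best = logical())
  if (length(precursor_db) == 0) {
    inform("precursor database is empty; no hits possible")
    return(list(hits = empty, n_dels_with_hit = 0L))
  }
  hits <- purrr::map_dfr(names(del_seqs), function(d) {
    purrr::map_dfr(names(precursor_db), function(p) {
      al <- local_align(del_seqs[[d]], precursor_db[[p]],
                        match = match, mismatch = mismatch, gap = gap)
      tibble(del_id = d, precursor_id = p, score = al$score,
             identity = al$identity, coverage = al$coverage)
    })
  }) %>%
    filter(.data$identity >= min_identity, .data$coverage >= min_coverage)
  if (nrow(hits) == 0) return(list(hits = empty, n_dels_with_hit = 0L))
  hits <- hits %>%
    group_by(.data$del_id) %>%
    arrange(dplyr::desc(.data$score), .data$precursor_id, .by_group = TRUE) %>%
    mutate(best = dplyr::row_number() == 1) %>%
    ungroup() %>%
    arrange(.data$del_id, .data$precursor_id)
  list(hits = hits, n_dels_with_hit = dplyr::n_distinct(hits$del_id))
}

#' Build the core DEL-DEM network
#'
#' Connects each differentially expressed lncRNA (DEL) to every
#' differentially expressed mRNA (DEM) whose gene is one of its cis targets.
#' An edge is concordant when both members move in the same direction
#' ("same expression trends"); concordant edges form the positive-regulation
#' network, discordant edges the negative one.
#'
#' @param cis Cis-pair table from [predict_cis_targets()].
#' @param del_calls An `lnc_de` object (or tibble with `feature_id`,
#'   `direction`) for the lncRNAs.
#' @param dem_calls Same, for the mRNAs; an optional `gene_id` column maps
#'   DEM features to genes (defaults to the feature id itself).
#' @return A list: `edges` (tibble `del_id`, `dem_id`, `gene_id`,
#'   `del_direction`, `dem_direction`, `concordant`) and `summary`
#'   (one-row tibble with `n_cis_genes_dem` — distinct cis genes that are
#'   DEMs, the Venn count — `n_edges`, `n_concordant`, `n_discordant`,
#'   `n_dels_in_network`).
#' @export
build_core_network <- function(cis, del_calls, dem_calls) {
  de_tbl <- function(x) {
    if (inherits(x, "lnc_de")) x <- x$table
    x <- as_tibble(x)
    if (!"gene_id" %in% names(x)) x$gene_id <- x$feature_id
    filter(x, .data$direction %in% c("up", "down")) %>%
      select("feature_id", "gene_id", "direction")
  }
  dels <- de_tbl(del_calls)
  dems <- de_tbl(dem_calls)
  edges <- as_tibble(cis) %>%
    inner_join(select(dels, del_id = "feature_id", del_direction = "direction"),
               by = c(lncrna_id = "del_id"), keep = FALSE) %>%
    rename(del_id = "lncrna_id", del_direction = "del_direction") %>%
    inner_join(select(dems, dem_id = "feature_id", "gene_id",
                      dem_direction = "direction"),
               by = "gene_id", relationship = "many-to-many") %>%
    mutate(concordant = .data$del_direction == .data$dem_direction) %>%
    select("del_id", "dem_id", "gene_id", "del_direction", "dem_direction",
           "concordant") %>%
    arrange(.data$del_id, .data$dem_id)
  summary <- tibble(
    n_cis_genes_dem = dplyr::n_distinct(edges$gene_id),
    n_edges = nrow(edges),
    n_concordant = sum(edges$concordant),
    n_discordant = sum(!edges$concordant),
    n_dels_in_network = dplyr::n_distinct(edges$del_id)
  )
  list(edges = edges, summary = summary)
}
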