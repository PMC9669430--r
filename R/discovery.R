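#' Filter assembled candidates against a reference annotation
#'
#' Applies the two removal rules used ahead of lncRNA prediction: candidates
#' whose structure exactly matches a known coding transcript are removed as
#' re-discoveries, and candidates shorter than `min_len` (spliced length,
#' strict `<`) are removed as fragments. Multi-exon structures match a
#' reference transcript when chromosome, strand and the full intron chain
#' are identical (terminal exon ends are free to differ); single-exon
#' candidates must match a single-exon reference transcript's exact interval.
#'
#' @param candidates Exon table of assembled candidates (one row per exon;
#'   columns `transcript_id`, `chrom`, `strand`, `start`, `end`).
#' @param reference Exon table of the reference annotation; rows with
#'   `biotype == "coding"` (or all rows when no `biotype` column is present)
#'   define the known-mRNA set.
#' @param min_len Minimum spliced length retained, in nt. The default 200
#'   keeps a 200-nt candidate and removes a 199-nt one.
#' @return A tibble with one row per candidate, in input order:
#'   `transcript_id`, `length`, `retained` (logical), `reason`
#'   (`"known_mrna"`, `"short"`, or `NA` when retained) and `flag`
#'   (`"unknown_chrom"` for candidates on chromosomes absent from the
#'   reference, else `NA`). Every candidate is either retained or carries
#'   exactly one removal reason.
#' @export
filter_candidates <- function(candidates, reference, min_len = 200) {
  candidates <- as_tibble(candidates)
  reference <- as_tibble(reference)
  if ("biotype" %in% names(reference)) {
    reference <- filter(reference, .data$biotype == "coding")
  }
  spans <- transcript_spans(candidates)
  # preserve candidate input order
  ord <- unique(candidates$transcript_id)
  spans <- spans[match(ord, spans$transcript_id), ]
  ref_keys <- chain_key(reference)$key
  cand_keys <- chain_key(candidates)
  spans <- left_join(spans, cand_keys, by = "transcript_id")
  unknown <- !spans$chrom %in% unique(reference$chrom)
  if (any(unknown)) {
    warn(sprintf(
      "%d candidate(s) on chromosomes absent from the reference were retained with a flag: %s",
      sum(unknown), paste(head(spans$transcript_id[unknown], 5), collapse = ", ")
    ))
  }
  known <- spans$key %in% ref_keys
  short <- spans$length < min_len
  reason <- dplyr::case_when(known ~ "known_mrna", short ~ "short",
                             TRUE ~ NA_character_)
  tibble(
    transcript_id = spans$transcript_id,
    length = spans$length,
    retained = is.na(reason),
    reason = reason,
    flag = ifelse(unknown, "unknown_chrom", NA_character_)
  )
}

LNCRNA_CLASSES <- c("exonic_sense_overlap", "antisense", "intronic", "intergenic")

#' @noRd
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' Classify lncRNAs by genomic position
#'
#' Assigns each retained noncoding transcript exactly one positional class,
#' using a fixed precedence: (1) `exonic_sense_overlap` when any exon
#' overlaps an exon of a same-strand coding transcript; (2) `antisense` when
#' any exon overlaps an opposite-strand coding exon; (3) `intronic` when the
#' transcript lies entirely inside one intron of a coding transcript (either
#' strand); (4) `intergenic` otherwise.
#'
#' @param transcripts Exon table of the transcripts to classify.
#' @param reference Exon table of the reference annotation (coding rows used).
#' @return A tibble `transcript_id`, `class`, one row per transcript.
#' @seealso [class_count_table()] for the aggregate class distribution,
#'   [transcript_summary_table()] for exon-count and length tables.
#' @export
classify_lncrna <- function(transcripts, reference) {
  transcripts <- as_tibble(transcripts)
  reference <- as_tibble(reference)
  if ("biotype" %in% names(reference)) {
    reference <- filter(reference, .data$biotype == "coding")
  }
  # introns of every coding transcript
  introns <- reference %>%
    group_by(.data$transcript_id) %>%
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              istart = list(if (dplyr::n() > 1) sort(.data$end)[-dplyr::n()] + 1 else integer(0)),
              iend = list(if (dplyr::n() > 1) sort(.data$start)[-1] - 1 else integer(0)),
              .groups = "drop") %>%
    tidyr::unnest(c("istart", "iend"))
  ids <- unique(transcripts$transcript_id)
  cls <- vapply(ids, function(id) {
    ex <- transcripts[transcripts$transcript_id == id, ]
    chrom <- ex$chrom[1]; strand <- ex$strand[1]
    ref_ex <- reference[reference$chrom == chrom, ]
    ov <- logical(nrow(ref_ex))
    for (k in seq_len(nrow(ex))) {
      ov <- ov | intervals_overlap(ex$start[k], ex$end[k], ref_ex$start, ref_ex$end)
    }
    if (any(ov & ref_ex$strand == strand)) return("exonic_sense_overlap")
    if (any(ov & ref_ex$strand != strand)) return("antisense")
    span <- c(min(ex$start), max(ex$end))
    ir <- introns[introns$chrom == chrom, ]
    if (nrow(ir) > 0 && any(ir$istart <= span[1] & span[2] <= ir$iend)) return("intronic")
    "intergenic"
  }, character(1))
  tibble(transcript_id = ids, class = unname(cls))
}

#' Aggregate positional-class distribution
#'
#' @param classes Output of [classify_lncrna()].
#' @return A tibble `class`, `n`, `fraction`, covering all four classes
#'   (zero rows included) in precedence order.
#' @export
class_count_table <- function(classes) {
  counts <- table(factor(classes$class, levels = LNCRNA_CLASSES))
  tibble(class = LNCRNA_CLASSES, n = as.integer(counts),
         fraction = if (sum(counts) > 0) as.numeric(counts) / sum(counts) else 0)
}

#' Exon-count and spliced-length distribution of a transcript set
#'
#' Produces the per-kind tables behind the usual lncRNA-versus-mRNA
#' exon-count and length histograms.
#'
#' @param exons Exon table; an optional `kind` column (e.g. `"lncRNA"`,
#'   `"mRNA"`) groups the output, otherwise a single group is reported.
#' @return A list of tibbles: `exon_counts` (`kind`, `n_exons`, `n`) and
#'   `lengths` (`kind`, `transcript_id`, `length`).
#' @export
transcript_summary_table <- function(exons) {
  exons <- as_tibble(exons)
  kind_map <- if ("kind" %in% names(exons)) {
    distinct(exons, .data$transcript_id, .data$kind)
  } else {
    tibble(transcript_id = unique(exons$transcript_id), kind = "all")
  }
  spans <- transcript_spans(select(exons, -dplyr::any_of("kind"))) %>%
    left_join(kind_map, by = "transcript_id")
  list(
    exon_counts = spans %>% dplyr::count(.data$kind, .data$n_exons, name = "n"),
    lengths = select(spans, "kind", "transcript_id", "length")
  )
}

#' Full lncRNA discovery step
#'
#' Runs the filter, coding-potential scoring and positional classification in
#' one call: candidates surviving the length and known-mRNA filters are
#' scored, and the noncoding survivors are classified.
#'
#' @inheritParams filter_candidates
#' @inheritParams coding_potential
#' @param seqs Named character vector (or `XStringSet`) of candidate
#'   transcript sequences; names must match `transcript_id`s.
#' @return A list: `filter` (per-candidate filter table), `scores`
#'   (coding-potential table for retained candidates), `lncrnas`
#'   (tibble of noncoding survivors with class and scores) and
#'   `class_counts`.
#' @export
discover_lncrnas <- function(candidates, reference, seqs, min_len = 200,
                             orf_min = 300, fickett_cut = 0.95, cov_min = 0.5) {
  seqs <- as_seq_vector(seqs, "seqs")
  flt <- filter_candidates(candidates, reference, min_len = min_len)
  retained <- flt$transcript_id[flt$retained]
  missing <- setdiff(retained, names(seqs))
  if (length(missing)) {
    abort(paste0("sequences missing for retained candidates: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  scores <- coding_potential(seqs[retained], orf_min = orf_min,
                             fickett_cut = fickett_cut, cov_min = cov_min)
  nc_ids <- scores$id[scores$label == "noncoding"]
  cand_nc <- filter(as_tibble(candidates), .data$transcript_id %in% nc_ids)
  cls <- if (length(nc_ids)) classify_lncrna(cand_nc, reference) else
    tibble(transcript_id = character(), class = character())
  lnc <- scores %>%
    filter(.data$label == "noncoding") %>%
    rename(transcript_id = "id") %>%
    inner_join(cls, by = "transcript_id")
  list(filter = flt, scores = scores, lncrnas = lnc,
       class_counts = class_count_table(cls))
}
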