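#' Longest open reading frame of a transcript sequence
#'
#' Scans the three sense-strand frames of each sequence for the longest
#' ATG-to-stop open reading frame. The stop codon is included in the
#' reported length. Ties are broken by the smallest start position.
#' Transcript sequences are assumed to be already stranded, so only the
#' given strand is scanned.
#'
#' @param seq Character vector of nucleotide sequences over A/C/G/T (or an
#'   `XStringSet`).
#' @return A tibble with one row per sequence: `id`, `start` (1-based offset
#'   of the ATG, 0 if no complete ORF), `length_nt` (ORF length in nt
#'   including the stop codon, 0 if none) and `frame` (0, 1 or 2; `NA` if
#'   none).
#' @export
#' @examples
#' longest_orf("ATGAAATAG") # one complete ORF of 9 nt
longest_orf <- function(seq) {
  seq <- as_seq_vector(seq, "seq")
  check_dna(seq)
  rows <- lapply(seq_along(seq), function(i) {
    res <- longest_orf_one(seq[[i]])
    tibble(id = names(seq)[i],
           start = as.integer(res[["start"]]),
           length_nt = as.integer(res[["len"]]),
           frame = if (res[["len"]] > 0) as.integer(res[["frame"]]) else NA_integer_)
  })
  bind_rows(rows)
}

#' @noRd
longest_orf_one <- function(s) {
  n <- nchar(s)
  best <- c(start = 0L, len = 0L, frame = 0L)
  if (n < 6) return(best)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (frame in 0:2) {
    starts <- seq.int(1 + frame, n - 2, by = 3)
    if (length(starts) < 2) next
    codons <- paste0(chars[starts], chars[starts + 1], chars[starts + 2])
    open_at <- NA_integer_ # position (codon index) of earliest ATG since last stop
    for (k in seq_along(codons)) {
      cd <- codons[k]
      if (is.na(open_at) && cd == "ATG") open_at <- k
      if (cd %in% STOP_CODONS) {
        if (!is.na(open_at)) {
          len <- (k - open_at + 1L) * 3L
          st <- starts[open_at]
          if (len > best["len"] || (len == best["len"] && st < best["start"])) {
            best <- c(start = st, len = len, frame = frame)
          }
        }
        open_at <- NA_integer_
      }
    }
  }
  best
}

# Fickett (1982) TESTCODE lookup tables: probability that a window with the
# given position/composition parameter value is coding, and the weights
# reflecting each parameter's discriminative power.
FICKETT_POSITION_BREAKS <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
FICKETT_CONTENT_BREAKS <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

#' @noRd
fickett_lookup <- function(value, breaks, probs) {
  idx <- which(value >= breaks)[1]
  probs[idx]
}

#' Fickett TESTCODE coding statistic
#'
#' Computes the classic TESTCODE score (Fickett, 1982): for each base, a
#' position parameter (asymmetry of its occurrence among the three codon-frame
#' positions, \eqn{max/(min+1)}) and a composition parameter (overall
#' fraction), both converted to coding probabilities through the published
#' lookup tables and combined with the published weights. Scores near or above
#' 0.95 are coding-like, scores below 0.74 noncoding-like.
#'
#' @param seq Character vector of nucleotide sequences (or `XStringSet`).
#' @return Numeric vector of TESTCODE scores.
#' @export
fickett_score <- function(seq) {
  seq <- as_seq_vector(seq, "seq")
  check_dna(seq)
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < 3) abort("fickett_score requires sequences of length >= 3")
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    pos_of <- (seq_len(n) - 1L) %% 3L + 1L
    score <- 0
    for (b in DNA_BASES) {
      cnt <- vapply(1:3, function(p) sum(chars == b & pos_of == p), numeric(1))
      pos_par <- max(cnt) / (min(cnt) + 1)
      cont_par <- sum(cnt) / n
      score <- score +
        fickett_lookup(pos_par, FICKETT_POSITION_BREAKS, FICKETT_POSITION_PROB[[b]]) *
          FICKETT_POSITION_WEIGHT[[b]] +
        fickett_lookup(cont_par, FICKETT_CONTENT_BREAKS, FICKETT_CONTENT_PROB[[b]]) *
          FICKETT_CONTENT_WEIGHT[[b]]
    }
    score
  }, numeric(1), USE.NAMES = FALSE)
}

#' Coding-potential call for candidate transcripts
#'
#' Transparent composite used in place of trained coding-potential tools
#' (CPC/CNCI-style classifiers): a transcript is labelled `coding` when its
#' longest ORF reaches `orf_min` nucleotides, or when a high Fickett TESTCODE
#' score coincides with an ORF covering at least `cov_min` of the transcript.
#' Everything else is labelled `noncoding`.
#'
#' @param seq Named character vector of transcript sequences (or `XStringSet`).
#' @param orf_min Minimum longest-ORF length (nt) that alone implies coding.
#' @param fickett_cut Fickett score at or above which a transcript with
#'   substantial ORF coverage is called coding.
#' @param cov_min Minimum ORF coverage (longest ORF / transcript length) used
#'   together with `fickett_cut`.
#' @return A tibble: `id`, `length`, `longest_orf_nt`, `orf_coverage`,
#'   `fickett`, `label` (`"coding"` or `"noncoding"`).
#' @export
coding_potential <- function(seq, orf_min = 300, fickett_cut = 0.95, cov_min = 0.5) {
  seq <- as_seq_vector(seq, "seq")
  if (length(seq) == 0) {
    return(tibble(id = character(), length = integer(), longest_orf_nt = integer(),
                  orf_coverage = numeric(), fickett = numeric(), label = character()))
  }
  orf <- longest_orf(seq)
  len <- unname(nchar(seq))
  fick <- fickett_score(seq)
  cov <- orf$length_nt / len
  tibble(
    id = names(seq),
    length = unname(len),
    longest_orf_nt = orf$length_nt,
    orf_coverage = unname(cov),
    fickett = fick,
    label = ifelse(orf$length_nt >= orf_min | (fick >= fickett_cut & cov >= cov_min),
                   "coding", "noncoding")
  )
}
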