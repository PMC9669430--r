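#' @noRd
counts_to_matrix <- function(counts) {
  counts <- as_tibble(counts)
  if (!"feature_id" %in% names(counts)) abort("counts must have a 'feature_id' column")
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  if (!is.numeric(m)) abort("count columns must be numeric")
  if (any(m < 0)) abort("counts must be non-negative")
  rownames(m) <- counts$feature_id
  m
}

#' @noRd
lengths_vector <- function(lengths, feature_ids) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$feature_id)
  }
  missing <- setdiff(feature_ids, names(lengths))
  if (length(missing)) {
    abort(paste0("feature lengths missing for: ", paste(head(missing, 5), collapse = ", ")))
  }
  len <- lengths[feature_ids]
  if (any(len < 1)) abort("feature lengths must be >= 1 bp")
  len
}

#' FPKM from a read-count matrix
#'
#' Fragments per kilobase of transcript per million mapped reads, the
#' length- and depth-normalised expression unit:
#' \deqn{FPKM_{ij} = counts_{ij} \cdot 10^9 / (total_j \cdot length_i)}
#' where `total_j` is the column sum of the supplied matrix.
#'
#' @param counts Count table: a `feature_id` column plus one numeric column
#'   per sample (non-negative).
#' @param lengths Feature lengths in bp: a tibble (`feature_id`, `length`)
#'   or a named numeric vector.
#' @return A tibble of the same shape as `counts` holding FPKM values.
#' @export
#' @examples
#' counts <- tibble::tibble(feature_id = "g1", s1 = 10)
#' compute_fpkm(counts, c(g1 = 1000)) # total 10 reads -> FPKM 1e6
compute_fpkm <- function(counts, lengths) {
  m <- counts_to_matrix(counts)
  len <- lengths_vector(lengths, rownames(m))
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(paste0("sample(s) with zero total counts: ",
                 paste(colnames(m)[totals <= 0], collapse = ", ")))
  }
  fpkm <- sweep(m, 2, totals, "/") * 1e9 / as.numeric(len)
  out <- as_tibble(fpkm)
  out <- dplyr::bind_cols(tibble(feature_id = rownames(m)), out)
  out
}

#' Pearson correlation between samples
#'
#' Sample-by-sample Pearson correlation computed on `log2(FPKM + 1)`, the
#' usual scale for between-sample QC heatmaps. A sample with zero variance
#' yields `NA` against every other sample; the diagonal is exactly 1.
#'
#' @param fpkm FPKM table as returned by [compute_fpkm()].
#' @return A tibble with a `sample` column and one column per sample holding
#'   the symmetric correlation matrix.
#' @export
sample_correlation <- function(fpkm) {
  m <- counts_to_matrix(fpkm)
  if (nrow(m) < 2) {
    warn("fewer than 2 features; correlations undefined off the diagonal")
  }
  lm2 <- log2(m + 1)
  sds <- apply(lm2, 2, stats::sd)
  r <- suppressWarnings(cor(lm2, method = "pearson"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  dplyr::bind_cols(tibble(sample = colnames(m)), as_tibble(r))
}

#' Expression summaries and the mRNA-versus-lncRNA comparison
#'
#' Emits the tables behind the standard QC panels: per-sample density of
#' `log2(FPKM + 1)`, per-kind quartiles of the per-feature mean expression,
#' and a two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of mRNA
#' versus lncRNA expression levels.
#'
#' @param fpkm FPKM table as returned by [compute_fpkm()].
#' @param kinds Tibble (`feature_id`, `kind`) with `kind` in
#'   `"mRNA"`/`"lncRNA"` (other labels are carried through the summaries but
#'   only these two enter the comparison).
#' @param n_grid Number of grid points per density curve.
#' @return A list: `density` (tibble `sample`, `x`, `density`), `per_kind`
#'   (tibble `kind`, `n`, `q1`, `median`, `q3` of mean `log2(FPKM+1)`), and
#'   `comparison` (tibble `statistic`, `p_value`, or `NULL` with a notice
#'   when either kind is absent).
#' @export
expression_summaries <- function(fpkm, kinds, n_grid = 128) {
  m <- counts_to_matrix(fpkm)
  kinds <- as_tibble(kinds)
  lm2 <- log2(m + 1)
  dens <- bind_rows(lapply(colnames(lm2), function(s) {
    d <- density(lm2[, s], n = n_grid)
    tibble(sample = s, x = d$x, density = d$y)
  }))
  feat <- tibble(feature_id = rownames(m), mean_log2_fpkm = rowMeans(lm2)) %>%
    inner_join(kinds, by = "feature_id")
  per_kind <- feat %>%
    group_by(.data$kind) %>%
    summarise(n = dplyr::n(),
              q1 = quantile(.data$mean_log2_fpkm, 0.25),
              median = median(.data$mean_log2_fpkm),
              q3 = quantile(.data$mean_log2_fpkm, 0.75),
              .groups = "drop")
  mrna <- feat$mean_log2_fpkm[feat$kind == "mRNA"]
  lnc <- feat$mean_log2_fpkm[feat$kind == "lncRNA"]
  comparison <- NULL
  if (length(mrna) == 0 || length(lnc) == 0) {
    inform("mRNA/lncRNA comparison skipped: one kind has zero features")
  } else {
    wt <- wilcox.test(mrna, lnc, alternative = "two.sided", exact = FALSE)
    comparison <- tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  list(density = dens, per_kind = per_kind, comparison = comparison)
}
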