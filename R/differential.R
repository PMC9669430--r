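#' Per-feature two-group differential-expression test
#'
#' Computes group-mean FPKM, pseudocounted log2 fold change
#' (`log2((mean2 + c) / (mean1 + c))`, group 2 versus group 1) and a
#' per-feature p-value. The default test is a pooled-variance (Student)
#' two-sample t on `log2(FPKM + 1)` — with three replicates per group the
#' pooled t is exactly sized under the log-scale normal working model,
#' whereas the Welch/Satterthwaite approximation is markedly conservative
#' at this sample size; both groups share one NB dispersion, so pooling is
#' appropriate. The alternative `nb_wald` is a Wald test on the log ratio
#' of group mean counts with a moment-estimated negative-binomial
#' dispersion, usable with single-replicate groups.
#'
#' @param counts Count table (`feature_id` + one numeric column per sample).
#' @param groups Tibble (`sample`, `group`) assigning every sample to one of
#'   exactly two groups; the first group level encountered is the reference
#'   (group 1).
#' @param lengths Feature lengths (tibble or named vector) for FPKM.
#' @param method `"t_logfpkm"` (default) or `"nb_wald"`.
#' @param pseudocount Pseudocount `c` on the FPKM scale used in the fold
#'   change.
#' @return A tibble: `feature_id`, `mean_fpkm_1`, `mean_fpkm_2`, `log2fc`,
#'   `statistic`, `p_value`, `all_zero` (flag for features with zero counts
#'   everywhere).
#' @export
de_test <- function(counts, groups, lengths,
                    method = c("t_logfpkm", "nb_wald"), pseudocount = 1) {
  method <- match.arg(method)
  groups <- check_two_groups(groups)
  m <- counts_to_matrix(counts)
  missing <- setdiff(colnames(m), groups$sample)
  if (length(missing)) {
    abort(paste0("samples missing from groups: ", paste(missing, collapse = ", ")))
  }
  glab <- setNames(as.character(groups$group), groups$sample)[colnames(m)]
  lev <- unique(glab)
  idx1 <- which(glab == lev[1]); idx2 <- which(glab == lev[2])
  if (method == "t_logfpkm" && (length(idx1) < 2 || length(idx2) < 2)) {
    abort("t_logfpkm needs >= 2 samples per group; use method = 'nb_wald'")
  }
  fpkm <- counts_to_matrix(compute_fpkm(counts, lengths))
  mean1 <- rowMeans(fpkm[, idx1, drop = FALSE])
  mean2 <- rowMeans(fpkm[, idx2, drop = FALSE])
  log2fc <- log2((mean2 + pseudocount) / (mean1 + pseudocount))
  all_zero <- rowSums(m) == 0

  if (method == "t_logfpkm") {
    l1 <- log2(fpkm[, idx1, drop = FALSE] + 1)
    l2 <- log2(fpkm[, idx2, drop = FALSE] + 1)
    n1 <- length(idx1); n2 <- length(idx2)
    m1 <- rowMeans(l1); m2 <- rowMeans(l2)
    v1 <- rowSums((l1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((l2 - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    stat <- (m2 - m1) / sqrt(se2)
    p <- 2 * pt(-abs(stat), n1 + n2 - 2)
    # degenerate rows: both groups constant
    degen <- se2 == 0
    p[degen] <- ifelse(m2[degen] == m1[degen], 1, 0)
    stat[degen] <- ifelse(m2[degen] == m1[degen], 0, Inf * sign(m2 - m1)[degen])
  } else {
    c0 <- 0.5
    cm1 <- rowMeans(m[, idx1, drop = FALSE])
    cm2 <- rowMeans(m[, idx2, drop = FALSE])
    v1 <- apply(m[, idx1, drop = FALSE], 1, var)
    v2 <- apply(m[, idx2, drop = FALSE], 1, var)
    if (length(idx1) < 2) v1 <- rep(NA_real_, nrow(m))
    if (length(idx2) < 2) v2 <- rep(NA_real_, nrow(m))
    disp_of <- function(v, mu) ifelse(is.na(v) | mu <= 0, NA_real_,
                                      pmax((v - mu) / mu^2, 0))
    a1 <- disp_of(v1, cm1); a2 <- disp_of(v2, cm2)
    alpha <- rowMeans(cbind(a1, a2), na.rm = TRUE)
    alpha[is.nan(alpha)] <- 0.1 # no replicate information at all
    var_log <- function(mu, n, alpha) (1 / pmax(mu, c0) + alpha) / n
    se2 <- var_log(cm1, length(idx1), alpha) + var_log(cm2, length(idx2), alpha)
    stat <- (log(cm2 + c0) - log(cm1 + c0)) / sqrt(se2)
    p <- 2 * pnorm(-abs(stat))
  }
  p[all_zero] <- NA_real_
  tibble(feature_id = rownames(m),
         mean_fpkm_1 = unname(mean1), mean_fpkm_2 = unname(mean2),
         log2fc = unname(log2fc), statistic = unname(stat),
         p_value = unname(p), all_zero = unname(all_zero))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, n p_{(j)} / j)}, mapped back to the
#' input order. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values)) abort("p_values must be numeric")
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad)) {
    abort(sprintf("p_values outside [0, 1] at position(s): %s",
                  paste(head(which(bad), 5), collapse = ", ")))
  }
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed features
#'
#' Applies the fold-change-plus-FDR rule: a feature is `up` when
#' `log2fc >= log2(fc_cut)` and `q < q_cut`, `down` when
#' `log2fc <= -log2(fc_cut)` and `q < q_cut`, otherwise `ns`.
#'
#' @param results Output of [de_test()].
#' @param fc_cut Fold-change cutoff (linear scale; default 2).
#' @param q_cut BH q-value cutoff (default 0.05).
#' @return An object of class `lnc_de`: the annotated table (with `q_value`
#'   and `direction`) plus the thresholds. Use [tidy()] for the table and
#'   [glance()] for the up/down summary counts.
#' @export
call_de <- function(results, fc_cut = 2, q_cut = 0.05) {
  results <- as_tibble(results)
  if (fc_cut < 1) abort("fc_cut must be >= 1")
  q <- bh_fdr(results$p_value)
  lfc_cut <- log2(fc_cut)
  direction <- dplyr::case_when(
    is.na(q) ~ "ns",
    results$log2fc >= lfc_cut & q < q_cut ~ "up",
    results$log2fc <= -lfc_cut & q < q_cut ~ "down",
    TRUE ~ "ns"
  )
  tab <- mutate(results, q_value = q, direction = direction)
  structure(list(table = tab, fc_cut = fc_cut, q_cut = q_cut),
            class = "lnc_de")
}

#' @export
print.lnc_de <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("DE calls: %d features, %d up / %d down (|FC| >= %g, q < %g)\n",
              g$n, g$n_up, g$n_down, x$fc_cut, x$q_cut))
  print(x$table, n = 5)
  invisible(x)
}

#' Features called in a given direction
#'
#' @param x An `lnc_de` object.
#' @param direction `"up"`, `"down"` or `"any"` (up or down).
#' @return Character vector of feature ids.
#' @export
de_features <- function(x, direction = c("any", "up", "down")) {
  stopifnot(inherits(x, "lnc_de"))
  direction <- match.arg(direction)
  tab <- x$table
  if (direction == "any") tab$feature_id[tab$direction %in% c("up", "down")]
  else tab$feature_id[tab$direction == direction]
}
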