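#' Read a GMT-style gene-set file
#'
#' One term per line: term id, description, then tab-separated member gene
#' ids.
#'
#' @param path Path to the GMT file.
#' @return A tibble: `term_id`, `name`, `genes` (list column of character
#'   vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    term_id = vapply(parts, `[`, character(1), 1),
    name = vapply(parts, `[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write a GMT-style gene-set file
#'
#' @param terms Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(seq_len(nrow(terms)), function(i) {
    paste(c(terms$term_id[i], terms$name[i], terms$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the query set over-represents the term's
#' genes relative to the background: with `N` background genes, `K` of them
#' in the term, and `n` drawn into the query, the p-value is the upper tail
#' \eqn{P(X \ge k)} of the hypergeometric distribution. Terms are
#' intersected with the background before testing; terms left empty are
#' skipped with a notice. BH q-values are computed across the tested terms.
#'
#' @param query Character vector of gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of background gene ids (typically all
#'   features tested for differential expression).
#' @param terms Gene-set tibble (`term_id`, `name`, `genes` list column),
#'   e.g. from [read_gmt()].
#' @return An object of class `lnc_enrichment` wrapping a tibble:
#'   `term_id`, `name`, `k` (hits in query), `K` (term size in background),
#'   `n` (query size), `N` (background size), `rich_factor` (`k / K`),
#'   `p_value`, `q_value`. Use [tidy()] / [glance()].
#' @export
hypergeom_enrich <- function(query, background, terms) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  offenders <- setdiff(query, background)
  if (length(offenders)) {
    abort(paste0("query genes absent from background: ",
                 paste(head(offenders, 10), collapse = ", ")))
  }
  terms <- as_tibble(terms)
  N <- length(background); n <- length(query)
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- intersect(terms$genes[[i]], background)
    K <- length(tg)
    if (K == 0) {
      inform(sprintf("term '%s' has no genes in the background; skipped",
                     terms$term_id[i]))
      return(NULL)
    }
    k <- length(intersect(query, tg))
    tibble(term_id = terms$term_id[i], name = terms$name[i],
           k = k, K = K, n = n, N = N,
           rich_factor = k / K,
           p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  tab <- bind_rows(rows)
  if (nrow(tab) > 0) tab$q_value <- bh_fdr(tab$p_value)
  structure(list(table = tab, n_query = n, n_background = N),
            class = "lnc_enrichment")
}

#' @export
print.lnc_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment: %d terms tested, query %d / background %d\n",
              nrow(x$table), x$n_query, x$n_background))
  print(x$table, n = 5)
  invisible(x)
}

#' Top enriched terms
#'
#' Stable selection of the `k` most significant terms (sorted by p-value,
#' ties broken by term id), with the columns behind the usual enrichment
#' scatter plot.
#'
#' @param results An `lnc_enrichment` object or its table.
#' @param k Number of terms to keep (default 20); fewer are returned when
#'   fewer were tested.
#' @return A tibble: `term_id`, `name`, `rich_factor`, `k`, `p_value`,
#'   `q_value`, ranked.
#' @export
top_terms <- function(results, k = 20) {
  tab <- if (inherits(results, "lnc_enrichment")) results$table else as_tibble(results)
  tab %>%
    arrange(.data$p_value, .data$term_id) %>%
    slice_head(n = k) %>%
    select("term_id", "name", "rich_factor", k = "k", "p_value", "q_value")
}
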