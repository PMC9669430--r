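#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DE-call object
#'
#' @param x An `lnc_de` object from [call_de()].
#' @param ... Unused.
#' @return The per-feature tibble with `log2fc`, `p_value`, `q_value` and
#'   `direction`.
#' @method tidy lnc_de
#' @export
tidy.lnc_de <- function(x, ...) x$table

#' One-row summary of a DE-call object
#'
#' @inheritParams tidy.lnc_de
#' @return A tibble: `n`, `n_up`, `n_down`, `n_ns`, `fc_cut`, `q_cut`.
#' @method glance lnc_de
#' @export
glance.lnc_de <- function(x, ...) {
  d <- x$table$direction
  tibble(n = length(d), n_up = sum(d == "up"), n_down = sum(d == "down"),
         n_ns = sum(d == "ns"), fc_cut = x$fc_cut, q_cut = x$q_cut)
}

#' Tidy an enrichment object
#'
#' @param x An `lnc_enrichment` object from [hypergeom_enrich()].
#' @param ... Unused.
#' @return The per-term tibble.
#' @method tidy lnc_enrichment
#' @export
tidy.lnc_enrichment <- function(x, ...) x$table

#' One-row summary of an enrichment object
#'
#' @inheritParams tidy.lnc_enrichment
#' @return A tibble: `n_terms`, `n_query`, `n_background`,
#'   `n_significant` (q < 0.05).
#' @method glance lnc_enrichment
#' @export
glance.lnc_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x$table), n_query = x$n_query,
         n_background = x$n_background,
         n_significant = if (nrow(x$table)) sum(x$table$q_value < 0.05) else 0L)
}
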