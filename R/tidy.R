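# broom-style verbs for the package's result types.

#' @rdname ppiscreen-tidiers
#' @param x A `ppi_enrichment`, `ppi_domain_pairs`,
#'   `ppi_interactome_summary` or `ppi_validation_summary` object.
#' @param ... Unused, for generic consistency.
#' @return `tidy()` returns the underlying result as a plain tibble;
#'   `glance()` returns a one-row tibble of summary statistics.
#' @export
tidy.ppi_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname ppiscreen-tidiers
#' @export
glance.ppi_enrichment <- function(x, ...) {
  tibble::tibble(
    namespace = attr(x, "namespace") %||% NA_character_,
    background = attr(x, "background") %||% NA_character_,
    n_query = attr(x, "n_query") %||% NA_integer_,
    n_terms_tested = nrow(x),
    n_significant = sum(x$p_adj < 0.05),
    min_p_adj = if (nrow(x) == 0) NA_real_ else min(x$p_adj)
  )
}

#' @rdname ppiscreen-tidiers
#' @export
tidy.ppi_domain_pairs <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname ppiscreen-tidiers
#' @export
glance.ppi_domain_pairs <- function(x, ...) {
  tibble::tibble(
    n_pairs_tested = nrow(x),
    n_significant = sum(x$p_adj < 0.05),
    min_p_adj = if (nrow(x) == 0) NA_real_ else min(x$p_adj),
    m_total = sum(x$m_observed)
  )
}

#' Tidiers for screen results
#'
#' [generics::tidy()] strips result classes back to plain tibbles;
#' [generics::glance()] condenses a result to one row of headline numbers
#' (terms tested, significant at 0.05, minimum adjusted p, ...).
#'
#' @name ppiscreen-tidiers
#' @export
tidy.ppi_validation_summary <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname ppiscreen-tidiers
#' @export
glance.ppi_interactome_summary <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname ppiscreen-tidiers
#' @export
glance.ppi_world <- function(x, ...) {
  tibble::tibble(
    seed = x$config$seed,
    n_proteins = nrow(x$proteins),
    n_baits = x$config$n_baits,
    n_raw_hits = nrow(x$screen),
    n_contaminant_preys = length(x$truth$contaminant_preys),
    n_duplicates = x$truth$n_duplicates
  )
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("ppi_enrichment", "ppi_domain_pairs",
                                  "ppi_interactome_summary",
                                  "ppi_validation_summary",
                                  "ppi_annotations", "ppi_gene_sets",
                                  "ppi_domain_sets",
                                  "ppi_validation_outcomes"))
  x
}
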