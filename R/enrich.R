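# The enrichment engine: exact hypergeometric upper tails,
# Benjamini-Hochberg adjustment, and term/category over-representation
# against configurable background populations.

#' Inclusive upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` annotated members in a sample of
#' `n` drawn without replacement from a population of `N` containing `K`
#' annotated members: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.  This
#' inclusive tail is the standard over-representation p-value.  Computed in
#' the log domain, exact and stable for populations well beyond 1e5.
#' Vectorized over all four arguments.
#'
#' @param N Population size.
#' @param K Annotated (success) count in the population.
#' @param n Sample size.
#' @param k Observed annotated count in the sample.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 3) # 66/252
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  check_count <- function(x, name) {
    if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
      abort(sprintf("argument '%s' must be a non-negative integer", name),
            class = "ppiscreen_domain_error")
    }
  }
  check_count(N, "N"); check_count(K, "K"); check_count(n, "n"); check_count(k, "k")
  if (any(K > N)) abort("argument 'K' exceeds population size N", class = "ppiscreen_domain_error")
  if (any(n > N)) abort("argument 'n' exceeds population size N", class = "ppiscreen_domain_error")
  if (any(k > pmin(n, K))) {
    abort("argument 'k' exceeds min(n, K)", class = "ppiscreen_domain_error")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: with `m` p-values
#' sorted ascending, `adj_(i) = min_(j >= i)(p_(j) * m / j)` capped at 1,
#' returned in the input's original order.  Stable under ties.
#'
#' @param p_values Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "ppiscreen_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Describe a background population for enrichment
#'
#' A single-category hypergeometric test needs the background population
#' size `N` and, per term, the number `K` of background members carrying the
#' term.  For genome-wide backgrounds where only the total size is known
#' (e.g. "human protein-coding genes, 19,008"), the per-term counts come
#' from a full annotation export via [background_from_annotations()].
#'
#' @param population_size Background population size `N`.
#' @param annotated Named integer vector mapping term id to `K`.
#' @param label Human-readable description of the background.
#' @return A list of class `ppi_background`.
#' @export
background_spec <- function(population_size, annotated, label = "custom") {
  population_size <- as.integer(population_size)
  if (is.na(population_size) || population_size <= 0) {
    abort("population_size must be a positive integer", class = "ppiscreen_domain_error")
  }
  annotated <- setNames(as.integer(annotated), names(annotated))
  if (any(annotated <= 0) || any(annotated > population_size)) {
    abort("every per-term background count K must satisfy 0 < K <= N",
          class = "ppiscreen_domain_error")
  }
  structure(list(population_size = population_size, annotated = annotated,
                 label = label),
            class = "ppi_background")
}

#' Background from a full annotation export
#'
#' Counts each term's carriers in an annotation table that covers the whole
#' background population.  `population_size` may exceed the number of
#' annotated proteins (unannotated background members carry no term).
#'
#' @param annotations `ppi_annotations` covering the background.
#' @param population_size Background size `N`; defaults to the number of
#'   distinct proteins in `annotations`.
#' @param label Background description.
#' @return A `ppi_background`.
#' @export
background_from_annotations <- function(annotations, population_size = NULL,
                                        label = NULL) {
  counts <- table(annotations$term_id)
  n_prot <- length(unique(annotations$protein_id))
  population_size <- population_size %||% n_prot
  if (population_size < n_prot) {
    abort("population_size is smaller than the number of annotated proteins",
          class = "ppiscreen_domain_error")
  }
  background_spec(population_size, setNames(as.integer(counts), names(counts)),
                  label %||% sprintf("annotation export (%d proteins)", n_prot))
}

new_enrichment <- function(df, namespace, background_label, n_query) {
  class(df) <- c("ppi_enrichment", class(df))
  attr(df, "namespace") <- namespace
  attr(df, "background") <- background_label
  attr(df, "n_query") <- n_query
  df
}

#' Term over-representation in a query set
#'
#' Tests every term annotated on at least one query protein (and carried by
#' at least `min_K` background members) with the inclusive upper-tail
#' hypergeometric p-value, then adjusts over exactly that tested family with
#' Benjamini-Hochberg.  The reported `fraction` is `k / n_query` with the
#' query size counting unannotated query members, matching the "% of preys"
#' convention of screen reports.
#'
#' @param query Character vector of protein accessions (deduplicated and
#'   normalized internally).
#' @param annotations `ppi_annotations` for the tested namespace.
#' @param background A `ppi_background` covering every tested term.
#' @param min_K Minimum background carrier count for a term to enter the
#'   tested family (use 10 to mirror the common GO `nodeSize = 10` preset).
#' @return A tibble of class `ppi_enrichment`, sorted by
#'   (`p_adj`, `p_raw`, `term_id`), with columns `term_id`, `term_name`,
#'   `k`, `n_query`, `K`, `N`, `fraction`, `p_raw`, `p_adj`.
#' @export
enrich_terms <- function(query, annotations, background, min_K = 1L) {
  query <- unique(normalize_protein_id(query))
  query <- query[query != ""]
  if (length(query) == 0) {
    abort("query set is empty", class = "ppiscreen_domain_error")
  }
  n_query <- length(query)
  N <- background$population_size
  hits <- annotations |>
    dplyr::filter(.data$protein_id %in% query) |>
    dplyr::count(.data$term_id, .data$term_name, name = "k")
  if (nrow(hits) > 0) {
    K <- unname(background$annotated[hits$term_id])
    if (anyNA(K)) {
      abort(sprintf("term %s observed in query but absent from the background",
                    hits$term_id[which(is.na(K))[1]]),
            class = "ppiscreen_inconsistency_error")
    }
    if (any(hits$k > K)) {
      abort(sprintf("term %s has more query carriers than background carriers",
                    hits$term_id[which(hits$k > K)[1]]),
            class = "ppiscreen_inconsistency_error")
    }
    hits$K <- K
    hits <- hits[hits$K >= min_K & hits$k >= 1, , drop = FALSE]
  } else {
    hits$K <- integer()
  }
  out <- hits |>
    dplyr::mutate(
      n_query = n_query,
      N = N,
      fraction = .data$k / n_query,
      p_raw = hypergeom_upper_tail(N, .data$K, n_query, .data$k)
    )
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out |>
    dplyr::select("term_id", "term_name", "k", "n_query", "K", "N",
                  "fraction", "p_raw", "p_adj") |>
    dplyr::arrange(.data$p_adj, .data$p_raw, .data$term_id)
  new_enrichment(out, attr(annotations, "namespace") %||% "annotation",
                 background$label, n_query)
}

#' Drug-target over-representation among baits
#'
#' Single-category test: are the screen's baits over-represented among known
#' drug targets, relative to the genome?  `N` is the genome size, `K` the
#' number of drug targets, `n` the number of baits, `k` the number of baits
#' that are drug targets.  With a single test the adjusted p-value equals
#' the raw one.
#'
#' @param baits Character vector of bait accessions.
#' @param target_set Character vector of drug-target accessions.
#' @param genome_size Background population size (protein-coding genes).
#' @return A one-row `ppi_enrichment` tibble.
#' @export
enrich_drug_targets <- function(baits, target_set, genome_size) {
  baits <- unique(normalize_protein_id(baits))
  baits <- baits[baits != ""]
  if (length(baits) == 0) abort("bait set is empty", class = "ppiscreen_domain_error")
  target_set <- unique(normalize_protein_id(target_set))
  K <- length(target_set)
  k <- length(intersect(baits, target_set))
  n <- length(baits)
  p <- hypergeom_upper_tail(genome_size, K, n, k)
  out <- tibble::tibble(
    term_id = "drug_target", term_name = "drug target",
    k = k, n_query = n, K = K, N = as.integer(genome_size),
    fraction = k / n, p_raw = p, p_adj = p
  )
  new_enrichment(out, "drug_target", sprintf("genome (%d)", genome_size), n)
}

#' Therapeutic-category over-representation
#'
#' Per-category hypergeometric tests for the interactome's proteins (baits
#' plus preys) against a genome background, Benjamini-Hochberg adjusted over
#' all tested categories.
#'
#' @param query Baits and preys of the final interactome.
#' @param category_table `ppi_annotations` mapping proteins to therapeutic
#'   categories (a genome-wide export).
#' @param genome_size Background population size.
#' @param min_K Minimum category size to test.
#' @return A `ppi_enrichment` tibble, one row per tested category.
#' @export
enrich_drug_categories <- function(query, category_table, genome_size,
                                   min_K = 1L) {
  background <- background_from_annotations(category_table, genome_size,
                                            sprintf("genome (%d)", genome_size))
  enrich_terms(query, category_table, background, min_K = min_K)
}
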