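# From raw hit table to the final "unique interactome": deduplication,
# contaminant-prey removal, known-interaction flagging, membrane annotation,
# and the summary counts.

#' Configuration of the screen filter
#'
#' The defaults encode the two contaminant classes removed computationally
#' from membrane two-hybrid screens: preys that carry out signal peptide
#' processing (`GO:0006465`) and ribosomal preys, both generic
#' translation/trafficking artifacts.  Ribosomal preys carry no single GO
#' id, so they are matched by a case-insensitive substring against term
#' names (default `"ribosom"`, hitting "ribosome", "ribosomal subunit",
#' "cytosolic ribosome", ...); an explicit accession list can be added for
#' screen-specific blacklists.  `membrane_terms` marks plasma-membrane
#' localization (default `GO:0005886`); supply the term's GO-graph
#' descendants as well if the annotation export does not propagate them.
#'
#' @param contaminant_terms Term ids whose prey carriers are removed.
#' @param contaminant_keywords Case-insensitive substrings matched against
#'   term names; carriers of a matching term are removed.
#' @param contaminant_proteins Optional explicit accession list to remove.
#' @param membrane_terms Term ids marking plasma-membrane localization.
#' @return A list of class `ppi_filter_config`.
#' @export
filter_config <- function(contaminant_terms = "GO:0006465",
                          contaminant_keywords = "ribosom",
                          contaminant_proteins = character(),
                          membrane_terms = "GO:0005886") {
  stopifnot(length(contaminant_terms) >= 1, length(contaminant_keywords) >= 1)
  structure(
    list(
      contaminant_terms = normalize_term_id(contaminant_terms),
      contaminant_keywords = tolower(trimws(contaminant_keywords)),
      contaminant_proteins = normalize_protein_id(contaminant_proteins),
      membrane_terms = normalize_term_id(membrane_terms)
    ),
    class = "ppi_filter_config"
  )
}

empty_interactions <- function() {
  tibble::tibble(bait_id = character(), prey_id = character(),
                 screen_id = character(), evidence = character())
}

#' Collapse a hit table to unique ordered bait-prey pairs
#'
#' A "unique interaction" is a distinct ordered bait-to-prey pair: the assay
#' is directional (bait construct versus prey construct), so reciprocal
#' detections, if any, remain distinct records.  Evidence flags of merged
#' duplicates are unioned and their screen ids collected (sorted,
#' `;`-joined); any extra columns keep their first value.  Output is sorted
#' by (`bait_id`, `prey_id`), which makes the operation idempotent and
#' insensitive to input order.
#'
#' @param records Interaction tibble as from [read_interactions()].
#' @return A tibble with one row per distinct ordered pair.
#' @export
deduplicate_interactions <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(empty_interactions())
  records |>
    dplyr::group_by(.data$bait_id, .data$prey_id) |>
    dplyr::summarise(
      screen_id = join_flags(list(unlist(split_flags(.data$screen_id)))),
      evidence = join_flags(list(unlist(split_flags(.data$evidence)))),
      dplyr::across(!dplyr::any_of(c("screen_id", "evidence")), dplyr::first),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bait_id, .data$prey_id)
}

contaminant_proteins <- function(annotations, config) {
  if (is.null(annotations)) {
    abort("contaminant filtering needs an annotation table covering GO terms",
          class = "ppiscreen_config_error")
  }
  name_lc <- tolower(annotations$term_name)
  by_keyword <- Reduce(`|`, lapply(config$contaminant_keywords,
                                   function(kw) grepl(kw, name_lc, fixed = TRUE)),
                       rep(FALSE, nrow(annotations)))
  flagged <- annotations$protein_id[annotations$term_id %in% config$contaminant_terms |
                                      by_keyword]
  sort(unique(c(flagged, config$contaminant_proteins)))
}

#' Remove interactions involving contaminant preys
#'
#' A record is removed if and only if its prey (never its bait: baits are
#' pre-validated constructs) carries a configured contaminant term, carries
#' a term whose name matches a contaminant keyword, or appears on the
#' explicit blacklist.  The two returned tables partition the input exactly.
#'
#' @param records Interaction tibble.
#' @param annotations `ppi_annotations` covering GO component/process terms.
#' @param config A [filter_config()].
#' @return A list with tibbles `kept` and `removed`.
#' @export
remove_contaminant_preys <- function(records, annotations,
                                     config = filter_config()) {
  bad <- contaminant_proteins(annotations, config)
  is_contaminant <- records$prey_id %in% bad
  list(kept = records[!is_contaminant, , drop = FALSE],
       removed = records[is_contaminant, , drop = FALSE])
}

#' Flag interactions already reported in a reference interactome
#'
#' Marks each record with the `known_reference` evidence flag when its
#' protein pair occurs, in either orientation, in a user-supplied reference
#' edge list (e.g. an export of a literature-curated interaction database).
#' Record count and order are unchanged.
#'
#' @param records Interaction tibble.
#' @param reference_edges Data frame whose first two columns are the protein
#'   identifiers of known interacting pairs (unordered).
#' @return The input tibble with `evidence` updated.
#' @export
flag_known_interactions <- function(records, reference_edges) {
  if (nrow(records) == 0) return(records)
  key <- function(a, b) {
    a <- normalize_protein_id(a); b <- normalize_protein_id(b)
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  }
  ref <- if (is.null(reference_edges) || nrow(reference_edges) == 0) character() else
    key(reference_edges[[1]], reference_edges[[2]])
  known <- key(records$bait_id, records$prey_id) %in% ref
  records$evidence[known] <- join_flags(
    lapply(split_flags(records$evidence[known]), c, "known_reference")
  )
  records
}

#' Annotate plasma-membrane localization
#'
#' @param proteins Character vector of accessions (or a data frame with a
#'   `protein_id` column).
#' @param annotations `ppi_annotations` with cellular-component terms.
#' @param config A [filter_config()] supplying `membrane_terms`.
#' @return Named logical vector: `TRUE` iff the protein carries at least one
#'   membrane term; proteins absent from the annotation table map to
#'   `FALSE`.
#' @export
annotate_membrane_localization <- function(proteins, annotations,
                                           config = filter_config()) {
  if (is.data.frame(proteins)) proteins <- proteins$protein_id
  proteins <- normalize_protein_id(proteins)
  carriers <- unique(annotations$protein_id[annotations$term_id %in% config$membrane_terms])
  setNames(proteins %in% carriers, proteins)
}

#' Summarize a filtered interactome
#'
#' @param records Deduplicated interaction tibble.
#' @param membrane_map Named logical vector from
#'   [annotate_membrane_localization()], or `NULL`.
#' @param n_removed_contaminant Count of contaminant records removed
#'   upstream, if known.
#' @return A one-row tibble of class `ppi_interactome_summary` with columns
#'   `n_unique_interactions`, `n_proteins`, `n_membrane_proteins`,
#'   `n_known`, `n_removed_contaminant`.
#' @export
summarize_interactome <- function(records, membrane_map = NULL,
                                  n_removed_contaminant = NA_integer_) {
  prots <- unique(c(records$bait_id, records$prey_id))
  n_mem <- if (is.null(membrane_map)) 0L else {
    sum(prots %in% names(membrane_map)[membrane_map])
  }
  out <- tibble::tibble(
    n_unique_interactions = nrow(records),
    n_proteins = length(prots),
    n_membrane_proteins = n_mem,
    n_known = sum(has_flag(records$evidence, "known_reference")),
    n_removed_contaminant = as.integer(n_removed_contaminant)
  )
  class(out) <- c("ppi_interactome_summary", class(out))
  out
}

#' Run the full screen filter
#'
#' Convenience wrapper chaining [deduplicate_interactions()],
#' [remove_contaminant_preys()], [flag_known_interactions()],
#' [annotate_membrane_localization()] and [summarize_interactome()].
#'
#' @param records Raw interaction tibble.
#' @param annotations `ppi_annotations` with GO terms.
#' @param config A [filter_config()].
#' @param reference_edges Optional reference edge list for known-interaction
#'   flagging.
#' @return List with `kept`, `removed`, `membrane` (named logical) and
#'   `summary`.
#' @export
filter_screen <- function(records, annotations, config = filter_config(),
                          reference_edges = NULL) {
  dedup <- deduplicate_interactions(records)
  split <- remove_contaminant_preys(dedup, annotations, config)
  kept <- split$kept
  if (!is.null(reference_edges)) {
    kept <- flag_known_interactions(kept, reference_edges)
  }
  membrane <- annotate_membrane_localization(
    unique(c(kept$bait_id, kept$prey_id)), annotations, config
  )
  list(
    kept = kept,
    removed = split$removed,
    membrane = membrane,
    summary = summarize_interactome(kept, membrane, nrow(split$removed))
  )
}
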