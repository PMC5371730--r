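# Two-step domain-pair enrichment: (1) partition the domain vocabulary on
# each side into co-occurrence sets (domains carried by exactly the same
# proteins within the side's universe are tested as a unit, avoiding
# redundant results and non-independent tests); (2) score every
# (bait-set, prey-set) pair with a four-parameter hypergeometric over the
# space of possible bait-involving interactions.

#' Partition domains into co-occurrence sets
#'
#' Within a protein universe, two domains belong to the same set if and only
#' if their carrier sets (restricted to the universe) are identical; a
#' domain that never co-occurs with another forms a set of length 1.  The
#' result is a true partition of the domain vocabulary annotated on the
#' universe.  Sets are ordered, and identified, by their smallest member
#' domain id, so output is deterministic.
#'
#' @param annotations `ppi_annotations` mapping proteins to domain ids.
#' @param universe Character vector of accessions defining the side (the
#'   screen's baits, or its detected preys).
#' @param side `"bait"` or `"prey"`.
#' @return A tibble of class `ppi_domain_sets` with columns `set_id`,
#'   `side`, `members` (list), `n_members`, `carriers` (list, within the
#'   universe), `n_carriers`.
#' @export
domain_cooccurrence_sets <- function(annotations, universe,
                                     side = c("bait", "prey")) {
  side <- match.arg(side)
  universe <- unique(normalize_protein_id(universe))
  if (length(universe) == 0) {
    abort("universe is empty", class = "ppiscreen_domain_error")
  }
  ann <- annotations |>
    dplyr::filter(.data$protein_id %in% universe) |>
    dplyr::distinct(.data$protein_id, .data$term_id)
  if (nrow(ann) == 0) {
    out <- tibble::tibble(set_id = character(), side = character(),
                          members = list(), n_members = integer(),
                          carriers = list(), n_carriers = integer())
    class(out) <- c("ppi_domain_sets", class(out))
    return(out)
  }
  carriers_by_domain <- lapply(split(ann$protein_id, ann$term_id), sort)
  signature <- vapply(carriers_by_domain, paste, character(1), collapse = "\r")
  groups <- split(names(carriers_by_domain), signature)
  members <- lapply(unname(groups), sort)
  ord <- order(vapply(members, `[[`, character(1), 1))
  members <- members[ord]
  carriers <- lapply(members, function(m) carriers_by_domain[[m[1]]])
  out <- tibble::tibble(
    set_id = vapply(members, `[[`, character(1), 1),
    side = side,
    members = members,
    n_members = lengths(members),
    carriers = carriers,
    n_carriers = lengths(carriers)
  )
  class(out) <- c("ppi_domain_sets", class(out))
  out
}

# protein -> set membership as a long tibble, for joining against edges
set_membership <- function(sets, col) {
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(sets), set_id = "set_id", prot = "carriers"),
    "prot"
  ) |>
    setNames(c(col, "prot"))
}

# number of proteome proteins carrying every member domain of each set
proteome_carrier_counts <- function(sets, proteome_annotations) {
  ann <- dplyr::distinct(tibble::as_tibble(proteome_annotations),
                         .data$protein_id, .data$term_id)
  carriers_by_domain <- split(ann$protein_id, ann$term_id)
  vapply(sets$members, function(m) {
    cs <- carriers_by_domain[m]
    if (any(vapply(cs, is.null, logical(1)))) return(0L)
    length(Reduce(intersect, cs))
  }, integer(1))
}

#' Count observed and possible bait-set / prey-set pairings
#'
#' For every (bait-set, prey-set) combination supported by at least one
#' detected interaction, computes the four parameters of the pair test:
#' `N_pairs` = number of possible interactions involving baits (number of
#' baits times proteome size); `M_detected` = number of detected
#' interactions; `n_possible` = (baits carrying the bait set) times
#' (proteome proteins carrying every domain of the prey set); `m_observed`
#' = detected interactions whose bait carries the bait set and whose prey
#' carries the prey set.  An interaction contributes to every combination
#' its endpoints carry; one whose prey has no domain annotation contributes
#' to no pair.
#'
#' @param interactions Deduplicated interaction tibble.
#' @param bait_sets,prey_sets `ppi_domain_sets` from
#'   [domain_cooccurrence_sets()].
#' @param proteome_annotations Domain annotations over the full proteome
#'   (used for prey-set carrier counts).
#' @param n_baits Number of baits screened.
#' @param proteome_size Size of the reference proteome.
#' @return A tibble with one row per pair (`m_observed >= 1`): `bait_set`,
#'   `prey_set`, `bait_set_members`, `prey_set_members`, `N_pairs`,
#'   `M_detected`, `n_possible`, `m_observed`.
#' @export
domain_pair_counts <- function(interactions, bait_sets, prey_sets,
                               proteome_annotations, n_baits, proteome_size) {
  N_pairs <- as.double(n_baits) * as.double(proteome_size)
  M <- nrow(interactions)
  empty <- tibble::tibble(
    bait_set = character(), prey_set = character(),
    bait_set_members = character(), prey_set_members = character(),
    N_pairs = double(), M_detected = integer(),
    n_possible = double(), m_observed = integer()
  )
  if (M == 0 || nrow(bait_sets) == 0 || nrow(prey_sets) == 0) return(empty)
  pairs <- interactions |>
    dplyr::select(prot = "bait_id", prey = "prey_id") |>
    dplyr::inner_join(set_membership(bait_sets, "bait_set"), by = "prot",
                      relationship = "many-to-many") |>
    dplyr::inner_join(set_membership(prey_sets, "prey_set") |>
                        dplyr::rename(prey = "prot"),
                      by = "prey", relationship = "many-to-many") |>
    dplyr::count(.data$bait_set, .data$prey_set, name = "m_observed")
  if (nrow(pairs) == 0) return(empty)
  bait_info <- tibble::tibble(
    bait_set = bait_sets$set_id,
    bait_set_members = vapply(bait_sets$members, paste, character(1), collapse = ";"),
    n_bait_carriers = bait_sets$n_carriers
  )
  prey_info <- tibble::tibble(
    prey_set = prey_sets$set_id,
    prey_set_members = vapply(prey_sets$members, paste, character(1), collapse = ";"),
    n_prey_carriers = proteome_carrier_counts(prey_sets, proteome_annotations)
  )
  out <- pairs |>
    dplyr::left_join(bait_info, by = "bait_set") |>
    dplyr::left_join(prey_info, by = "prey_set") |>
    dplyr::mutate(
      N_pairs = N_pairs,
      M_detected = M,
      n_possible = as.double(.data$n_bait_carriers) * as.double(.data$n_prey_carriers)
    )
  if (any(out$n_prey_carriers == 0)) {
    abort(sprintf(
      "prey set %s has observed interactions but no proteome carriers; the proteome annotation table does not cover the detected preys",
      out$prey_set[which(out$n_prey_carriers == 0)[1]]),
      class = "ppiscreen_inconsistency_error")
  }
  if (any(out$m_observed > pmin(out$M_detected, out$n_possible))) {
    abort("m_observed exceeds min(M_detected, n_possible); inconsistent inputs",
          class = "ppiscreen_inconsistency_error")
  }
  dplyr::select(out, "bait_set", "prey_set", "bait_set_members",
                "prey_set_members", "N_pairs", "M_detected", "n_possible",
                "m_observed")
}

#' Score counted domain-set pairs
#'
#' `p_raw = P(X >= m_observed)` for `X ~ Hypergeometric(N_pairs, M_detected,
#' n_possible)`; `p_adj` by Benjamini-Hochberg over all tested pairs (pairs
#' with `m_observed = 0` are never tested: they cannot be enriched and would
#' only deflate the family).  Sorted by (`p_adj`, `p_raw`, `bait_set`,
#' `prey_set`).
#'
#' @param counted Output of [domain_pair_counts()].
#' @return A tibble of class `ppi_domain_pairs` with `p_raw` and `p_adj`
#'   columns appended.
#' @export
domain_pair_enrichment <- function(counted) {
  if (nrow(counted) == 0) {
    out <- dplyr::mutate(counted, p_raw = double(), p_adj = double())
  } else {
    if (any(counted$m_observed > pmin(counted$M_detected, counted$n_possible)) ||
        any(counted$n_possible > counted$N_pairs) ||
        any(counted$M_detected > counted$N_pairs)) {
      abort("domain-pair counts violate their invariants",
            class = "ppiscreen_domain_error")
    }
    out <- counted |>
      dplyr::mutate(
        p_raw = hypergeom_upper_tail(.data$N_pairs, .data$M_detected,
                                     .data$n_possible, .data$m_observed),
        p_adj = bh_adjust(.data$p_raw)
      ) |>
      dplyr::arrange(.data$p_adj, .data$p_raw, .data$bait_set, .data$prey_set)
  }
  class(out) <- c("ppi_domain_pairs", class(out))
  out
}

#' Domain-set pair enrichment, end to end
#'
#' Builds bait-side co-occurrence sets over the baits, prey-side sets over
#' the detected preys (carrier counts for the test are taken over the full
#' proteome), counts every supported pair and scores it.
#'
#' @param interactions Deduplicated interaction tibble.
#' @param domain_annotations `ppi_annotations` of domains over the full
#'   proteome.
#' @param baits Character vector of bait accessions.
#' @param proteome_size Size of the reference proteome (a required input:
#'   it defines the space of possible interactions).
#' @param prey_universe Universe used to define prey-side co-occurrence;
#'   defaults to the distinct preys of `interactions`.
#' @return A `ppi_domain_pairs` tibble.
#' @export
enrich_domain_pairs <- function(interactions, domain_annotations, baits,
                                proteome_size, prey_universe = NULL) {
  baits <- unique(normalize_protein_id(baits))
  prey_universe <- prey_universe %||% unique(interactions$prey_id)
  bait_sets <- domain_cooccurrence_sets(domain_annotations, baits, "bait")
  if (length(prey_universe) == 0 || nrow(bait_sets) == 0) {
    return(domain_pair_enrichment(
      domain_pair_counts(interactions[0, , drop = FALSE], bait_sets,
                         bait_sets, domain_annotations,
                         length(baits), proteome_size)
    ))
  }
  prey_sets <- domain_cooccurrence_sets(domain_annotations, prey_universe, "prey")
  counted <- domain_pair_counts(interactions, bait_sets, prey_sets,
                                domain_annotations, length(baits), proteome_size)
  domain_pair_enrichment(counted)
}
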