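# Orthogonal-validation bookkeeping: per-(interaction, method) outcome rows
# in, rate table out.

#' Read an orthogonal-validation outcome table
#'
#' Tab-separated columns `bait_id`, `prey_id`, `method` (one of
#' `coip_flag`, `coip_native`, `bret`, `myth_retest`) and `outcome` (one of
#' `validated`, `not_validated`, `untestable`).  One row per
#' (interaction, method) attempt.
#'
#' @param path Path to the outcome file.
#' @return A tibble of class `ppi_validation_outcomes`.
#' @export
read_validation_outcomes <- function(path) {
  df <- read_tsv_strict(path, c("bait_id", "prey_id", "method", "outcome"),
                        "validation outcome")
  df$bait_id <- normalize_protein_id(df$bait_id)
  df$prey_id <- normalize_protein_id(df$prey_id)
  df$method <- trimws(df$method)
  df$outcome <- trimws(df$outcome)
  bad_m <- setdiff(unique(df$method), validation_methods())
  if (length(bad_m) > 0) {
    abort(sprintf("unknown validation method(s): %s", paste(bad_m, collapse = ", ")),
          class = "ppiscreen_schema_error")
  }
  bad_o <- setdiff(unique(df$outcome), validation_outcomes())
  if (length(bad_o) > 0) {
    abort(sprintf("unknown validation outcome(s): %s", paste(bad_o, collapse = ", ")),
          class = "ppiscreen_schema_error")
  }
  class(df) <- c("ppi_validation_outcomes", class(df))
  df
}

#' Validation-rate summary
#'
#' Computes, for the whole outcome table and for each method (plus any
#' user-defined scope grouping several methods, e.g. the two
#' co-immunoprecipitation variants), the number of interactions tested, the
#' number validated, and the success rate as a percentage rounded to one
#' decimal.  An interaction counts as validated in a scope if at least one
#' of the scope's methods validated it; `untestable` attempts are excluded
#' from both numerator and denominator.
#'
#' @param outcomes Tibble as from [read_validation_outcomes()].
#' @param scopes Named list of method groups reported as additional rows;
#'   the default adds a `coip` scope covering both co-IP variants.
#' @return A tibble of class `ppi_validation_summary` with columns `scope`,
#'   `n_tested`, `n_validated`, `rate` (percent, one decimal; `NA` when
#'   nothing was testable).
#' @export
validation_summary <- function(outcomes,
                               scopes = list(coip = c("coip_flag", "coip_native"))) {
  key <- paste(outcomes$bait_id, outcomes$prey_id, sep = "\r")
  dup <- duplicated(paste(key, outcomes$method, sep = "\r"))
  if (any(dup)) {
    abort(sprintf("duplicate (interaction, method) row(s), first at row %d",
                  which(dup)[1]),
          class = "ppiscreen_row_error")
  }
  testable <- outcomes$outcome != "untestable"
  one_scope <- function(scope, methods) {
    sel <- testable & outcomes$method %in% methods
    keys <- unique(key[sel])
    validated <- unique(key[sel & outcomes$outcome == "validated"])
    tibble::tibble(
      scope = scope,
      n_tested = length(keys),
      n_validated = length(validated),
      rate = if (length(keys) == 0) NA_real_ else
        round(100 * length(validated) / length(keys), 1)
    )
  }
  rows <- dplyr::bind_rows(
    one_scope("overall", validation_methods()),
    dplyr::bind_rows(lapply(sort(unique(outcomes$method)),
                            function(m) one_scope(m, m))),
    dplyr::bind_rows(purrr::imap(scopes, function(methods, nm) one_scope(nm, methods)))
  )
  class(rows) <- c("ppi_validation_summary", class(rows))
  rows
}
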