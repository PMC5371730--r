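#' Normalize protein identifiers
#'
#' Screens and annotation exports mix gene symbols and database accessions.
#' A single normalization rule is applied everywhere before tables are
#' joined, so that `adora2a `, `ADORA2A` and `Adora2a` all address the same
#' protein: surrounding whitespace is stripped and the identifier is
#' upper-cased.  Gene symbols and UniProt-style accessions are written in
#' upper case already, so the rule is the identity on well-formed input and
#' is idempotent by construction.
#'
#' @param x Character vector of protein identifiers.
#' @return Character vector of the same length, normalized.
#' @examples
#' normalize_protein_id(c(" adora2a", "GPR37 "))
#' @export
normalize_protein_id <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Normalize term identifiers
#'
#' Term identifiers (GO accessions such as `GO:0006465`, InterPro domains
#' such as `IPR017452`, disease or drug-category codes) are case-sensitive
#' database accessions and are left untouched apart from whitespace
#' stripping.  Idempotent.
#'
#' @param x Character vector of term identifiers.
#' @return Character vector of the same length, normalized.
#' @export
normalize_term_id <- function(x) {
  trimws(as.character(x))
}
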