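# Readers and writers for the tab-separated tables the pipeline exchanges.
# All files are UTF-8, tab-separated, with a header row; lines starting with
# "#" are comments.  Unknown extra columns are preserved on read and ignored
# by downstream computation.

read_tsv_strict <- function(path, required, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path), class = "ppiscreen_io_error")
  }
  df <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    show_col_types = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(
      sprintf(
        "%s file %s has %d malformed row(s); first at line %d (%s)",
        what, path, nrow(probs), probs$row[1], probs$expected[1]
      ),
      class = "ppiscreen_parse_error"
    )
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("%s file %s is missing mandatory column(s): %s",
              what, path, paste(missing, collapse = ", ")),
      class = "ppiscreen_schema_error"
    )
  }
  df
}

# ";"-joined flag sets: parse, validate against a vocabulary, and re-join in
# sorted order so equal sets have equal string representations.
split_flags <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, "[;,]")
}

join_flags <- function(flags) {
  vapply(flags, function(f) {
    f <- sort(unique(trimws(f)))
    paste(f[f != ""], collapse = ";")
  }, character(1))
}

normalize_evidence <- function(x, where = "evidence") {
  flags <- split_flags(x)
  bad <- setdiff(trimws(unlist(flags)), c("", evidence_vocabulary()))
  if (length(bad) > 0) {
    abort(sprintf("unknown %s flag(s): %s", where, paste(unique(bad), collapse = ", ")),
          class = "ppiscreen_schema_error")
  }
  join_flags(flags)
}

has_flag <- function(x, flag) {
  vapply(split_flags(x), function(f) flag %in% trimws(f), logical(1))
}

#' Read a bait-prey interaction table
#'
#' Reads a tab-separated hit table as produced by a two-hybrid screen.  The
#' file must name at least the columns `bait_id` and `prey_id`; optional
#' `screen_id` (originating screen or replicate) and `evidence`
#' (`;`-separated flags from `myth`, `known_reference`, `validated_coip`,
#' `validated_bret`) columns are carried along, and any further columns are
#' preserved untouched.  Identifiers are normalized with
#' [normalize_protein_id()]; row order is preserved and duplicated rows are
#' kept (deduplication is a separate, explicit stage).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with one row per data row of the file: columns
#'   `bait_id`, `prey_id`, `screen_id`, `evidence`, then any extra columns.
#' @seealso [deduplicate_interactions()], [write_table()]
#' @export
read_interactions <- function(path) {
  df <- read_tsv_strict(path, c("bait_id", "prey_id"), "interaction")
  df$bait_id <- normalize_protein_id(df$bait_id)
  df$prey_id <- normalize_protein_id(df$prey_id)
  bad <- which(df$bait_id == "" | df$prey_id == "" |
                 is.na(df$bait_id) | is.na(df$prey_id))
  if (length(bad) > 0) {
    abort(
      sprintf("empty bait_id or prey_id in data row(s): %s",
              paste(head(bad, 5), collapse = ", ")),
      class = "ppiscreen_row_error"
    )
  }
  if (!"screen_id" %in% names(df)) df$screen_id <- ""
  df$screen_id <- ifelse(is.na(df$screen_id), "", trimws(df$screen_id))
  if (!"evidence" %in% names(df)) df$evidence <- "myth"
  df$evidence <- normalize_evidence(df$evidence)
  dplyr::relocate(df, "bait_id", "prey_id", "screen_id", "evidence")
}

#' Build an annotation table in memory
#'
#' The in-memory representation of a protein-to-term annotation namespace is
#' a long tibble with columns `protein_id`, `term_id`, `term_name` and a
#' `namespace` attribute.  Rows are deduplicated on (protein, term); a term's
#' name is taken from its first non-missing occurrence (and defaults to the
#' term id) so every term has exactly one name.
#'
#' @param protein_id,term_id,term_name Character vectors (recycled to a
#'   common length); `term_name` may be `NULL` or `NA` to default to the id.
#' @param namespace Single string labelling the namespace, e.g. `"go_cc"`,
#'   `"interpro"`, `"disease"`, `"drug_category"`.
#' @return A tibble of class `ppi_annotations`.
#' @export
annotation_table <- function(protein_id, term_id, term_name = NULL,
                             namespace = "annotation") {
  protein_id <- normalize_protein_id(protein_id)
  term_id <- normalize_term_id(term_id)
  if (is.null(term_name)) term_name <- NA_character_
  df <- tibble::tibble(
    protein_id = protein_id,
    term_id = term_id,
    term_name = trimws(as.character(term_name))
  )
  # one canonical name per term: first non-missing, else the id
  names_df <- df |>
    dplyr::filter(!is.na(.data$term_name), .data$term_name != "") |>
    dplyr::distinct(.data$term_id, .keep_all = TRUE) |>
    dplyr::select("term_id", canonical = "term_name")
  df <- df |>
    dplyr::distinct(.data$protein_id, .data$term_id) |>
    dplyr::left_join(names_df, by = "term_id") |>
    dplyr::mutate(term_name = dplyr::coalesce(.data$canonical, .data$term_id)) |>
    dplyr::select("protein_id", "term_id", "term_name")
  attr(df, "namespace") <- namespace
  class(df) <- c("ppi_annotations", class(df))
  df
}

#' Read a protein-to-term annotation table
#'
#' Expects a tab-separated file with columns `protein_id`, `term_id` and an
#' optional `term_name`.  Proteins with no rows are simply absent from the
#' table; (protein, term) pairs are deduplicated.
#'
#' @param path Path to the annotation file.
#' @param namespace Label for the namespace the file annotates.
#' @return A tibble of class `ppi_annotations` (see [annotation_table()]).
#' @export
read_annotations <- function(path, namespace = "annotation") {
  df <- read_tsv_strict(path, c("protein_id", "term_id"), "annotation")
  bad <- which(is.na(df$protein_id) | is.na(df$term_id) |
                 trimws(df$protein_id) == "" | trimws(df$term_id) == "")
  if (length(bad) > 0) {
    abort(sprintf("malformed annotation row(s) (missing field): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "ppiscreen_row_error")
  }
  annotation_table(
    df$protein_id, df$term_id,
    if ("term_name" %in% names(df)) df$term_name else NULL,
    namespace = namespace
  )
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.  Duplicate members
#' within a line are collapsed; duplicate set names across lines are an
#' error because the collection would be ambiguous.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble of class `ppi_gene_sets` with columns `set_name`,
#'   `description`, `members` (list of character vectors), `n_members`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("gene-set file not found: %s", path), class = "ppiscreen_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", keep[which(short)[1]]),
          class = "ppiscreen_parse_error")
  }
  set_name <- trimws(vapply(fields, `[[`, character(1), 1))
  if (any(set_name == "")) {
    abort(sprintf("GMT line %d has an empty set name", keep[which(set_name == "")[1]]),
          class = "ppiscreen_parse_error")
  }
  if (anyDuplicated(set_name)) {
    abort(sprintf("duplicate gene-set name: %s",
                  set_name[duplicated(set_name)][1]),
          class = "ppiscreen_parse_error")
  }
  members <- lapply(fields, function(f) {
    m <- normalize_protein_id(f[-(1:2)])
    sort(unique(m[m != ""]))
  })
  out <- tibble::tibble(
    set_name = set_name,
    description = vapply(fields, `[[`, character(1), 2),
    members = members,
    n_members = lengths(members)
  )
  class(out) <- c("ppi_gene_sets", class(out))
  out
}

#' Flatten a gene-set collection to an annotation table
#'
#' Lets GMT collections (a pathway stand-in) flow through the same
#' enrichment engine as any other namespace: each set becomes a term whose
#' carriers are its members.
#'
#' @param gene_sets A `ppi_gene_sets` tibble from [read_gene_sets()].
#' @param namespace Namespace label for the resulting table.
#' @return A `ppi_annotations` tibble.
#' @export
gene_sets_as_annotations <- function(gene_sets, namespace = "gene_set") {
  long <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(gene_sets), "set_name", "description", "members"),
    "members"
  )
  annotation_table(long$members, long$set_name, long$description, namespace = namespace)
}

#' Write a result table deterministically
#'
#' Writes a tibble as a UTF-8, tab-separated file with a header, columns in
#' the requested order, and `\n` line endings.  P-value-like columns (names
#' starting `p_` or `q_`) are rendered in scientific notation with 11
#' significant digits; other numeric columns use R's full default precision;
#' list columns are `;`-joined.  Output is byte-identical across runs for
#' identical input, which makes run manifests and determinism checks
#' meaningful.
#'
#' @param x Data frame of records to write.
#' @param path Output file path.
#' @param columns Ordered character vector of columns to write (the schema);
#'   defaults to all columns of `x`.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path, columns = names(x)) {
  missing <- setdiff(columns, names(x))
  if (length(missing) > 0) {
    abort(sprintf("record set is missing schema column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "ppiscreen_schema_error")
  }
  x <- as.data.frame(x)[, columns, drop = FALSE]
  cells <- lapply(columns, function(col) {
    v <- x[[col]]
    if (is.list(v)) {
      v <- vapply(v, function(e) paste(sort(unique(as.character(e))), collapse = ";"),
                  character(1))
    }
    if (anyNA(v)) {
      abort(sprintf("missing value in column '%s' at record %d",
                    col, which(is.na(v))[1]),
            class = "ppiscreen_row_error")
    }
    if (is.numeric(v)) {
      if (grepl("^[pq]_", col)) sprintf("%.10e", v)
      else if (is.integer(v) || all(v == round(v))) format(v, scientific = FALSE, trim = TRUE)
      else as.character(v)
    } else {
      as.character(v)
    }
  })
  lines <- c(
    paste(columns, collapse = "\t"),
    if (nrow(x) > 0) do.call(paste, c(cells, sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
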