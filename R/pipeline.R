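# Orchestration: one declarative config, a fixed stage order, deterministic
# table outputs, and a machine-readable manifest with per-file row counts
# and content digests.

#' Declarative pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed forwarded to the synthetic generator.
#' @param synthetic A [synthetic_config()] describing the simulated screen;
#'   its own seed is overridden by `seed`.
#' @param filter A [filter_config()].
#' @param reference_edges Optional known-interaction edge list (data frame,
#'   first two columns protein ids).
#' @param min_K Minimum background carrier count for enrichment.
#' @param stages Named logical vector toggling the `filter`, `enrich` and
#'   `domain_pairs` stages.
#' @return A list of class `ppi_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            filter = filter_config(),
                            reference_edges = NULL,
                            min_K = 1L,
                            stages = c(filter = TRUE, enrich = TRUE,
                                       domain_pairs = TRUE)) {
  synthetic$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), synthetic = synthetic,
         filter = filter, reference_edges = reference_edges,
         min_K = as.integer(min_K),
         stages = stages),
    class = "ppi_pipeline_config"
  )
}

stage_on <- function(config, stage) {
  isTRUE(config$stages[[stage]])
}

#' Run the full synthetic-screen pipeline
#'
#' Simulates a screen, filters it, runs prey-category enrichment and
#' domain-set pair enrichment, and writes every result table plus a
#' manifest (`manifest.tsv`: file, row count, md5 digest) into
#' `config$out_dir`.  Identical config and seed yield a byte-identical
#' output directory.  Any stage failure aborts with the stage name; files
#' written by the failed run are removed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the filter `summary`, the enrichment and
#'   domain-pair tables, and the `manifest`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(x, name, columns = names(x)) {
    path <- file.path(config$out_dir, name)
    write_table(x, path, columns)
    written <<- c(written, path)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "ppiscreen_stage_error")
    })
  }

  world <- run_stage("simulate", {
    w <- generate_world(config$synthetic)
    emit(w$screen, "interactions.tsv")
    emit(w$domain_annotations, "domain_annotations.tsv")
    emit(w$go_annotations, "go_annotations.tsv")
    emit(w$category_annotations, "category_annotations.tsv")
    emit(tibble::tibble(
      key = c("seed", "contaminant_preys", "planted_bait_domain",
              "planted_prey_domain", "planted_prey_category"),
      value = c(as.character(config$seed),
                paste(w$truth$contaminant_preys, collapse = ";"),
                w$truth$planted_bait_domain, w$truth$planted_prey_domain,
                w$truth$planted_prey_category)
    ), "truth.tsv")
    w
  })
  baits <- world$proteins$protein_id[seq_len(config$synthetic$n_baits)]

  filtered <- run_stage("filter", {
    dedup <- deduplicate_interactions(world$screen)
    if (stage_on(config, "filter")) {
      split <- remove_contaminant_preys(dedup, world$go_annotations, config$filter)
    } else {
      split <- list(kept = dedup, removed = dedup[0, , drop = FALSE])
    }
    kept <- split$kept
    if (!is.null(config$reference_edges)) {
      kept <- flag_known_interactions(kept, config$reference_edges)
    }
    membrane <- annotate_membrane_localization(
      unique(c(kept$bait_id, kept$prey_id)), world$go_annotations, config$filter)
    summary <- summarize_interactome(kept, membrane, nrow(split$removed))
    emit(kept, "kept.tsv")
    emit(split$removed, "removed.tsv")
    emit(summary, "summary.tsv")
    list(kept = kept, removed = split$removed, summary = summary)
  })

  enrichment <- NULL
  if (stage_on(config, "enrich")) {
    enrichment <- run_stage("enrich", {
      preys <- setdiff(unique(filtered$kept$prey_id), baits)
      bg <- background_from_annotations(world$category_annotations,
                                        config$synthetic$proteome_size,
                                        "synthetic proteome")
      enr <- enrich_terms(preys, world$category_annotations, bg,
                          min_K = config$min_K)
      emit(enr, "enrichment_disease.tsv")
      enr
    })
  }

  pairs <- NULL
  if (stage_on(config, "domain_pairs")) {
    pairs <- run_stage("domain_pairs", {
      dp <- enrich_domain_pairs(filtered$kept, world$domain_annotations,
                                baits, config$synthetic$proteome_size)
      emit(dp, "domain_pairs.tsv")
      dp
    })
  }

  manifest <- run_stage("manifest", {
    files <- sort(basename(written))
    m <- tibble::tibble(
      file = files,
      n_rows = vapply(file.path(config$out_dir, files), function(f) {
        length(readLines(f)) - 1L
      }, integer(1), USE.NAMES = FALSE),
      md5 = unname(tools::md5sum(file.path(config$out_dir, files)))
    )
    emit(m, "manifest.tsv")
    m
  })

  invisible(list(world = world, filtered = filtered, enrichment = enrichment,
                 domain_pairs = pairs, manifest = manifest))
}
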