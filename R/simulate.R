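# Seeded synthetic screens: an annotated proteome with Zipf-skewed domain
# frequencies, a raw hit table with duplicated detections and promiscuous
# contaminant preys, a planted bait-domain/prey-domain affinity, and a
# planted prey-category enrichment.  Every pipeline stage can be exercised,
# and its recovery measured against the generator's recorded truth, without
# any external download.

#' Configuration of the synthetic screen generator
#'
#' Defaults emulate a mid-size membrane two-hybrid campaign: 48 baits
#' screened against a 2,000-protein proteome, 1,500 raw hits, a tenth of
#' rows re-detected in a second replicate, ten promiscuous contaminant preys
#' (annotated with signal peptide processing `GO:0006465` or a term named
#' "cytosolic ribosome") that light up with roughly half the baits, one
#' planted domain-pair affinity at odds multiplier 20, and one planted prey
#' category carried by 30% of detected preys versus 5% of the background.
#'
#' @param seed Integer seed governing every draw.
#' @param proteome_size Number of proteins in the synthetic proteome.
#' @param n_baits Number of baits (the first `n_baits` proteome proteins).
#' @param domain_vocab Size of the domain vocabulary (`DOM001`, ...).
#' @param domains_per_protein Mean of the per-protein Poisson domain count.
#' @param domain_frequency_skew Zipf exponent of domain frequencies.
#' @param n_raw_hits Core random hit count before contaminants/duplicates.
#' @param duplicate_fraction Probability a row is re-emitted as a duplicate.
#' @param n_contaminant_preys Number of contaminant preys.
#' @param contaminant_bait_fraction Probability a contaminant prey hits each
#'   bait.
#' @param planted_bait_domain,planted_prey_domain The planted domain pair.
#' @param planted_odds_multiplier Prey-weight multiplier applied when the
#'   bait carries the planted bait domain and the prey the planted prey
#'   domain (1 = null).
#' @param planted_prey_category,planted_category_rate_in_preys,planted_category_rate_in_background
#'   The planted category term and its carrier rates among detected
#'   (non-contaminant) preys versus the rest of the proteome.
#' @param membrane_rate Fraction of the proteome annotated with the plasma
#'   membrane term `GO:0005886`.
#' @return A list of class `ppi_synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             proteome_size = 2000L,
                             n_baits = 48L,
                             domain_vocab = 150L,
                             domains_per_protein = 1.5,
                             domain_frequency_skew = 1.2,
                             n_raw_hits = 1500L,
                             duplicate_fraction = 0.1,
                             n_contaminant_preys = 10L,
                             contaminant_bait_fraction = 0.5,
                             planted_bait_domain = "DOM001",
                             planted_prey_domain = "DOM002",
                             planted_odds_multiplier = 20,
                             planted_prey_category = "DIS001",
                             planted_category_rate_in_preys = 0.3,
                             planted_category_rate_in_background = 0.05,
                             membrane_rate = 0.25) {
  cfg <- list(
    seed = as.integer(seed),
    proteome_size = as.integer(proteome_size),
    n_baits = as.integer(n_baits),
    domain_vocab = as.integer(domain_vocab),
    domains_per_protein = domains_per_protein,
    domain_frequency_skew = domain_frequency_skew,
    n_raw_hits = as.integer(n_raw_hits),
    duplicate_fraction = duplicate_fraction,
    n_contaminant_preys = as.integer(n_contaminant_preys),
    contaminant_bait_fraction = contaminant_bait_fraction,
    planted_bait_domain = planted_bait_domain,
    planted_prey_domain = planted_prey_domain,
    planted_odds_multiplier = planted_odds_multiplier,
    planted_prey_category = planted_prey_category,
    planted_category_rate_in_preys = planted_category_rate_in_preys,
    planted_category_rate_in_background = planted_category_rate_in_background,
    membrane_rate = membrane_rate
  )
  probs <- c("duplicate_fraction", "contaminant_bait_fraction",
             "planted_category_rate_in_preys",
             "planted_category_rate_in_background", "membrane_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(sprintf("%s must lie in [0, 1]", p), class = "ppiscreen_config_error")
    }
  }
  if (cfg$planted_odds_multiplier < 1) {
    abort("planted_odds_multiplier must be >= 1", class = "ppiscreen_config_error")
  }
  if (cfg$domain_vocab < 2) {
    abort("domain_vocab must be at least 2", class = "ppiscreen_config_error")
  }
  if (cfg$proteome_size <= cfg$n_baits || cfg$n_baits < 1 || cfg$n_raw_hits < 1) {
    abort("counts must be positive and proteome_size must exceed n_baits",
          class = "ppiscreen_config_error")
  }
  if (cfg$domains_per_protein < 0) {
    abort("domains_per_protein must be >= 0", class = "ppiscreen_config_error")
  }
  structure(cfg, class = "ppi_synthetic_config")
}

#' Generate an annotated synthetic world and its screen
#'
#' Draws, under a single seed and in a fixed order (proteome, domain
#' annotations, GO annotations, core screen edges, contaminant edges,
#' duplicates, category labels), everything the pipeline consumes.  The
#' planted bait domain is guaranteed on at least 3 baits and the planted
#' prey domain on at least 20 proteome proteins (the domain assignment is
#' redrawn if not).  Category labels are drawn last, conditioned on the
#' realized non-contaminant prey set, so the configured in-prey rate refers
#' to proteins the screen actually detected.  Identical (config, seed)
#' yields byte-identical output.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `ppi_world`: `proteins`, `domain_annotations`,
#'   `go_annotations`, `category_annotations`, `screen` (raw hit table),
#'   `truth` (planted parameters and realized lists), `config`.
#' @export
generate_world <- function(config = synthetic_config()) {
  if (!inherits(config, "ppi_synthetic_config")) {
    abort("config must come from synthetic_config()", class = "ppiscreen_config_error")
  }
  withr::with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(config) {
  n <- config$proteome_size
  ids <- sprintf("P%0*d", max(4L, nchar(n)), seq_len(n))
  baits <- ids[seq_len(config$n_baits)]
  dom_ids <- sprintf("DOM%03d", seq_len(config$domain_vocab))
  zipf <- (seq_len(config$domain_vocab))^(-config$domain_frequency_skew)

  # domain annotations, redrawn until the planted domains are frequent
  # enough to carry a signal (>= 3 baits / >= 20 proteome proteins)
  planted_possible <- config$domains_per_protein > 0 &&
    all(c(config$planted_bait_domain, config$planted_prey_domain) %in% dom_ids)
  for (attempt in seq_len(50L)) {
    n_dom <- rpois(n, config$domains_per_protein)
    prot_rep <- rep(ids, n_dom)
    draw <- sample(dom_ids, length(prot_rep), replace = TRUE, prob = zipf)
    dom_ann <- dplyr::distinct(tibble::tibble(protein_id = prot_rep, term_id = draw))
    if (!planted_possible) break
    n_bd <- sum(baits %in% dom_ann$protein_id[dom_ann$term_id == config$planted_bait_domain])
    n_pd <- sum(dom_ann$term_id == config$planted_prey_domain)
    if (n_bd >= 3 && n_pd >= 20) break
    if (attempt == 50L) {
      abort("could not place the planted domains after 50 attempts; configuration infeasible",
            class = "ppiscreen_config_error")
    }
  }
  domain_annotations <- annotation_table(dom_ann$protein_id, dom_ann$term_id,
                                         namespace = "domain")

  # GO annotations: contaminant preys + membrane localization
  non_baits <- ids[-seq_len(config$n_baits)]
  contaminants <- if (config$n_contaminant_preys > 0) {
    sort(sample(non_baits, config$n_contaminant_preys))
  } else character()
  ribosomal <- seq_along(contaminants) %% 2 == 0
  membrane <- ids[runif(n) < config$membrane_rate]
  go_prot <- c(contaminants, membrane)
  go_term <- c(ifelse(ribosomal, "GO:0022626", "GO:0006465"),
               rep("GO:0005886", length(membrane)))
  go_name <- c(ifelse(ribosomal, "cytosolic ribosome", "signal peptide processing"),
               rep("plasma membrane", length(membrane)))
  go_annotations <- annotation_table(go_prot, go_term, go_name, namespace = "go")

  # core screen edges: bait uniform, prey weight 1 except the planted pair
  bait_draw <- sample(baits, config$n_raw_hits, replace = TRUE)
  bait_carriers <- intersect(
    baits, dom_ann$protein_id[dom_ann$term_id == config$planted_bait_domain])
  prey_carriers <- dom_ann$protein_id[dom_ann$term_id == config$planted_prey_domain]
  prey_draw <- character(config$n_raw_hits)
  boosted <- bait_draw %in% bait_carriers & config$planted_odds_multiplier > 1
  if (any(!boosted)) {
    prey_draw[!boosted] <- sample(ids, sum(!boosted), replace = TRUE)
  }
  if (any(boosted)) {
    w <- ifelse(ids %in% prey_carriers, config$planted_odds_multiplier, 1)
    prey_draw[boosted] <- sample(ids, sum(boosted), replace = TRUE, prob = w)
  }
  core <- tibble::tibble(bait_id = bait_draw, prey_id = prey_draw,
                         screen_id = "R1", evidence = "myth")

  # promiscuous contaminant edges
  if (length(contaminants) > 0) {
    grid <- expand.grid(bait_id = baits, prey_id = contaminants,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < config$contaminant_bait_fraction
    cont <- tibble::tibble(bait_id = grid$bait_id[keep],
                           prey_id = grid$prey_id[keep],
                           screen_id = "R1", evidence = "myth")
  } else {
    cont <- core[0, , drop = FALSE]
  }
  raw <- dplyr::bind_rows(core, cont)

  # replicate re-detections
  dup_rows <- which(runif(nrow(raw)) < config$duplicate_fraction)
  dups <- raw[dup_rows, , drop = FALSE]
  dups$screen_id <- "R2"
  screen <- dplyr::bind_rows(raw, dups)

  # planted prey category, conditioned on the realized prey set
  prey_set <- setdiff(unique(core$prey_id), contaminants)
  rate <- ifelse(ids %in% prey_set,
                 config$planted_category_rate_in_preys,
                 config$planted_category_rate_in_background)
  cat_carriers <- ids[runif(n) < rate]
  category_annotations <- annotation_table(
    cat_carriers, rep(config$planted_prey_category, length(cat_carriers)),
    rep("planted prey category", length(cat_carriers)),
    namespace = "disease"
  )

  all_preys <- unique(screen$prey_id)
  proteins <- tibble::tibble(
    protein_id = ids,
    symbol = ids,
    role = dplyr::case_when(
      ids %in% baits & ids %in% all_preys ~ "both",
      ids %in% baits ~ "bait",
      ids %in% all_preys ~ "prey",
      TRUE ~ "background"
    )
  )

  dedup_keys <- function(df) {
    d <- dplyr::distinct(df, .data$bait_id, .data$prey_id)
    d <- dplyr::arrange(d, .data$bait_id, .data$prey_id)
    d
  }
  truth <- list(
    seed = config$seed,
    planted_bait_domain = config$planted_bait_domain,
    planted_prey_domain = config$planted_prey_domain,
    planted_odds_multiplier = config$planted_odds_multiplier,
    planted_bait_carriers = sort(bait_carriers),
    planted_prey_carriers = sort(unique(prey_carriers)),
    planted_edges = dedup_keys(core[core$bait_id %in% bait_carriers &
                                      core$prey_id %in% prey_carriers, ]),
    contaminant_preys = contaminants,
    contaminant_edges = dedup_keys(screen[screen$prey_id %in% contaminants, ]),
    planted_prey_category = config$planted_prey_category,
    category_carriers = sort(cat_carriers),
    prey_universe = sort(prey_set),
    n_duplicates = length(dup_rows)
  )

  structure(
    list(proteins = proteins,
         domain_annotations = domain_annotations,
         go_annotations = go_annotations,
         category_annotations = category_annotations,
         screen = screen,
         truth = truth,
         config = config),
    class = "ppi_world"
  )
}

#' Raw hit table of a synthetic world
#'
#' Returns the screen drawn for `world`.  The hit table is generated
#' together with the world (category labels are conditioned on the realized
#' prey set), so this accessor validates that `config` matches the one the
#' world was built from and returns the stored table; determinism and the
#' specified draw order are preserved.
#'
#' @param world A `ppi_world` from [generate_world()].
#' @param config The same [synthetic_config()] used to build `world`.
#' @return The raw interaction tibble (columns `bait_id`, `prey_id`,
#'   `screen_id`, `evidence`).
#' @export
generate_screen <- function(world, config = world$config) {
  if (!inherits(world, "ppi_world")) {
    abort("world must come from generate_world()", class = "ppiscreen_config_error")
  }
  if (!identical(unclass(config), unclass(world$config))) {
    abort("config does not match the one the world was generated with",
          class = "ppiscreen_config_error")
  }
  world$screen
}

#' @export
print.ppi_world <- function(x, ...) {
  cat(sprintf(
    "<ppi_world> seed %d: %d proteins (%d baits), %d raw hits, %d contaminant preys\n",
    x$config$seed, x$config$proteome_size, x$config$n_baits,
    nrow(x$screen), length(x$truth$contaminant_preys)
  ))
  invisible(x)
}
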