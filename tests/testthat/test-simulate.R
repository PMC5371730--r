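test_that("the generator is deterministic given (config, seed)", {
  cfg <- synthetic_config(seed = 17)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  saveRDS(w1, d1); saveRDS(w2, d2)
  expect_identical(unname(tools::md5sum(d1)), unname(tools::md5sum(d2)))
  unlink(c(d1, d2))
  expect_identical(generate_screen(w1), generate_screen(w2))
  # the screen accessor insists on the generating config
  other <- synthetic_config(seed = 18)
  expect_error(generate_screen(w1, other), class = "ppiscreen_config_error")
})

test_that("planted structure respects the configured rates", {
  cfg <- synthetic_config(seed = 23)
  w <- generate_world(cfg)

  # planted domains frequent enough to carry signal
  expect_gte(length(w$truth$planted_bait_carriers), 3)
  expect_gte(length(w$truth$planted_prey_carriers), 20)

  # background category carriers ~ Binomial(n_background, 0.05); check a
  # 99.9% interval around the expectation
  bg <- setdiff(w$proteins$protein_id, w$truth$prey_universe)
  n_bg <- length(bg)
  carriers_bg <- sum(w$truth$category_carriers %in% bg)
  expect_gte(carriers_bg, qbinom(0.0005, n_bg, 0.05))
  expect_lte(carriers_bg, qbinom(0.9995, n_bg, 0.05))

  # contaminant preys carry exactly the two contaminant GO classes
  cont_ann <- w$go_annotations[w$go_annotations$protein_id %in%
                                 w$truth$contaminant_preys, ]
  expect_true(all(cont_ann$term_id %in%
                    c("GO:0006465", "GO:0022626", "GO:0005886")))
  expect_true(all(c("GO:0006465", "GO:0022626") %in% cont_ann$term_id))

  # duplicate rows: recorded truth matches the table and re-materializes
  # identically from the seed; realized count sits in a 99.9% binomial band
  w_again <- generate_world(cfg)
  expect_equal(w$truth$n_duplicates, w_again$truth$n_duplicates)
  n_dup <- sum(w$screen$screen_id == "R2")
  expect_equal(n_dup, w$truth$n_duplicates)
  n_raw <- nrow(w$screen) - n_dup
  expect_gte(n_dup, qbinom(0.0005, n_raw, cfg$duplicate_fraction))
  expect_lte(n_dup, qbinom(0.9995, n_raw, cfg$duplicate_fraction))
})

test_that("contaminant preys are promiscuous relative to ordinary preys", {
  w <- generate_world(synthetic_config(seed = 31))
  dedup <- deduplicate_interactions(w$screen)
  deg <- table(dedup$prey_id)
  cont_deg <- as.numeric(deg[w$truth$contaminant_preys])
  other_deg <- as.numeric(deg[setdiff(names(deg), w$truth$contaminant_preys)])
  # ~ contaminant_bait_fraction * n_baits = 24 baits each, far above typical
  expect_gt(min(cont_deg), 10)
  expect_gt(mean(cont_deg), 5 * mean(other_deg))
})

test_that("a null configuration draws edges uniformly", {
  cfg <- synthetic_config(seed = 41, planted_odds_multiplier = 1,
                          n_contaminant_preys = 0, duplicate_fraction = 0)
  w <- generate_world(cfg)
  expect_equal(nrow(w$screen), cfg$n_raw_hits)
  # bait marginal uniform over the 48 baits
  counts <- table(factor(w$screen$bait_id,
                         levels = w$proteins$protein_id[1:48]))
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.001)
})

test_that("degenerate configurations stay well-defined", {
  cfg <- synthetic_config(seed = 5, domains_per_protein = 0,
                          proteome_size = 200, n_baits = 10, n_raw_hits = 100)
  w <- generate_world(cfg)
  expect_equal(nrow(w$domain_annotations), 0)
  dp <- enrich_domain_pairs(deduplicate_interactions(w$screen),
                            w$domain_annotations,
                            w$proteins$protein_id[1:10], 200)
  expect_equal(nrow(dp), 0)

  expect_error(synthetic_config(domain_vocab = 1),
               class = "ppiscreen_config_error")
  expect_error(synthetic_config(duplicate_fraction = 1.5),
               class = "ppiscreen_config_error")
  expect_error(synthetic_config(planted_odds_multiplier = 0.5),
               class = "ppiscreen_config_error")
})

test_that("prey-category enrichment recovers the planted signal across seeds", {
  hits <- 0L
  null_hits <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(seed = s)
    w <- generate_world(cfg)
    kept <- filter_screen(w$screen, w$go_annotations)$kept
    preys <- setdiff(unique(kept$prey_id), w$proteins$protein_id[1:cfg$n_baits])
    bg <- background_from_annotations(w$category_annotations, cfg$proteome_size)
    res <- enrich_terms(preys, w$category_annotations, bg)
    if (nrow(res) > 0 && res$term_id[1] == cfg$planted_prey_category &&
        res$p_adj[1] < 0.05) hits <- hits + 1L

    cfg0 <- synthetic_config(seed = s, planted_category_rate_in_preys = 0.05)
    w0 <- generate_world(cfg0)
    kept0 <- filter_screen(w0$screen, w0$go_annotations)$kept
    preys0 <- setdiff(unique(kept0$prey_id), w0$proteins$protein_id[1:cfg0$n_baits])
    bg0 <- background_from_annotations(w0$category_annotations, cfg0$proteome_size)
    res0 <- enrich_terms(preys0, w0$category_annotations, bg0)
    if (nrow(res0) > 0 && any(res0$p_adj < 0.05)) null_hits <- null_hits + 1L
  }
  expect_gte(hits, 95)       # planted rates: recovered in >= 95 of 100 seeds
  expect_lte(null_hits, 10)  # null rates: false alarm in <= 10 of 100 seeds
})
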