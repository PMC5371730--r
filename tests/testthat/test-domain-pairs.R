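test_that("co-occurrence sets partition domains by identical carriers", {
  # P1{d1,d2}, P2{d1,d2}, P3{d3} -> sets {d1,d2} and {d3}
  ann <- annotation_table(c("P1", "P1", "P2", "P2", "P3"),
                          c("d1", "d2", "d1", "d2", "d3"))
  sets <- domain_cooccurrence_sets(ann, c("P1", "P2", "P3"), "bait")
  expect_equal(nrow(sets), 2)
  expect_equal(sets$members[[1]], c("d1", "d2"))
  expect_equal(sets$carriers[[1]], c("P1", "P2"))
  expect_equal(sets$members[[2]], "d3")

  # every domain on a distinct protein -> all singletons
  ann2 <- annotation_table(c("P1", "P2", "P3"), c("a", "b", "c"))
  sets2 <- domain_cooccurrence_sets(ann2, c("P1", "P2", "P3"), "prey")
  expect_equal(sets2$n_members, rep(1L, 3))

  # domains outside the universe are not represented
  sets3 <- domain_cooccurrence_sets(ann, c("P1", "P2"), "bait")
  expect_false("d3" %in% unlist(sets3$members))
})

test_that("co-occurrence output is a true partition (randomized)", {
  withr::with_seed(5, {
    for (rep in 1:40) {
      fx <- random_annotation_fixture(sample(3:12, 1))
      sets <- domain_cooccurrence_sets(fx$annotations, fx$universe, "bait")
      doms <- sort(unique(fx$annotations$term_id[
        fx$annotations$protein_id %in% fx$universe]))
      got <- sort(as.character(unlist(sets$members)))
      expect_identical(got, doms)            # union covers the vocabulary
      expect_equal(anyDuplicated(got), 0)    # sets are disjoint
    }
  })
})

test_that("growing the universe only splits sets, never merges them", {
  withr::with_seed(6, {
    for (rep in 1:40) {
      fx <- random_annotation_fixture(sample(4:12, 1))
      small <- fx$universe[-length(fx$universe)]
      s_small <- domain_cooccurrence_sets(fx$annotations, small, "bait")
      s_big <- domain_cooccurrence_sets(fx$annotations, fx$universe, "bait")
      set_of <- function(sets, d) {
        idx <- which(vapply(sets$members, function(m) d %in% m, logical(1)))
        if (length(idx) == 0) NA_integer_ else idx
      }
      shared <- intersect(unlist(s_small$members), unlist(s_big$members))
      for (grp in s_big$members) {
        grp <- intersect(grp, shared)
        if (length(grp) > 1) {
          ids <- vapply(grp, function(d) set_of(s_small, d), integer(1))
          expect_equal(length(unique(ids)), 1)
        }
      }
    }
  })
})

toy_pair_world <- function() {
  # 2 baits (B1 carries bd), proteome of 10, prey domain pd on 3 proteins,
  # 4 detected edges of which 2 match (B1 -> pd carriers)
  ann <- annotation_table(
    c("B1", "P3", "P4", "P5", "B2", "P6"),
    c("bd", "pd", "pd", "pd", "other", "other2")
  )
  edges <- tibble::tibble(
    bait_id = c("B1", "B1", "B2", "B2"),
    prey_id = c("P3", "P4", "P5", "P6"),
    screen_id = "S1", evidence = "myth"
  )
  list(ann = ann, edges = edges)
}

test_that("pair counts implement the four-parameter definition", {
  tw <- toy_pair_world()
  bait_sets <- domain_cooccurrence_sets(tw$ann, c("B1", "B2"), "bait")
  prey_sets <- domain_cooccurrence_sets(tw$ann, unique(tw$edges$prey_id), "prey")
  counts <- domain_pair_counts(tw$edges, bait_sets, prey_sets, tw$ann, 2, 10)
  row <- counts[counts$bait_set_members == "bd" & counts$prey_set_members == "pd", ]
  expect_equal(row$N_pairs, 20)
  expect_equal(row$M_detected, 4)
  expect_equal(row$n_possible, 3)   # 1 bait with bd x 3 proteome proteins with pd
  expect_equal(row$m_observed, 2)

  # no interactions -> empty result
  expect_equal(nrow(domain_pair_counts(tw$edges[0, ], bait_sets, prey_sets,
                                       tw$ann, 2, 10)), 0)

  # an interaction whose prey lacks domain annotation contributes nothing
  edges2 <- dplyr::bind_rows(tw$edges,
                             tibble::tibble(bait_id = "B1", prey_id = "P9",
                                            screen_id = "S1", evidence = "myth"))
  prey_sets2 <- domain_cooccurrence_sets(tw$ann, unique(edges2$prey_id), "prey")
  counts2 <- domain_pair_counts(edges2, bait_sets, prey_sets2, tw$ann, 2, 10)
  expect_equal(sum(counts2$m_observed),
               sum(counts$m_observed) + 0)  # only M changed
  expect_equal(unique(counts2$M_detected), 5)
})

test_that("pair enrichment scores with the hypergeometric tail and BH", {
  tw <- toy_pair_world()
  res <- enrich_domain_pairs(tw$edges, tw$ann, c("B1", "B2"), 10)
  row <- res[res$bait_set_members == "bd" & res$prey_set_members == "pd", ]
  # P(X >= 2), X ~ HG(N=20, K=4, n=3) = 100/1140
  expect_equal(row$p_raw, 100 / 1140, tolerance = 1e-12)
  expect_equal(res$p_adj, bh_oracle(res$p_raw), tolerance = 1e-12)
  expect_true(!is.unsorted(res$p_adj))

  # invariant violations are rejected
  bad <- res
  bad$m_observed <- bad$n_possible + 1
  expect_error(domain_pair_enrichment(bad), class = "ppiscreen_domain_error")
})

test_that("sum identity: total m equals per-interaction set-pair multiplicity", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      cfg <- synthetic_config(seed = 100 + rep, proteome_size = 300,
                              n_baits = 12, n_raw_hits = 200,
                              domain_vocab = 40)
      w <- generate_world(cfg)
      kept <- filter_screen(w$screen, w$go_annotations)$kept
      baits <- w$proteins$protein_id[1:12]
      bait_sets <- domain_cooccurrence_sets(w$domain_annotations, baits, "bait")
      prey_sets <- domain_cooccurrence_sets(w$domain_annotations,
                                            unique(kept$prey_id), "prey")
      counts <- domain_pair_counts(kept, bait_sets, prey_sets,
                                   w$domain_annotations, 12, 300)
      n_sets_on <- function(sets, prot) {
        sum(vapply(sets$carriers, function(cs) prot %in% cs, logical(1)))
      }
      per_edge <- vapply(seq_len(nrow(kept)), function(i) {
        n_sets_on(bait_sets, kept$bait_id[i]) * n_sets_on(prey_sets, kept$prey_id[i])
      }, numeric(1))
      expect_equal(sum(counts$m_observed), sum(per_edge))
    }
  })
})
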