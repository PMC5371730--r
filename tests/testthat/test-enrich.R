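test_that("hypergeometric upper tail matches hand-derived values", {
  # k = 0 spans the whole distribution
  expect_identical(hypergeom_upper_tail(100, 30, 10, 0), 1)
  # N=10, K=4, n=5, k=3: 66/252 by exhaustive enumeration
  expect_equal(hypergeom_upper_tail(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  # combinatorial sum (C(5,4)C(15,2)+C(5,5)C(15,1))/C(20,6)
  expect_equal(hypergeom_upper_tail(20, 5, 6, 4), 540 / 38760, tolerance = 1e-12)
  # stable at population scale
  expect_gt(hypergeom_upper_tail(100000, 5000, 100, 20), 0)
})

test_that("hypergeometric tail rejects out-of-bound arguments by name", {
  expect_error(hypergeom_upper_tail(10, 11, 5, 3), "K",
               class = "ppiscreen_domain_error")
  expect_error(hypergeom_upper_tail(10, 4, 11, 3), "n",
               class = "ppiscreen_domain_error")
  expect_error(hypergeom_upper_tail(10, 4, 5, 5), "k",
               class = "ppiscreen_domain_error")
  expect_error(hypergeom_upper_tail(-1, 0, 0, 0), "N",
               class = "ppiscreen_domain_error")
})

test_that("tail is decreasing in k and symmetric in (K, n)", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      N <- sample(5:60, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      ks <- 0:min(n, K)
      tails <- hypergeom_upper_tail(N, K, n, ks)
      # below the support minimum n+K-N the tail is pinned at 1; above it
      # the tail is strictly decreasing in k
      lo <- max(0, n + K - N)
      expect_true(all(tails[ks <= lo] == 1))
      strict <- tails[ks >= lo]
      expect_true(length(strict) <= 1 || all(diff(strict) < 0))
      k <- sample(ks, 1)
      expect_equal(hypergeom_upper_tail(N, K, n, k),
                   hypergeom_upper_tail(N, n, K, k), tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "ppiscreen_domain_error")
  expect_error(bh_adjust(c(0.1, -0.1)), class = "ppiscreen_domain_error")

  withr::with_seed(21, {
    for (rep in 1:50) {
      p <- runif(sample(1:40, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
      # order-preserving on the sorted sequence
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
})

test_that("BH controls the false discovery rate in a planted-null simulation", {
  alpha <- 0.05
  withr::with_seed(42, {
    fdp <- replicate(2000, {
      p <- c(runif(40), rbeta(10, 0.05, 1))  # 40 true nulls, 10 alternatives
      discoveries <- which(bh_adjust(p) <= alpha)
      if (length(discoveries) == 0) 0 else mean(discoveries <= 40)
    })
    expect_lte(mean(fdp), alpha + 0.01)
  })
})

test_that("term enrichment computes counts, p-values and ordering", {
  ann <- annotation_table(
    c("Q1", "Q2", "Q3", "Q4", "X1", "Q1", "Q5"),
    c("A", "A", "A", "A", "A", "B", "B"),
    namespace = "demo"
  )
  bg <- background_spec(20, c(A = 5, B = 2), "toy background")
  query <- c("Q1", "Q2", "Q3", "Q4", "Q5", "Q6")
  res <- enrich_terms(query, ann, bg)
  expect_s3_class(res, "ppi_enrichment")
  a <- res[res$term_id == "A", ]
  expect_equal(a$k, 4)
  expect_equal(a$K, 5)
  expect_equal(a$n_query, 6)
  expect_equal(a$p_raw, 540 / 38760, tolerance = 1e-12)
  expect_equal(a$fraction, 4 / 6)
  expect_equal(res$p_adj, bh_oracle(res$p_raw), tolerance = 1e-12)
  expect_true(!is.unsorted(res$p_adj))

  # terms with k = 0 are not reported
  expect_false("C" %in% res$term_id)
  # min_K restricts the tested family (and the BH denominator)
  res10 <- enrich_terms(query, ann, bg, min_K = 5)
  expect_equal(res10$term_id, "A")

  # background must cover tested terms
  bad_bg <- background_spec(20, c(A = 5), "missing B")
  expect_error(enrich_terms(query, ann, bad_bg),
               class = "ppiscreen_inconsistency_error")
  # k > K is an annotation/background mismatch
  bg_small <- background_spec(20, c(A = 2, B = 2), "K too small")
  expect_error(enrich_terms(query, ann, bg_small),
               class = "ppiscreen_inconsistency_error")
})

test_that("enrichment p-values are uniform under a label-permutation null", {
  withr::with_seed(99, {
    prots <- sprintf("P%03d", 1:200)
    ann <- annotation_table(sample(prots, 400, replace = TRUE),
                            sample(sprintf("T%02d", 1:10), 400, replace = TRUE))
    bg <- background_from_annotations(ann, 200)
    pvals <- unlist(lapply(1:150, function(i) {
      q <- sample(prots, 30)
      enrich_terms(q, ann, bg)$p_raw
    }))
    # discrete p-values are super-uniform in the tail; check no inflation
    expect_gt(mean(pvals > 0.5), 0.35)
    expect_lt(mean(pvals < 0.05), 0.08)
  })
})

test_that("drug-target and drug-category enrichment parameterize correctly", {
  # toy oracle check: N=100, K=10, n=10, k=5
  baits <- sprintf("B%02d", 1:10)
  targets <- c(baits[1:5], sprintf("T%02d", 1:5))
  res <- enrich_drug_targets(baits, targets, 100)
  expect_equal(res$k, 5)
  expect_equal(res$K, 10)
  expect_equal(res$p_raw, hypergeom_enum_oracle_large(100, 10, 10, 5),
               tolerance = 1e-10)
  expect_equal(res$p_adj, res$p_raw)

  # disjoint baits and targets -> p = 1 at k = 0
  none <- enrich_drug_targets(baits, "ZZZ", 100)
  expect_equal(none$k, 0)
  expect_equal(none$p_raw, 1)

  # per-category results equal the single-category test composed per term
  cat_ann <- annotation_table(
    c("B01", "B02", "C1", "B03", "C2", "C3", "B04", "B05"),
    c("CAT1", "CAT1", "CAT1", "CAT2", "CAT2", "CAT2", "CAT3", "CAT3")
  )
  res_cat <- enrich_drug_categories(baits, cat_ann, 100)
  for (i in seq_len(nrow(res_cat))) {
    expect_equal(res_cat$p_raw[i],
                 hypergeom_upper_tail(100, res_cat$K[i], 10, res_cat$k[i]))
  }
  expect_equal(res_cat$p_adj, bh_oracle(res_cat$p_raw), tolerance = 1e-12)

  # no category intersects the query -> empty result
  empty <- enrich_drug_categories("ZZ9", cat_ann, 100)
  expect_equal(nrow(empty), 0)
})
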