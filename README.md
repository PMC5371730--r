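# ppiscreen

Post-processing and statistical annotation for membrane yeast two-hybrid
(MYTH) interaction screens.

Split-ubiquitin screens of full-length membrane baits — such as G
protein-coupled receptors (GPCRs) screened against a cDNA prey library —
produce raw hit tables riddled with duplicated detections and promiscuous
"sticky" preys. `ppiscreen` turns such a table into a unique, annotated
interactome and scores it: it deduplicates ordered bait→prey pairs, removes
contaminant preys (signal-peptide-processing proteins, `GO:0006465`, and
ribosomal proteins — generic translation/trafficking artifacts), flags
pairs already present in a reference interactome, annotates plasma-membrane
localization, and runs over-representation statistics over any annotation
namespace (GO, diseases, drug targets, therapeutic categories, GMT gene
sets) and over domain pairs. A seeded synthetic screen generator with
planted signals makes every stage testable end to end without downloads.

## The statistics

**Term over-representation.** For a query of `n` proteins against a
background of `N` proteins of which `K` carry a term, observing `k`
carriers in the query is scored with the inclusive upper tail of the
hypergeometric distribution,

    P = P(X >= k),  X ~ Hypergeometric(N, K, n),

computed exactly in the log domain. P-values are adjusted across the tested
family (terms with `k >= 1` query carriers and `K >= min_K` background
carriers) with the Benjamini–Hochberg step-up procedure.

**Domain-set pair enrichment.** Domain co-occurrence blurs which domain
drives an interaction, so domains are first partitioned, separately on
baits and on preys, into *co-occurrence sets*: domains carried by exactly
the same proteins within the side's universe are tested as one unit. Every
(bait-set, prey-set) combination supported by at least one detected
interaction is then scored with a four-parameter hypergeometric:

    N = n_baits × proteome_size      (possible bait-involving pairs)
    M = number of detected interactions
    n = (baits carrying the bait set) × (proteome proteins carrying the prey set)
    m = detected interactions whose endpoints carry both sets

    P = P(X >= m),  X ~ Hypergeometric(N, M, n),

again BH-adjusted over all tested pairs.

**Validation rates.** Per-(interaction, method) outcome tables from
orthogonal validation (co-immunoprecipitation, BRET, MYTH retest of known
pairs) are summarized as success rates; an interaction counts as validated
in a scope if at least one of the scope's methods validated it, and
untestable attempts are excluded from both numerator and denominator.

## Worked example

A synthetic screen with the default study conditions: 48 baits, a
2,000-protein proteome, 1,500 raw hits, 10 promiscuous contaminant preys,
a planted bait-domain/prey-domain affinity (`DOM001`/`DOM002`, odds ×20)
and a planted prey category (`DIS001`, 30% of preys vs 5% of background).

```r
library(ppiscreen)

cfg   <- synthetic_config(seed = 7)
world <- generate_world(cfg)
hits  <- generate_screen(world)

res <- filter_screen(hits, world$go_annotations)
res$summary
#>   n_unique_interactions n_proteins n_membrane_proteins n_known n_removed_contaminant
#> 1                  1471        988                 228       0                   225
```

The raw 1,902-row hit table collapses to 1,471 unique interactions among
988 proteins after removing every edge involving a contaminant prey (the
removed set equals the generator's truth list exactly).

```r
baits <- world$proteins$protein_id[1:48]
pairs <- enrich_domain_pairs(res$kept, world$domain_annotations, baits,
                             proteome_size = cfg$proteome_size)
head(tidy(pairs), 3)
#>   bait_set_members prey_set_members n_possible m_observed     p_adj
#> 1 DOM001           DOM002                 5586        409 4.87e-159
#> 2 DOM004           DOM002                  588         49 8.85e- 19
#> 3 DOM003           DOM002                 1470         72 4.81e- 15
```

The planted pair ranks first by adjusted P; the runners-up are correlated
pairs sharing the planted prey domain.

```r
preys <- setdiff(unique(res$kept$prey_id), baits)
bg    <- background_from_annotations(world$category_annotations,
                                     cfg$proteome_size)
enrich_terms(preys, world$category_annotations, bg)
#>   term_id  k n_query   K    N fraction    p_raw    p_adj
#> 1 DIS001 266     940 312 2000    0.283 1.74e-52 1.74e-52
```

The planted category annotates 28.3% of the 940 detected preys against
312/2,000 in the background. Validation rates from the packaged
orthogonal-validation fixture:

```r
validation_summary(read_validation_outcomes(
  system.file("extdata", "synthetic_validation_outcomes.tsv",
              package = "ppiscreen")))
#>   scope       n_tested n_validated  rate
#> 1 overall           40          28  70
#> 2 bret               8           8 100
#> 3 coip_flag         18          12  66.7
#> 4 coip_native       16          10  62.5
#> 5 coip              34          22  64.7
```

`autoplot()` methods give ggplot views of enrichment tables, domain-pair
results and validation summaries; `tidy()`/`glance()` follow broom
conventions. `run_pipeline(pipeline_config(out_dir, seed))` chains
simulate → filter → enrich → domain pairs and writes deterministic TSVs
plus a digest manifest.

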