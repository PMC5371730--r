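---
title: "Models and methods behind ppiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ppiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscreen)
```

## The problem

Membrane yeast two-hybrid (MYTH) screens detect interactions of full-length
membrane baits — prototypically G protein-coupled receptors — against a
prey library in living yeast. The raw output is a bait→prey hit table with
three systematic artifacts: the same pair detected in several replicates,
promiscuous preys that light up with many unrelated baits, and a residue of
generic "sticky" protein classes (signal-peptide-processing machinery,
ribosomal proteins) known to bind non-specifically during translation and
trafficking. `ppiscreen` implements the computational half of screen
refinement — deduplication, contaminant filtering, reference flagging,
localization annotation — and the statistics used to interpret the
resulting interactome: term enrichment, drug-target and therapeutic-category
enrichment, and a bespoke domain-set pair enrichment.

## Filtering model and its assumptions

A *unique interaction* is a distinct **ordered** bait→prey pair. The assay
is directional (the bait carries the transcription-factor tag), so
reciprocal detections, if any, are biologically distinct observations and
are kept separate. Evidence flags and screen identifiers of merged
duplicates are unioned, and the output is sorted, which makes
deduplication idempotent and order-insensitive.

Contaminant removal applies to preys only: baits are pre-validated
constructs. The default contaminant definition combines one explicit term
(`GO:0006465`, signal peptide processing) with a term-*name* keyword
(`"ribosom"`), because no single GO identifier delimits "ribosomal
contaminants"; an explicit accession blacklist can be added. Removal is
monotone — growing the contaminant configuration can only shrink the kept
set — and the kept/removed tables always partition the input exactly.

Membrane annotation is a configurable term set defaulting to the plasma
membrane component term `GO:0005886`. Whether an annotation export
propagates GO-graph descendants varies by source, so descendant terms must
be supplied by the user if wanted; the package deliberately has no GO-graph
awareness.

Known-interaction flagging matches **unordered** pairs against a
user-supplied reference edge list: reference databases do not preserve
bait/prey orientation.

## Enrichment statistics

Over-representation uses the inclusive upper tail `P(X >= k)` of the
hypergeometric distribution, computed exactly in the log domain
(`stats::phyper` under the `hypergeom_upper_tail()` surface), and
Benjamini–Hochberg adjustment (`stats::p.adjust` under `bh_adjust()`).
The tested family is exactly the reported family: terms with at least one
query carrier and at least `min_K` background carriers. `min_K = 1` by
default; `min_K = 10` mirrors the `nodeSize = 10` preset common in GO
enrichment tools. Reported fractions are `k / n_query` with the query size
counting unannotated members, matching the "% of preys" convention of
screen reports; the alternative (dropping unannotated query members from
`n`) can be obtained by pre-filtering the query, but is not the default
because screens report fractions of detected preys, not of annotatable
preys.

Flat per-term tests are used for every namespace, including GO. Tools that
decorrelate the GO graph (weight-based algorithms) produce different
numbers on GO namespaces by design; results here are comparable in spirit,
not numerically, to such outputs.

Ties in result ordering are broken by `(p_adj, p_raw, term_id)` so output
tables are deterministic.

## Domain-set pair enrichment

The two-step procedure addresses redundancy among protein domains. Within
a side's universe (the baits; the detected preys), domains with identical
carrier sets are merged into one *co-occurrence set*: enrichment cannot
distinguish them, merging avoids redundant results and needless
multiple-testing burden, and the set makes the ambiguity explicit. The
partition is computed by grouping domains on their sorted carrier
signature; adding a protein to the universe can only split sets, never
merge them.

Each supported (bait-set, prey-set) pair is scored with
`P(X >= m), X ~ HG(N, M, n)` where `N` = baits × proteome size (all
possible bait-involving pairs), `M` = detected interactions, `n` = (baits
carrying the bait set) × (proteome proteins carrying *every* domain of the
prey set), and `m` = detected interactions whose endpoints carry both sets.
Three design points were genuinely open and are resolved as follows:

* **Prey-side universe.** Co-occurrence equivalence on the prey side is
  computed over the *detected* preys, while the carrier count entering `n`
  is taken over the full proteome. The proteome size is a required input
  parameter — it defines the space of possible interactions and no default
  could be right for every organism or annotation release.
* **Test family.** Only pairs with `m >= 1` are tested. Pairs with `m = 0`
  cannot be enriched, and including them would only deflate the BH family.
* **Multi-membership.** One interaction supports every set pair its
  endpoints carry; this follows from the counting definitions. An
  interaction whose prey carries no annotated domain supports no pair.

## The synthetic generator

`synthetic_config()` defaults define the study conditions the package is
benchmarked under: a 2,000-protein proteome, 48 baits, a 150-domain
vocabulary with Zipf-skewed frequencies (exponent 1.2) and Poisson(1.5)
domains per protein, 1,500 core hits, 10% duplicate rows, 10 contaminant
preys each hitting half the baits, one planted domain pair at odds
multiplier 20, and one planted prey category at 30% in-prey versus 5%
background prevalence. A quarter of the proteome carries the plasma
membrane term so the localization stage is exercised. These sizes keep a
full pipeline run below a second while giving the planted signals
realistic strength relative to the noise floor.

Draws happen in a fixed order under one seed: proteome, domain
annotations, GO annotations, core edges, contaminant edges, duplicates,
category labels. Category labels come *last*, conditioned on the realized
non-contaminant prey set: prey draws are uniform (weight 1, modified only
by the planted domain-pair multiplier), so an in-prey category rate can
only be realized after the preys are known. `generate_screen()` therefore
returns the screen drawn alongside the world, validating that the supplied
config matches. The planted bait domain is guaranteed on at least 3 baits
and the planted prey domain on at least 20 proteome proteins by redrawing
the domain assignment (the defaults make a redraw rare).

What the generator does *not* emulate: MYTH biochemistry (expression
levels, reporter dynamics, selection stringency), correlated annotation
structure (GO-graph dependencies, domain co-evolution beyond identical
carrier signatures), and orientation biases of real libraries. Passing the
planted-signal recovery tests therefore demonstrates that the statistics
detect the effects they model under clean sampling assumptions — not that
real screens meet those assumptions.

## Numerical and I/O choices

* Hypergeometric tails are exact log-domain computations; no normal or
  Poisson approximation is used anywhere.
* Result tables render p-values in scientific notation with 11 significant
  digits; files are UTF-8, tab-separated, `\n`-terminated, and
  byte-identical across runs given identical inputs, so directory-level
  digest comparison is a meaningful determinism check
  (`run_pipeline()` writes an md5 manifest).
* Identifier normalization (strip whitespace, upper-case protein ids,
  whitespace-only for term accessions) is applied at every boundary and is
  idempotent. Which identifier space (UniProt accession versus gene
  symbol) to use for joins is the user's choice; the normalization rule
  only guards against case/whitespace mismatches, it cannot reconcile
  different identifier systems.
* Degenerate inputs are defined, not errors: empty interaction tables
  yield empty results and all-zero summaries; a world generated with zero
  domains per protein yields an empty domain-pair table.

## Problem sizes used in the test suite

Property-style checks run at sizes chosen so the whole suite completes in
a few minutes on one CPU: exhaustive hypergeometric enumeration up to
`N = 12`; 1,000 random vectors against a literal BH step-up oracle; 500
random fixtures for the partition/refinement invariants; 100 seeded
synthetic screens (plus 100 null screens at odds multiplier 1) for
planted-pair recovery and for planted-category recovery; 25 seeds for
exact contaminant truth recovery; a 2,000-replicate planted-null FDR
simulation.

## Known limitations

* Flat GO tests, no graph decorrelation (see above).
* The co-occurrence partition is sensitive to annotation completeness: one
  missing domain annotation splits a set.
* Real-data reproduction of published interactome-scale counts depends on
  the annotation releases used at the time; the package ships no database
  snapshots and makes no claim of numerically reproducing
  database-dependent tables.
* The validation fixtures shipped under `inst/extdata/` are synthetic
  per-interaction reconstructions consistent with published aggregate
  counts (40 tested / 28 validated overall; 34/22 by co-IP; 8/8 by BRET
  with two overlaps; 50/12 known-pair retest); the true per-interaction
  assignments live in supplementary material not shipped here, and any
  user table in the same schema can be substituted.
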