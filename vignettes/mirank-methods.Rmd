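---
title: "Cross-study rank aggregation of predominant food miRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study rank aggregation of predominant food miRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirank)
```

## The problem

MicroRNA profiling studies of animal-source foods — milk, muscle, offal,
fat, seafood — report their most abundant mature miRNAs, but on
incompatible platforms, with incompatible normalization, and in
species-specific nomenclature dialects (`bta-miR-148a-3p`,
`Oni-miR-1`, `spu-miR-92b-3p`, `miR-100-x`). Absolute expression values
cannot be compared across such studies. What *can* be compared is ordinal
structure: which miRNAs a study places in its top ten. `mirank`
implements a meta-analysis over exactly that signal: a Borda-type
**frequency-weighted ordinal recurrence** score that aggregates per-study
top-N lists into consensus rankings, followed by a set-level analysis of
which conserved miRNAs are shared across food groups, which are exclusive
to one group, and which exclusives survive processing (cooking, drying,
sonication). Generic target-coverage, hypergeometric over-representation
and interaction-network analytics round out the downstream stages.

## The aggregation model

Each study contributes one ranked top-N list (N = 10 by default) per food
product. Position $r$ in a list earns the score

$$s(r) = \max(N - r + 1,\; 0),$$

so the most abundant miRNA earns 10, the tenth earns 1, and anything
beyond the window earns 0. A miRNA's total score in a scope (one product,
or all products of a food group) is the weighted sum of its per-study
scores, with equal study weights by default. Alongside the total we track
**recurrence** — the number of contributing study lists that contain the
miRNA — and the best position it ever achieved.

Assumptions worth stating plainly:

* Ordinal positions are comparable across platforms even when expression
  values are not. This is the method's core premise, not a derived fact.
* Equal study weights treat a 6-animal microarray study and a 40-animal
  sequencing study as equally informative. The `weights` argument of
  `aggregate_scope()` exposes this choice; uniform rescaling provably
  never changes the consensus order (tested).
* A top-10 window discards information below rank 10. That is
  deliberate: source studies often report only their top ten, and
  biological relevance arguments for food miRNAs rest on high abundance.

### Ties

Published tables occasionally mark entries "ranked similarly". Members of
a tie spanning positions $r, r+1, \dots$ each receive the arithmetic mean
of the plain scores over the spanned positions, with positions beyond the
window contributing 0. A two-way tie at the 10/11 boundary thus scores
0.5 per member. This policy is our own choice — source tables mark ties
but never score them — selected because it is symmetric among tie members
and conserves total Borda mass: any full top-10 list injects exactly
$\sum_{r=1}^{10} s(r) = 55$ points, ties or not (tested as an invariant).

### Consensus ordering

Records sort by total score (descending), then recurrence (descending),
then best position (ascending), then name. Only the first key is part of
the source method's description; "cumulative recurrence" in its name
motivates recurrence as the second key, and the remaining keys exist so
the order is total and reproducible. `consensus()` records which key
separated each adjacent pair (`decided_by`), and `top_k()` flags cuts
that fall inside a run of records tied on everything but the name, so a
lexicographic accident never silently decides membership of a top list.
Score comparisons use an absolute tolerance of 1e-9; tie scores are
halves, hence exactly representable, so the tolerance only matters for
unusual user-supplied weights.

## Nomenclature

`canonicalize()` reduces a raw name to a species-independent identity
(base + arm): the species prefix is stripped (known prefixes from a
configurable table; unknown lowercase 3–4 letter prefixes are stripped
with a warning so one unlisted dialect cannot split an identity), stem
casing is normalized, `-5p`/`-3p` is split into an arm field,
underscore annotations and `-x/-y/-z` placeholder suffixes are dropped.
Two deliberate conservatisms:

* **No arm guessing.** `miR-148a` and `miR-148a-3p` stay distinct under
  the default arm-exact matching, because silently assigning the dominant
  arm would change set counts. Where the arm is genuinely known from
  context, `resolve_arms()` applies an explicit user-supplied lookup.
* **No family collapsing.** `miR-92a` and `miR-92b` are different mature
  miRNAs. `mirna_family()` exists for coarser analyses but is never used
  on the reproduction path.

## Presence, exclusivity, persistence

The unit of the set analysis is a presence matrix: conserved miRNA ×
(food group, processing state), with a provenance label per cell. Within
a food type, a miRNA in at least two products' top lists is *shared* and
one in exactly one product's list is *selective* (`shared_selective()`).
Across the five groups (lean meat, meat fat, meat offal, dairy, seafood),
a miRNA is *group-exclusive* when every presence cell — raw and
processed pooled — falls in one group (`group_exclusive()`). Pooling
states per group matters: a miRNA seen only in raw milk and skimmed milk
powder is still dairy-exclusive. `processing_persistence()` then reports
the exclusives that carry at least one processed-state cell.

The packaged fixtures transcribe the published raw- and processed-state
presence tables. Running the partition on them yields 46 raw / 26
processed / 48 distinct conserved miRNAs, exclusive sets of sizes
3 / 3 / 3 / 6 for lean meat, meat fat, meat offal and dairy, and exactly
four persisting exclusives (miR-133b, miR-23a-3p, miR-192-5p,
miR-200c-3p). Two discrepancies between the source tables and their
narrative are reported as notes rather than resolved: the offal trio
contains miR-192-5p where the narrative once prints miR-92-5p (a name
with no table row), and miR-30e-5p is tabulated for both beef heart and
pearl oyster, making it cross-group — strict computation therefore
yields 3 seafood exclusives (18 in total) against a narrated 4 (19).
`run_reproduction()` refuses to run if the fixture counts drift.

## Downstream analytics

These stages are generic re-implementations of what the source workflow
delegated to database services, operating on user-supplied tables so the
pipeline is runnable offline:

* **Target coverage** — `coverage_counts()` counts distinct targeting
  miRNAs per gene; `select_top_targeted()` keeps genes covered by at
  least `min_mirnas` (default 40) up to a cap (default 100), with a
  `fraction` alternative (e.g. top 20%) exposed as a parameter of the
  same selector.
* **ORA** — `hypergeom_p()` is the upper-tail hypergeometric probability
  computed through the survival function; `run_ora()` adjusts across
  *all* tested sets with Benjamini–Hochberg before any overlap filter.
  The default background is the target-map universe, mirroring
  prediction-based enrichment where the background is the predicted
  target space, not the gene-set collection's union; a `universe`
  argument overrides it. One-sided over-representation only.
* **Network** — undirected simple graphs with STRING-style 0–1000
  scores; fractional scores rescale by 1000, duplicate pairs keep the
  maximum, self-loops are dropped with a warning. `threshold()` (default
  700 = "high confidence") retains isolated nodes so degree-0 entries
  stay visible; `degrees()`, `min_degree_filter()` (default 2) and
  `hubs()` (default 5) reproduce the usual degree-table presentation.
  Published degree tables and validated-target counts are
  database-version-dependent and are treated as format references only.

## The synthetic-data generator

`synthetic_config()` describes a study corpus with known ground truth,
standing in for per-study rankings that the literature reports only in
print. Per product, the rank-$r$ pool member has true abundance
$\propto r^{-1.2}$; a Zipf profile was chosen because reported top-10
fractions of mapped miRNA reads in real food miRNomes (roughly 43–97%)
imply heavy-tailed dominance. Each group's pool mixes a shared core
(rotated across products so products differ without losing their
exclusives) with planted group-exclusive miRNAs — 3/3/3/6/4 under the
default five-group configuration. Studies observe abundances under
multiplicative log-normal noise (σ = 0.3 by default) and report their
observed top ten; emitted names carry a random species prefix with
probability 0.5 and lose their arm with probability 0.1, so re-ingesting
a generated corpus exercises the nomenclature module. All randomness
flows from the single config seed; replicate $r$ of an experiment uses
seed + $r$. Identical configs reproduce files byte for byte (tested).

What the generator does *not* emulate: sequencing reads, platform biases,
EV packaging, or inter-product correlation of noise — noise acts directly
on abundances. Passing recovery tests therefore show the aggregation
machinery is correct and noise-robust, not that real cross-platform
heterogeneity behaves like log-normal jitter.

Two recovery regimes are asserted. Noiseless: with σ = 0 the consensus
equals the true order exactly, for any number of studies. Stochastic:
with σ = 0.3, 8 studies per product, a 30-miRNA pool and top-10 lists,
mean recall of the true top-10 by the consensus top-10 across 20 seeded
replicates is at least 0.9 (observed ≈ 0.95). Because armless jitter
changes canonical identity *by design*, recovery experiments resolve
armless emissions through the generator's ground-truth arm lookup — the
package's sanctioned mechanism for arm resolution — rather than
reverting to arm guessing.

A property worth knowing about noisy end-to-end runs: presence at the
top-10 boundary is unstable. A shared miRNA sitting near rank 10 can
reach the consensus top-10 in only one group and then appears
group-exclusive. The planted exclusives, which sit safely inside the
window, are always recovered in their correct groups; the exact
exclusive-set equality is guaranteed only for the noiseless presence
structure. Interpret real-data exclusivity calls with the same caution.

## Numerical and degenerate-input choices

* Ranks are 1-based; position 1 is most abundant. Rank gaps are kept as
  given with a warning; duplicate miRNAs within one study list and
  same-rank rows without a shared tie token are fatal, with line numbers.
* Tie spans must be contiguous; non-contiguous spans are fatal.
* Empty scopes, empty queries, empty universes and empty allow-lists are
  fatal rather than silently empty.
* `hypergeom_p` validates count consistency (`x ≤ min(K, n)`,
  `K, n ≤ M`) and returns exactly 1 at `x = 0`.
* Problem sizes in the shipped tests and acceptance script: enumeration
  oracles to universe size 12, recovery at 20 replicates × 8 studies ×
  30-miRNA pools, five-group corpora of 80 study lists — sizes chosen so
  the whole suite exercises every stage in well under a minute while the
  stochastic assertions still have room to fail if the method regresses.

## Known limitations

* The reproduction path starts from published *presence* tables, not from
  the underlying per-study rankings (which exist only in a print
  appendix); consensus rankings on real data therefore require the user
  to supply ranking tables in the documented dialect.
* Equal study weights and the top-10 window are modelling choices, not
  estimates; sensitivity to both is exposed through parameters but not
  explored automatically.
* The conserved-miRNA filter is list-based (by citation), with no
  sequence-level homology computation.
* ORA treats gene sets as flat; no ontology-graph redundancy reduction.
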