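---
title: "Designing small ranked tailored reference databases"
author: "smartdb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing small ranked tailored reference databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartdb)
```

## The problem

Comparative discovery of genomic islands (GIs) — prophages, integrative
conjugative elements and related mobile elements — works by searching a
query genome against a reference database (DB) of related genomes. A
reference genome that carries the *uninterrupted* integration site of a
candidate GI constitutes one unit of **support** for the call. Reference
DB composition is therefore a real design problem: a single reference
genome gives poor recovery, while an overlarge DB slows the search by
orders of magnitude and, past a few hundred genomes, mostly adds support
for unreliable calls. The sweet spot is a few hundred *diverse* genomes
centred on the query's species.

`smartdb` implements a complete design system for such databases over a
GTDB-style release (seven-rank taxonomy, one designated representative
genome per species, per-domain species trees with branch lengths in
substitutions per site):

1. **Within-species ranking** (`rank_species()`): the species
   representative is removed and returned to the head of the list; the
   remaining genomes are doubly sorted for quality — MIMAG tier in the
   order high, medium, low (missing last), then contig count ascending —
   and the lowest-quality 10% are pinned at the bottom; the top 90% are
   reordered for diversity by a greedy max-sum rule on MinHash sketch
   distances: the representative is first, the second genome is the one
   most distant from it, the third maximises the summed distance to the
   first two, and so on.
2. **Per-species design** (`design_for_species()`): the DB is filled from
   the species' ranked list up to a size cap (200 by default in practice;
   200/300/500 are the conventional settings). If the cap is not reached,
   the ranked lists of neighbouring species are appended in order of
   ascending patristic distance on the species tree, the last donor
   truncated to land exactly on the cap. **No genome from outside the
   source species' taxonomic order is ever admitted**, so databases in
   genome-poor orders stay below the cap (*submaximal*), and databases
   with fewer than 5 genomes are reported by name.
3. **Deduplication** (`deduplicate()`): phylogenetic filling makes many
   species — typically all species of a small order — share one DB
   composition, so compositions equal *as accession sets* are stored
   once. Far fewer DBs than species are needed.

The package also implements the evaluation statistics used to justify the
design: recovery curves over nested DB sizes (`recovery_curve()`),
fractional yields under taxonomic omission (`omission_yields()`),
support-origin fractions (`support_origin_fractions()`), and
actual/possible support decay over tree distance
(`support_decay_profile()`), plus the two descriptive profiles relating
sketch distance, shared taxonomic rank and tree distance.

## Distances

Two distance notions are deliberately kept separate:

* **Within a species**, genomes are compared by bottom-s MinHash sketch
  distance (`build_sketch()`, `sketch_distance()`), with the standard
  genome-sketching defaults `k = 21`, `s = 1000`. The Jaccard index `j`
  estimated from the bottom-s union estimator is transformed as
  `D = -(1/k) log(2j / (1 + j))`, clamped to [0, 1]; `j = 0` maps to the
  saturation value 1 since the transform diverges. Sketch distances above
  ~0.2 are outside the estimator's reliable range
  (`sketch_vs_tree_profile()` quantifies this against tree distance and
  cuts off reporting past tree distance 0.5).
* **Between species**, distance is the patristic (path-sum) distance
  between the two species' leaves on the per-domain species tree;
  intra-species pairs are assigned distance zero by convention. Trees are
  per-domain objects and cross-domain distances are never requested,
  because phylogenetic filling stops at the order.

Hashing is pinned for cross-platform reproducibility: canonical k-mers
(lexicographic minimum of a k-mer and its reverse complement) are packed
into 2-bit codes, mixed with a seeded splitmix64 finalizer, and truncated
to 53 bits so every hash value is exactly representable in an R double.
Consequences worth knowing: sketches are only comparable at equal
`k`/`s`/`hash_seed`; when the sketch capacity exceeds the union
cardinality the Jaccard estimate is *exact* (this is tested against a
brute-force k-mer-set oracle); and k is limited to 31 so a k-mer fits one
64-bit word. Users of an external sketching tool can bypass sketching
entirely: `read_distance_table()` ingests its five-column pairwise
output.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cap` | per run (200/300/500 typical) | maximum genomes per DB |
| `rank_limit` | `"order"` (fixed) | taxonomic ceiling of phylogenetic filling |
| `small_db_threshold` | 5 | DBs below this size are reported by name |
| `min_genome_size_bp` | 200000 | floor for representative sketches; smaller genomes are outside the taxonomy's scope |
| `k` | 21 | k-mer length (bp) |
| `s` | 1000 | sketch capacity (hashes) |
| `hash_seed` | 42 | seed of the pinned 64-bit hash |

## Numerical and tie-breaking choices

Reproducibility demands total orders everywhere the procedure is
underspecified; all tie-breaks are deterministic and documented:

* **Quality sort**: quality tier, then contig count (unknown after
  known), then accession lexicographically.
* **Greedy diversity**: ties in the summed distance go to the genome
  earlier in the quality order. Pairs with no recorded distance (for
  example a genome whose sketch failed) contribute 0 to the sum — the
  genome is deprioritised, never dropped.
* **Quality tail**: the tail is `floor(0.1 * (N - 1))` genomes with `N`
  counting the representative; the floor never promotes a low-quality
  genome and gives an empty tail for small species. The representative
  counts toward neither the sort nor the tail. If a species'
  representative was never collected, the quality leader seeds the
  diversity order and a warning is issued.
* **Neighbour order**: ascending patristic distance, ties broken in
  favour of species sharing the target's family, then by species name.
* **Donor contribution**: a donor species contributes its own ranked
  list (its representative first); the final donor is cut mid-list to
  land exactly on the cap.
* **Deduplication**: compositions are compared as unordered accession
  sets (search-index content is order-insensitive); the stored member
  order is the fill order of the lexicographically least source species.
* **Species processed in lexicographic order**; design files and all
  serialisations are byte-stable so design sets are diffable across runs.
* **Newick input**: absent branch lengths default to 0 with a warning —
  real release trees always carry lengths, hand-written fixtures may not.
* **Profile binning**: 50 bins spanning [0, 3.7) substitutions per site;
  distances at or beyond 3.7 are dropped (no overflow bin) and tallied.
  Bins with no possible pairs report `NA`, not 0.

Two genuinely open points were resolved as follows. Inter-species
distance is taken leaf-to-leaf between the species' representative leaves
on the tree (the natural reading of a species-representative tree); and
the 10% quality tail is computed on the list *without* the
representative, which is removed in step 1 before any sorting happens.

## The synthetic release generator

Desk-scale testing cannot use a real release (hundreds of thousands of
assemblies), so `generate_release()` builds one from a seed: a
monophyletic taxonomy (orders cut into families, families into genera)
realised as per-domain Newick trees with branch lengths spanning the
within-genus (~0.01–0.06) to between-order (~0.7–1.4) range; heavy-tailed
genome counts per species (most species contribute one genome, a few
contribute dozens — mirroring the real skew where the majority of species
are singletons); sampled MIMAG tiers and contig counts; and genome
sequences evolved from a per-domain root by nested per-rank point
mutation plus a per-genome within-species load, so sketch distances
correlate with planted divergence. `generate_gi_calls()` plants GI
support structure on top: per-genome supporter probability
`p0[type] * exp(-decay * d)` in tree distance `d`, a 7-fold `p0` gap
between the prophage-like and Reject-like types (matching the observed
order-of-magnitude gap in mean support between those classes), Reject
attributes violating at least one Reject clause (size < 5 kbp, no
serine/tyrosine integrase, flank identity block > 300 bp), and a
configurable tandem fraction.

What passing tests on these fixtures do show: the design engine, ranking,
dedup accounting, and every evaluation statistic are algorithmically
correct (they match independent straight-line oracles), and the planted
statistical structure (decay, support gaps, origin contrasts) is
recovered. What they do not show: anything about real assembly quality
metadata, real within-species population structure, horizontal transfer,
or the biological correctness of GI calling itself — GI calls are inputs
to this package, never outputs.

Problem sizes used by the shipped test-suite and acceptance script: 20
releases of ~100 species across 6–10 orders for the design-engine
equivalence checks; 200 random instances of up to 12 genomes for the
ranking oracle; 50 sequence pairs for sketch exactness; and a decay-demo
preset of ~1300 retained GI calls for the support statistics.

## Resolution limits and known limitations

* The decay profile's per-bin ratio is a binomial estimate; in bins with
  only a few dozen possible pairs its sampling noise exceeds the
  between-bin decay step (adjacent bins differ by a factor
  `exp(-decay * 0.074)`), so monotonicity of the planted decay is only
  meaningful — and only asserted — over well-populated bins.
* Omission yields are guaranteed nested-monotone
  (species ≥ genus ≥ family ≥ order) when all GIs share one DB scope;
  with mixed scopes the denominator exclusions (GIs from family-limited
  DBs leave the family- and order-omission denominators) can in
  principle produce local inversions.
* The greedy max-sum diversity rule is a heuristic; alternative criteria
  (max-min, clustering) are out of scope.
* Genome collection is an injectable-fetcher contract (retry until done
  or no progress); actual mirroring logic lives outside the package, as
  does the external BLASTN index builder, which `emit_db()` only invokes
  through a configurable command template.
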