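# smartdb

Small Ranked Tailored reference databases for comparative genomics of
prokaryotes.

## The problem

Comparative genomic-island (GI) discovery searches a query genome against
a reference database (DB) of related genomes; each reference genome that
carries the *uninterrupted* integration site of a candidate island is one
unit of **support** for the call. DB composition drives everything
downstream: one reference genome per species gives poor recovery, while
DBs of thousands of genomes are slow to search and — past a few hundred
genomes — mostly add support for unreliable calls. `smartdb` builds, for
every species of a GTDB-style release, a capped, ranked, species-tailored
reference DB, and provides the statistics used to evaluate such designs.

The core procedure, for a species *s* with ranked genome list
*R(s)* and cap *c*:

1. **Rank within species.** Remove the species representative; doubly
   sort the rest by assembly quality (MIMAG tier high < medium < low,
   then contig count ascending); pin the worst ⌊0.1·(N−1)⌋ at the
   bottom; greedily reorder the top 90% for diversity on MinHash
   distances *D* — representative first, then at each step the genome
   maximising Σ *D*(g, selected).
2. **Fill phylogenetically.** Take the first *c* genomes of *R(s)*;
   while short of *c*, append *R(s′)* for neighbouring species *s′* in
   order of ascending patristic distance *d*(s, s′) on the species tree,
   truncating the last donor at *c*. Never reach outside the taxonomic
   order of *s* — DBs in genome-poor orders stay submaximal.
3. **Deduplicate.** Species whose DBs are equal as accession sets share
   one stored DB; far fewer DBs than species are needed.

Sketch distances use the standard transform
*D* = −(1/k)·ln(2j/(1+j)) on the bottom-s MinHash Jaccard estimate *j*
(defaults k = 21, s = 1000); between-species distances are patristic
path sums on the per-domain species tree, with intra-species pairs at
distance 0.

Evaluation statistics: recovery curves over nested DB sizes, fractional
yields under taxonomic omission (species/genus/family/order),
support-origin fractions (only-inside / only-outside / mixed relative to
the query's species), and actual/possible support decay binned over tree
distance. A fully seeded synthetic release generator
(`generate_release()`, `generate_gi_calls()`) makes all of it testable
without downloads.

## Worked example

```r
library(smartdb)

rel <- generate_release(fixture_config(seed = 42, n_orders = 6,
                                       mean_species_per_order = 10),
                        with_sequences = FALSE)
rel
#> smartdb_release (seed 42): 89 species, 257 genomes, 2 domain(s), no sequences

ranked <- rank_all_species(rel$metadata)
set <- design_all(rel$lineages$species, ranked, rel$trees, rel$lineages,
                  design_config(cap = 20))
summarize_design_set(set)
#>   species cap unique_dbs submaximal_dbs small_dbs unique_genomes
#> 1      89  20         23              2         0            256
```

89 species need only 23 unique databases: phylogenetic filling makes all
species of a small order share one composition. Two databases are
submaximal — their orders hold fewer than 20 genomes in total. On the
same release, planted GI support shows the characteristic contrast
between reliable and unreliable call types:

```r
gis <- filter_calls(generate_gi_calls(rel))$retained
support_origin_fractions(gis, genome_species_map(rel))
#>     type   n only_outside only_inside mixed
#> 1  NonPI 708        0.318     0.00706 0.675
#> 2 Phage1 441        0.231     0.00000 0.769
#> 3 Reject 468        0.551     0.06624 0.382
```

The low-support Reject type is *both* more often supported only from
outside the species (0.551 vs 0.231) *and* more often supported only
from inside it (0.066 vs 0) than the reliable prophage type — the
signature of its ~7-fold lower mean support.

A thin command-line front end over these functions ships in
`inst/scripts/smartdb` (subcommands `design`, `rank`, `distances`,
`quick-setup`, `emit`, `sketch-reps`), operating on release directories
written by `write_release()`.

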