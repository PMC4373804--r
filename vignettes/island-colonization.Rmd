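---
title: "Inferring inter-island colonization from haplotype networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring inter-island colonization from haplotype networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islehaps)
```

## The inference problem

A species endemic to an oceanic archipelago must have crossed the sea at
least once per occupied island. Presence data alone give only that lower
bound — the *chorological minimum*, `occupied islands − 1`. Non-recombining
organellar sequence data sharpen the picture: if every haplotype arises by
mutation on a single island (a safe assumption for an archipelago endemic),
then finding the same haplotype on two islands is direct molecular evidence
of an inter-island movement that presence data cannot see, while a haplotype
confined to one island is a failure to find such evidence. `islehaps`
implements this inference chain for short mtDNA fragments: haplotype
collapsing, parsimony network construction, ancestrality ranking, and a set
of colonization metrics comparable across species and archipelagos.

## From alignment to haplotype table

`read_alignment()` ingests a pre-aligned FASTA (alignment itself is
upstream of this package), enforces equal lengths, unique identifiers and a
nucleotide alphabet, uppercases, and maps U to T. `trim_alignment()` drops
a fixed number of leading/trailing columns — typical for Sanger data whose
first decades of bases are unreliable (e.g. trimming 62 leading positions
of a 279 bp fragment to a 217 bp analysis window).

`collapse_haplotypes()` partitions ingroup samples by exact sequence
identity and tabulates counts per island and per population. Outgroup
samples (continental congeners used to orient ancestrality) are collapsed
separately, labelled before the ingroup, and excluded from island counts.
Two details are deliberate choices rather than field conventions:

* **Ambiguity policy.** Published studies rarely state how ambiguous base
  calls were handled when defining haplotypes. The default, `exclude`,
  drops any sequence with a gap, `N` or IUPAC code inside the window, and
  warns; the alternative, `collapse_compatible`, merges an ambiguous
  sequence into the unique resolved haplotype it matches at all its
  unambiguous sites and excludes it (with a warning) when zero or several
  candidates are compatible. Neither is claimed to be what any particular
  study did; `exclude` is the default because it is reproducible without
  judgement calls.
* **Island aliasing.** Islands connected by a recent land bridge function
  as one island for colonization counting. A configurable alias map is
  applied before counting; the shipped default merges Baltra into Santa
  Cruz.

Where only a haplotype-by-island count matrix is available (the usual
situation when reanalysing published summaries), `read_incidence()` builds
a *sequence-free* table; the metrics below work on it, and the
sequence-dependent operations refuse it with a typed error.

## The parsimony haplotype network

`build_network()` connects observed haplotypes by single-substitution
edges, inserting `k − 1` unnamed intermediate nodes ("missing haplotypes",
extinct or unsampled) on any retained k-step connection. The construction
is a minimum-spanning network: candidate pairs are sorted by Hamming
distance (counting only sites where both sequences are unambiguous), ties
broken by the lexicographic id pair, and a pair is retained when its two
endpoints lie in components that were still separate before the current
distance level. All tied minimal connections between the same pair of
components are retained, so mutational ambiguity appears as *loops* —
cycles flagged per node via biconnected components — rather than being
resolved arbitrarily. Homoplasy (recurrent mutation) is the biological
source of such loops.

Classical statistical-parsimony software additionally computes a
probabilistic connection limit beyond which haplotypes are left
unconnected. That probability computation is not reproduced here;
`max_steps` is an explicit parameter instead, defaulting to unlimited,
which is appropriate for single-species data sets whose network is fully
connected. A re-derivation dressed up as the classical limit would be
less honest than a plain cut-off.

`classify_nodes()` labels haplotypes by expanded-graph degree (0 isolated,
1 tip, ≥2 interior); under coalescent expectations interior haplotypes are
older than tips. `lineages()` partitions haplotypes into connected
components, optionally after severing named connections — the natural way
to delimit geographic lineage groups. `ancestrality_rank()` orders
haplotypes lexicographically by (i) substitution steps to the nearest
outgroup haplotype, (ii) number of connections to other observed ingroup
haplotypes, (iii) islands occupied, then sample count. Steps to the
outgroup use the raw pairwise distance rather than a network path, so the
criterion is defined even when the outgroup lies beyond `max_steps`; the
degree criterion deliberately excludes the outgroup connection, which is
already criterion (i). Remaining ties are broken by haplotype id and
flagged, and with no outgroup the report simply omits criterion (i) and
says so.

## Colonization metrics

For a species with `h` haplotypes in an archipelago of `I` (largest)
islands, occupying `n` of them:

* `chorological_minimum(n)` = `n − 1`.
* `max_potential(h, I)` = `h × (I − 1)`: every haplotype could in principle
  have reached every other island.
* `inferred_events(table)`: three sharing rules, always co-reported.
  `shared_count` is the number of haplotypes on ≥ 2 islands;
  `per_haplotype_spanning` is `Σ (k − 1)` over haplotypes spanning `k ≥ 2`
  islands — the minimum number of arrivals beyond each haplotype's single
  island of origin; `spanning_plus_components` adds `C − 1`, where `C`
  counts the connected components of the island graph whose edges are
  shared haplotypes, i.e. the events still needed to connect island groups
  sharing nothing. `per_haplotype_spanning` is the headline rule because it
  works at event granularity; the other two bracket it. No single rule
  reproduces every published count — different studies have plainly used
  different readings — which is exactly why all three are explicit.
* `colonization_success(inferred, max_potential)`: their ratio in `[0, 1]`,
  kept at full precision and rounded half-up to 3 decimals for display
  (`round_half_up()` avoids R's round-half-to-even).

`species_report()` assembles the cross-species comparison table, computing
all rules when a haplotype table is supplied and passing through an
externally published event count (rule `"external"`) otherwise, sorted by
success. The packaged `galapagos_species_summary()` carries the published
inputs for seven species across three archipelagos;
`xylocopa_incidence()` carries the carpenter-bee incidence structure, with
the caveat (documented there) that per-cell counts beyond the published
totals are a plausible reconstruction.

## The synthetic-data generator

`simulate_colonization()` is a forward-time stepping-stone model built to
have exactly the statistical structure the inference assumes: one haploid
Wright–Fisher deme per island, a single founding colonization, finite-sites
mutation on a short locus, and rare uniform migration. Each generation
every occupied island produces `deme_size` offspring from uniformly chosen
parents; offspring mutate each site independently (recurrent mutation is
allowed — it is what produces homoplasy loops for the network tests); each
offspring then emigrates with probability `migration_prob`. Every move is
logged, and a move is a *colonization event* when the haplotype neither
originated on nor had previously reached the destination island. This
bookkeeping definition makes the true event count exactly recomputable
from the genealogy plus the log, which the tests exploit as an oracle.
Final sampling draws `samples_per_island` individuals without replacement
(exhaustively where demes are smaller). A single seed drives everything;
per-generation sub-seeds are derived deterministically so event ordering
is stable.

The `galapagos_params()` preset — nine named islands, 217 bp,
13 samples per occupied island (≈ 117 total), deme size 60, 150
generations, migration 10⁻³ per individual per generation, mutation
2 × 10⁻⁵ per site — was calibrated so that across seeds the haplotype
count and the single-island-haplotype fraction bracket the values typical
of a strongly isolated archipelago endemic (on the order of a dozen
haplotypes, three quarters of them single-island). It is a structural
stand-in, not a fitted model: it has no selection, no demographic growth,
no geography (all island pairs are equidistant), and no sequencing error,
so passing tests demonstrate that the inference chain recovers known
truth under the model's own assumptions — not that those assumptions hold
for any real archipelago.

`recovery_experiment()` sweeps migration and mutation grids with seeded
replicates and reports mean true events, mean inferred events per rule and
mean success per cell. Two of its properties are worth stating precisely:
with zero migration every rule infers zero events, and mean success
increases with migration between well-separated rates. Inferred events
bound true events from below — sharing can only be observed where both
shores were sampled and the migrant lineage survived — so "success" is a
detection-limited index, not an estimate of the migration rate.

## Numerical and degenerate-input choices

* Distances are integer Hamming counts; sites ambiguous in either sequence
  are skipped, never counted as mismatches.
* Zero-distance pairs (possible when sequences differ only at ambiguous
  sites) are never network edges; such haplotypes simply remain in the
  same component if otherwise connected.
* Network construction is invariant to input order; all ordering is by
  sorted haplotype id and distance level.
* A single-haplotype table yields an edgeless network and an `isolated`
  classification rather than an error; an empty table is an error.
* `max_potential` of a single-island archipelago is 0, and the success
  ratio is then reported as undefined (a typed error from
  `colonization_success`; the pipeline omits the field).
* Problem sizes in the shipped tests are kept small (networks of ≤ 6
  observed haplotypes against brute-force oracles, simulator runs of tens
  of generations, a 2 × 50-replicate migration contrast) — large enough to
  exercise every code path and the stochastic contrasts, small enough to
  run routinely.

## Known limitations

* The probabilistic parsimony connection limit is a plain `max_steps`
  cut-off, not the classical 95 % computation.
* Inferred intermediates carry no sequences; when several mutational
  orders are consistent, the network keeps all tied connections (loops)
  but does not enumerate intermediate states.
* The metrics treat islands as exchangeable; distances, areas and
  palaeogeographic connections are out of scope.
* `per_haplotype_spanning` assumes a single island of origin per
  haplotype; under recurrent long-range mutation on multiple islands it
  can overcount, though with migration it far more often undercounts
  because unsampled or extinct sharing is invisible.
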