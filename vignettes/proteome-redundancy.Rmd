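---
title: "Minimizing proteome redundancy: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizing proteome redundancy: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoprune)
```

## The problem

High-throughput sequencing of bacterial outbreaks produces many
near-identical genomes of the same species: strains, sub-strains and
isolates whose proteomes differ by a handful of point substitutions and the
occasional gained or lost gene. In a protein knowledgebase this shows up as
massive redundancy — thousands of essentially identical sequences per
species — which slows searches, biases statistics and buries novel
relationships. `proteoprune` implements a two-stage procedure that flags
whole *proteomes* (not individual proteins) as redundant, keeps a minimal
representative set, and records, for every removed proteome, which
survivors stand in for it.

## Stage 1: proteome comparison

Proteome similarity is asymmetric. The similarity of a query proteome $B$
to a subject proteome $A$ is a length-weighted mean of per-protein
identities:

$$S(A,B) = \frac{\sum_{b \in B} \mathrm{length}(b)\,\cdot\,\mathrm{AS}_{90}(A,b)}
                {\sum_{b \in B} \mathrm{length}(b)}$$

where $\mathrm{AS}_{90}(A,b)$ is the identity of protein $b$ to the longest
protein of $A$ reaching at least 90% identity, and 0 if no protein of $A$
qualifies. Long proteins therefore weigh more than short ones, and proteins
of $B$ with no counterpart in $A$ pull the score down by their full length.
`similarity_score()` implements the formula; `match_sequences()` produces
the per-protein identities by greedy asymmetric clustering: the subject's
proteins are sorted by decreasing length (ties by id, for reproducibility)
and each query protein is aligned against them in that order until the
first — hence longest — seed reaching the threshold is found.

Two heuristics keep the comparison space tractable:

* **Taxonomy.** Only proteomes in the same species group are compared
  (`group_by_species()`). Within-species comparisons of this kind sit in
  roughly the 0.8–1.0 similarity range, while cross-species pairs of the
  same genus fall below the 0.9 edge threshold anyway, so nothing relevant
  is lost. The grouping key is an input column, not derived from a
  taxonomy dump, which keeps the tool self-contained.
* **Size.** A comparison of query $B$ against subject $A$ is performed only
  when $0.9\,|B| \le |A|$ (`size_heuristic()`): a much smaller subject
  cannot cover the query at similarity 0.9, so the score is bounded below
  the threshold before any alignment is run. With 10 000 query proteins and
  a 1000-protein subject the comparison is skipped; the opposite direction
  is still performed, since the small proteome can be redundant to the
  large one.

### Identity definition and alignment

The per-protein identity is the number of identical aligned columns in a
global alignment, divided by the length of the **shorter** sequence. The
alignment maximizes identical columns with free gaps (match +1, mismatch 0,
gap 0), which makes the optimum equal to the longest common subsequence of
the pair; it is computed by a two-row dynamic programme in C++
(`pairwise_identity()`). This choice reproduces percent-identity semantics
without a substitution-matrix dependency, is symmetric, and gives identity
1 whenever one sequence is an exact sub-sequence of the other. Tests
cross-check it against an independent aligner (Biostrings global alignment
under the same scoring).

One numerical consequence worth knowing: when two or more substitutions
interact (e.g. `..XY..` vs `..YX..`), the optimal alignment can recover one
extra column through a crossing realignment, so a sequence with $k$
substituted positions can score slightly *above* $(L-k)/L$. Single isolated
substitutions cannot do this. The synthetic generator's identity guarantee
is therefore stated as $1 - \mathrm{rate}$ within $\pm 1/L$ rather than
exactly.

### The word filter

Before aligning, `word_filter_passes()` counts k-mers (default word size 5,
the usual choice for identity thresholds of 0.7 and above) shared between
the pair. A pair at identity $c$ over shorter length $L$ under substitution
divergence must share at least
$L - w\lceil (1-c)L \rceil - w + 1$ of the shorter sequence's k-mers, since
each differing position destroys at most $w$ of its $L - w + 1$ k-mers.
Pairs below the bound are rejected without alignment. The bound is exact
for the substitution-dominated divergence this tool targets; a contrived
pair that reaches 90% identity only through a heavily gapped, rearranged
alignment could in principle be screened out, but such pairs do not arise
between strains of one species, and the test suite verifies on generated
strain data that filtered and unfiltered matching agree exactly.

## Stage 2: redundancy graph reduction

Comparisons with $S \ge 0.9$ become edges of a directed *redundancy graph*:
an edge $X \to Y$ means "X is redundant to Y". The threshold is applied
with an absolute tolerance of $10^{-12}$ so a score computed as exactly 0.9
is not lost to floating-point representation. Redundancy is non-symmetric
and non-transitive, hence the directed graph rather than clusters.

Finding the smallest set of proteomes that represents the graph is the
minimum dominating set problem on directed graphs, which is NP-hard; a
reasonable dominating set — not necessarily minimal — is sufficient here.
`reduce_graph()` eliminates nodes iteratively: rank every removable node,
remove the weakest, recompute, repeat until nothing is removable. Ranks are
quintuples compared lexicographically:

1. **Indegree** — proteomes redundant to this node (higher is better);
2. **Outdegree** — proteomes this node is redundant to (lower is better);
3. **Priority score** — 2 for reference proteomes, 1 otherwise;
4. **Annotation level** — count of curator-reviewed entries;
5. **Previous state** — 1 if non-redundant in the previous release, 0 if
   redundant; included to damp oscillation between states across releases.

Degrees are recounted on the *surviving* subgraph after every elimination
— "before elimination" in the ranking definitions refers to the elimination
of the node itself. The precedence of priority score over annotation level
follows the parameter listing order; the published ranking examples cannot
distinguish the two orders (the preferred node wins on both components in
the only example that exercises them), so the listing order was adopted as
the design choice.

Removal is constrained so that information is never stranded: a node may
only be removed if it has a surviving out-neighbour (its future
representative) and if it is not the last surviving neighbour of any
already-removed node. When a node is removed, each of its surviving
out-neighbours gains it in their *represented* set; representation is
always via original direct edges, never re-routed transitively. The
survivors therefore summarily connect directly to all removed nodes — a
dominating set by construction, verified after every single removal in the
property tests and compared against an exhaustive-search optimum
(`brute_force_dominating_set()`) on graphs of up to 12 nodes.

Ties are broken in a fixed chain: equal ranks → remove the node whose
represented set is smaller (the better-connected node is kept) → seeded
random choice. The seed is part of the configuration (default 0), making
runs bit-for-bit reproducible; the published procedure permits removal "at
random" at this point, and the seed simply pins that choice down.

**Protected proteomes.** Reference proteomes — curator-designated
representatives — are never removed, and an additional user-supplied
immune list can extend the protected set. Curator review of flagged
proteomes is out of scope; the immune list is its mechanical stand-in.

## Incremental updates and reinstatement

Redundant proteomes are not discarded: they stay available for comparison
against newly arriving proteomes of the same species group.
`incremental_update()` compares newcomers (both directions, heuristics
applied) against all same-group proteomes including previously redundant
ones, rebuilds the graph from old plus new comparison records, sets each
old proteome's previous-state component from its prior status, and re-runs
the reduction. A previously redundant proteome whose coverage becomes
essential — for instance, the only proteome that dominates a newcomer —
re-enters the non-redundant set; the test suite constructs exactly this
scenario. With no newcomers at all, the previous-state component keeps the
solution where it was.

## The synthetic strain generator

Real strain collections are dominated by point substitutions with
occasional gene loss and gain; `generate_base_proteome()` and
`mutate_strain()` emulate exactly that. Design choices:

* **Exact-count substitutions.** Each retained protein has exactly
  `round(rate * length)` positions substituted (chosen without replacement,
  replacement drawn from the 19 alternative residues), not Bernoulli
  per-site noise, so expected identities are analytic and the ground truth
  needs no tolerance allowance.
* **Defaults as study conditions.** The default family is one base proteome
  of 50 proteins of 100–400 residues plus 9 strains at 1% substitution
  divergence — a small but structurally faithful model of an
  outbreak-sequenced bacterial species branch; per-protein identity 0.99
  and proteome similarity ≈ 0.99 put every strain safely above the 0.9
  threshold, so each family should collapse to one representative.
* **Deterministic survivor.** The base proteome gets annotation level 1
  (strains 0), mirroring the originally deposited, better-annotated
  genome. This makes the expected survivor well defined, so the generator
  can emit per-proteome ground-truth labels instead of only survivor
  counts.
* **Analytic ground truth.** A strain is labelled redundant iff every
  retained protein reaches the identity threshold
  ($1 - \mathrm{round}(rL)/L \ge 0.9$) and the length-weighted similarity
  to its base (retained weight over retained-plus-gained length) reaches
  the edge threshold — computed from the generator's own bookkeeping, not
  by running the pipeline.

What the generator does **not** emulate: paralogous families, indels and
rearrangements, codon-level evolution, assembly artefacts, and annotation
differences between pipelines. Passing the synthetic recovery tests
demonstrates that the machinery collapses substitution-diverged strain
families correctly; it does not certify behaviour on proteomes whose
divergence is dominated by gene-structure differences.

## Problem sizes and runtime choices

The test suite and the acceptance script run entirely on generated data:
5 families × 10 proteomes × 50 proteins (100–400 aa) for end-to-end
recovery, 200 random digraphs of up to 12 nodes (edge density 0.1–0.5) for
dominating-set validity against the exhaustive optimum, and smaller
fixtures elsewhere. These sizes exercise every code path — the word
filter, both heuristics, rank recomputation, tie-breaking, protection and
reinstatement — while keeping a full run in the tens of seconds on one
core.

## Known limitations

* The greedy elimination yields a *reasonable* dominating set, not a
  minimal one; the exhaustive oracle is only feasible to 15 nodes.
* The identity measure counts matched columns over the shorter length with
  free gaps; it is deliberately insensitive to length difference, which is
  instead handled by the length-weighting of the proteome score and the
  size heuristic.
* Species grouping is taken as input; misassigned groups translate
  directly into missed or spurious comparisons.
* Viral-scale groups (tens of thousands of proteomes per species) would
  need different heuristics; the per-group all-against-all comparison is
  quadratic in group size.
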