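# proteoprune

Whole-proteome redundancy minimization for sequence databases.

Outbreak-scale sequencing deposits many near-identical genomes of the same
bacterial species — strains, sub-strains and isolates whose predicted
proteomes differ by a few point substitutions. For anyone maintaining or
searching a protein knowledgebase this redundancy means slower searches,
biased statistics and result lists drowned in thousands of copies of the
same protein. `proteoprune` identifies redundant *proteomes* (not
individual proteins), keeps a minimal representative set, and records for
every removed proteome which survivors stand in for it.

## Method

The pipeline has two stages.

**1. Comparison.** Within each species group, every ordered pair of
proteomes (A, B) is scored by a length-weighted similarity

    S(A,B) = Σ_b length(b) · AS90(A,b) / Σ_b length(b)     (b ∈ B)

where `AS90(A,b)` is the identity of protein `b` of B to the longest
protein of A reaching ≥ 90% identity, and 0 if none qualifies. Identities
come from greedy asymmetric clustering (CD-HIT-2D style): A's proteins,
sorted by decreasing length, serve as seeds, and each protein of B is
aligned against them in order until the first seed at ≥ 90% identity. Two
heuristics prune the comparison space: only same-species proteomes are
compared, and a comparison is skipped when the subject is more than 10%
smaller than the query (`0.9·|B| > |A|`), since it could never reach the
threshold.

**2. Reduction.** Comparisons with `S ≥ 0.9` become edges of a directed
redundancy graph (`X → Y`: "X is redundant to Y"). The survivors must form
a dominating set — every removed proteome keeps a direct edge to a
survivor that represents it. Since minimum dominating set is NP-hard, the
graph is reduced greedily: nodes are ranked by the quintuple (indegree ↑,
outdegree ↓, priority score ↑, annotation level ↑, previous state ↑),
compared lexicographically; the weakest removable node is eliminated,
ranks are recomputed, and the loop repeats until no node can be removed
without stranding a removed proteome. Reference proteomes are protected
from removal, ties are broken by represented-set size and then by a seeded
random choice, and previously redundant proteomes stay available for
comparison so that new data can reinstate them.

## Worked example

```r
library(proteoprune)

# two synthetic species: a base proteome plus 3 strains at 1% divergence
specs <- lapply(1:2, function(i)
  family_spec(n_proteins = 10, length_range = c(100, 300),
              n_strains = 3, substitution_rate = 0.01, seed = 10 + i))
coll <- generate_family_collection(specs)

res <- run_prm(coll$proteomes)
res
#> <prm_result> 8 proteomes in 2 species group(s): 2 non-redundant, 6 redundant

tidy(res)
#> # A tibble: 8 × 4
#>   proteome_id    species_group_id status        representatives
#>   <chr>          <chr>            <chr>         <chr>
#> 1 fam01_base     fam01            non-redundant ""
#> 2 fam01_strain01 fam01            redundant     "fam01_base"
#> 3 fam01_strain02 fam01            redundant     "fam01_base"
#> 4 fam01_strain03 fam01            redundant     "fam01_base"
#> 5 fam02_base     fam02            non-redundant ""
#> 6 fam02_strain01 fam02            redundant     "fam02_base"
#> 7 fam02_strain02 fam02            redundant     "fam02_base"
#> 8 fam02_strain03 fam02            redundant     "fam02_base"
```

Each strain sits at similarity ≈ 0.99 to its base (1% substitutions,
length-weighted), well above the 0.9 edge threshold, so each family
collapses onto its base proteome; the strains are flagged redundant with
the base recorded as their representative. The classic four-protein score
check:

```r
similarity_score(data.frame(query_length = c(545, 393, 130, 75),
                            identity = c(0.9853, 0.9975, 1, 1)))
#> [1] 0.9921312   # 0.9921 to 4 decimals
```

`autoplot(res)` summarizes statuses per species group;
`autoplot(res$graphs[["fam01"]], res$reductions[["fam01"]])` draws the
redundancy graph with survivors highlighted. File-based workflows
(`run_pipeline()`, `incremental_update()`) read per-proteome FASTA plus a
metadata TSV and write results, comparison and edge-list TSVs; a
command-line front end with `compare`, `reduce`, `run`, `update` and
`simulate` subcommands lives at `inst/cli/prm.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/prm.R", package="proteoprune"))') run --help`).

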