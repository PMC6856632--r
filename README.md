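# microassembly

Null-model inference of the ecological processes that assemble microbial
communities, for ecologists working from OTU count tables and a phylogeny.

For every pair of communities the package asks: is their compositional
turnover dominated by deterministic selection, by restricted or excessive
dispersal, or by drift? The answer comes from the two-stage framework
standard in microbial ecology:

1. **βNTI** — the z-score of the observed β mean nearest-taxon distance
   (βMNTD) against a null that shuffles taxon identities across the
   patristic distance matrix:

   βMNTD(k,m) = ½ [ Σ_{i∈Tk} f_ik · min_{j∈Tm} d_ij
                  + Σ_{j∈Tm} f_jm · min_{i∈Tk} d_ij ]

   βNTI > +2 → heterogeneous selection; βNTI < −2 → homogeneous selection.

2. **RC_Bray** — for pairs with |βNTI| ≤ 2, the observed Bray–Curtis
   dissimilarity is ranked within a null of probabilistically reassembled
   communities (richness- and read-total-preserving; taxa drawn ∝
   occupancy, reads filled ∝ pool-wide relative abundance), rescaled to
   [−1, 1]. RC > 0.95 → dispersal limitation; RC < −0.95 → homogenizing
   dispersal; otherwise undominated (drift/diversification).

Around this core the package ships the supporting statistics of a typical
survey (alpha-diversity estimators, rarefaction, Jaccard/Bray–Curtis
matrices, PCoA/NMDS, ANOSIM, PERMDISP, Mantel tests, Spearman environmental
correlations, ANCOM, Spearman co-occurrence networks with MCODE-style module
detection), a fully seeded synthetic-community generator with explicit
selection / dispersal-limitation / drift regimes, and a bundled pairwise
turnover matrix from a 13-sample Antarctic shelf-sediment 16S survey
(8 inshore, 5 offshore samples) used as a worked reference dataset.

## Worked example

Classify the bundled reference matrix:

```r
library(microassembly)
res <- reproduce_table1()
subset(res$summary, scope == "all")
#>  scope n_pairs                 process count fraction
#>    all      78 heterogeneous_selection     1   0.0128
#>    all      78   homogeneous_selection     1   0.0128
#>    all      78    dispersal_limitation    61   0.7821
#>    all      78  homogenizing_dispersal     0   0.0000
#>    all      78             undominated    15   0.1923
```

Of the 78 sample pairs, 61 (78.2%) are driven by dispersal limitation, 15
(19.2%) are undominated, and 2 (2.6%) show deterministic selection — the
inshore–offshore pair JB01–JB02 with βNTI = 2.45 (heterogeneous selection),
and R19–R17 with βNTI = −2.13 (homogeneous selection; its RC of 0.72 is
overridden because selection takes precedence):

```r
fx <- load_table1_fixture()
classify_pair(fx$bnti["JB01", "JB02"], fx$rc["JB01", "JB02"])
#> [1] "heterogeneous_selection"
```

The same analysis end-to-end on synthetic communities assembled under a
known regime:

```r
sim <- simulate_dataset(simulation_config("dispersal_limitation",
                                          n_taxa = 100, depth = 5000,
                                          group_sizes = c(inshore = 8,
                                                          offshore = 5),
                                          seed = 42))
out <- run_assembly_analysis(sim$table, sim$tree, sim$metadata,
                             null_model_config(n_null = 199, seed = 42))
subset(out$summary, scope == "all" & count > 0)
#>  scope n_pairs                process count fraction
#>    all      78   dispersal_limitation    36   0.4615
#>    all      78 homogenizing_dispersal     6   0.0769
#>    all      78            undominated    36   0.4615
```

The planted dispersal limitation dominates the recovered partition, and no
pair is mistaken for selection.

A thin command-line front end is installed with the package
(`system.file("cli", "microassembly", package = "microassembly")`) with
subcommands `simulate`, `diversity`, `nullmodels`, `assembly`, `stats`,
`reproduce-table1` and `run`, each a flag-parser over the exported
functions; `run_pipeline()` orchestrates the full chain from a YAML config
and writes TSV outputs plus a manifest.

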