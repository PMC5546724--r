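# hictad

Multi-resolution identification of topologically associating domains
(TADs) from intra-chromosomal Hi-C contact maps.

TADs are contiguous genomic segments whose loci contact each other more
often than they contact the outside — diagonal blocks in a Hi-C contact
map. `hictad` finds them by community detection on the bin chain: for a
partition σ of the n bins into contiguous domains it maximizes the
resolution-parameterized modularity

    Q = (1/2N) * Σ_ij (W_ij − γ E_ij) δ(σ_i, σ_j)

where `W` is the contact matrix, `N` the total read count, `γ > 0` the
resolution parameter (larger γ → more, smaller domains), and `E` a
background model that preserves both the observed coverage of every bin
and the distance dependence of contact frequency:

    E_ij = κ*_i κ*_j f(|i − j|),   with   Σ_j E_ij = c_i  for every bin i.

The decay `f(d)` is estimated from the map by local smoothing (1%
window, log–log local fit) and the effective coverages `κ*` are solved
by damped fixed-point iteration — a generalization of ICE-style matrix
balancing with the observed coverage profile as the target.

Optimization uses a contiguity-constrained Louvain heuristic (only
segment-endpoint bins may switch to the adjacent segment; random update
order; multilevel aggregation with bin-level refinement). Multiple
stochastic trials give each of the n+1 borders a boundary score — the
fraction of trials calling it — and borders scoring ≥ 0.9 in 10 trials
become consensus TAD boundaries. An exact O(n³) dynamic-programming
optimizer (Nussinov-style recurrence over segment splits) provides the
provably optimal partition for validation at small n, partitions are
compared by normalized mutual information `2I(X;Y)/(H(X)+H(Y))`, and a
synthetic generator with planted (optionally nested) domains, power-law
decay, heterogeneous coverage, and Poisson noise makes every stage
testable without external data.

## Worked example

Simulate a 200-bin chromosome with 8 planted domains at 40 kb bins,
call TADs at γ = 1, and compare against the planted truth:

```r
library(hictad)

g  <- generate_map(synthetic_spec(200, n_domains = 8, within_enrichment = 2,
                                  depth = 2e6, seed = 3))
cc <- call_tads(g$map, caller_config(gamma = 1, n_trials = 10,
                                     cutoff = 0.9, seed = 2))
glance(cc)
#> # A tibble: 1 × 9
#>   gamma n_tads median_size_bp mean_trial_q sd_trial_q n_trials cutoff ...
#> 1     1      8        1080000       0.0533          0       10    0.9

normalized_mutual_information(cc$partition, g$truth$partition)
#> [1] 1
```

The call recovered all 8 planted domains (median size 1.08 Mb at 40 kb
bins); every one of the 10 stochastic trials reached the same partition
(`sd_trial_q = 0`), and the consensus agrees perfectly with the planted
truth (NMI = 1). `tidy(cc)` returns the domains as a tibble,
`write_tads_bed()` / `write_boundary_scores()` emit BED and bedGraph,
`autoplot(cc)` draws the boundary-score track, and
`sweep_resolutions(map, c(0.75, 1, 1.5, 2.25, 3))` summarizes how domain
count and size change with γ. The same pipeline is available from a
shell via the thin CLI at `inst/scripts/hictad`
(`call`, `sweep`, `exact`, `compare`, `simulate`, `enrich`).

For the model's assumptions, algorithmic details, and known limitations
see the methods vignette (`vignettes/hictad-methods.Rmd`).

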