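---
title: "Multi-resolution TAD calling: model, algorithms, and design choices"
author: "hictad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution TAD calling: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hictad)
```

## The problem

A Hi-C experiment summarizes the spatial organization of a chromosome as a
contact map: a symmetric matrix $W$ whose entry $W_{ij}$ counts ligation
events between equally sized genomic bins $i$ and $j$. Topologically
associating domains (TADs) appear as blocks of elevated contact frequency
along the diagonal. They exist at several length scales — large domains
contain sub-domains — so a caller should expose the scale as an explicit,
tunable parameter rather than commit to one.

`hictad` treats TAD identification as community detection on a chain: bins
are nodes, contacts are weighted edges, and domains are *contiguous*
segments of bins that are more connected internally than a suitable null
model predicts.

## Objective

For a partition $\sigma$ of the $n$ bins into contiguous domains, the
score is a resolution-parameterized modularity
$$
Q \;=\; \frac{1}{2N}\sum_{i,j}\bigl(W_{ij}-\gamma E_{ij}\bigr)\,
\delta_{\sigma_i\sigma_j},
$$
where $N=\tfrac12\sum_{ij}W_{ij}$ is the total read count, $E$ is the
expected map under the null model, and $\gamma>0$ is the resolution
parameter. The sum runs over ordered pairs, diagonal included (a flag
drops it for maps whose diagonal was removed upstream). With the diagonal
included and a converged null model, the single-domain partition scores
exactly $1-\gamma$ — a useful self-check that the suite asserts on every
fixture. Raising $\gamma$ penalizes expected contacts more strongly, so
only pairs close to the diagonal remain profitable and the optimal
domains become smaller and more numerous; $\gamma = 1$ is the natural
starting point.

## The background model

Chromatin is a polymer: expected contact frequency depends strongly on
genomic distance, and sequencing depth per bin ("visibility") is uneven.
The null model factorizes both effects:
$$
E_{ij} \;=\; \kappa^*_i\,\kappa^*_j\, f(|i-j|),
$$
with the *effective coverages* $\kappa^*$ chosen so the model reproduces
every observed bin coverage, $\sum_j E_{ij}=c_i$ (and therefore
$\sum_{ij}E_{ij}=2N$). This is a generalization of matrix balancing:
ICE solves the same kind of system with a uniform target coverage,
whereas here the target is the observed coverage profile itself.

### Distance decay estimation

$f(d)$ starts from the raw mean of all matrix elements at each bin
distance $d$, then is smoothed locally with a window of
$\max(3,\operatorname{round}(0.01\,n))$ distance points (1% of the
series; the `span` argument). Smoothing is a **local linear fit in
log–log space** evaluated at each distance. The reason is numerical, and
it matters: contact decay is close to $d^{-1}$, and a plain running mean
on the linear distance grid underestimates $f(1)$ by roughly 25% (the
edge window averages $f(1)$ with the much smaller $f(2)$, $f(3)$) and
overestimates $f(2)$. Those biases sit at exactly the distances that
decide domain boundaries, and in development they planted artifactual
two-bin micro-domains near map edges. A local linear fit in log–log
space is exact on a pure power law, so it has no such bias; windows with
fewer than two positive raw means fall back to the window's arithmetic
mean, which also keeps $f \ge 0$ without any clipping rule. $f(0)$ is
the raw diagonal mean, unsmoothed, since the diagonal is not part of the
decay curve (and is identically zero on ICE-style maps).

### Solving for the effective coverages

The system $\kappa_i\sum_j \kappa_j f(|i-j|)=c_i$ is solved by damped
fixed-point iteration: the raw update
$\kappa_i \leftarrow c_i/\sum_j\kappa_j f(|i-j|)$ is combined with the
previous iterate through a geometric mean,
$\kappa^{\text{new}}=\sqrt{\kappa^{\text{old}}\,\kappa^{\text{upd}}}$.
The damping halves the update's log-step, which suppresses the two-cycle
oscillation plain iteration exhibits on maps with heterogeneous
coverage. Initialization is deterministic,
$\kappa_i=\sqrt{c_i/\bar c}$, so the null model is fully reproducible.
Bins with zero coverage (unmappable regions) are pinned at $\kappa=0$
and excluded from all sums. Convergence is declared when
$\max_i |\sum_j E_{ij}-c_i|/\max(c_i,1)\le$ `tol` (default $10^{-6}$,
default cap 2000 iterations; typical maps converge in a few dozen).
Non-convergence returns the best iterate flagged `converged = FALSE`
with a warning rather than an error, since a slightly unbalanced model
is still usable for exploration.

```{r null-model}
fx <- standard_fixtures("F200")
model <- solve_effective_coverage(fx$F200$map,
                                  estimate_distance_decay(fx$F200$map))
glance(model)
```

## The contiguity-constrained Louvain heuristic

Standard Louvain cannot be used: arbitrary label adoption would produce
non-contiguous "domains". The modification restricts moves so contiguity
is invariant: starting from singleton segments, only a bin at an *end*
of its segment may change label, and only to the adjacent segment on
that side. Each sweep visits all bins in a fresh uniformly random order
(the only stochastic element) and applies the best of
{move left, move right, stay} when its gain is strictly positive, with
ties broken toward the lower-indexed side. Move gains are computed in
O(1) from per-row cumulative sums of $B = W-\gamma E$. When a full sweep
makes no move, segments are locked into super-bins, the score matrix is
aggregated, and the same dynamics runs on the chain of super-bins
(allowing merges and endpoint defections of whole segments); each
multilevel cycle then re-opens a bin-level refinement pass initialized
from the current partition, so single bins can still slide across
boundaries after coarse merges. Cycles repeat until no move exists at
any level. Every accepted move strictly increases $Q$, so the procedure
terminates; `max_levels` and `max_sweeps` are pure safety caps and are
not expected to bind.

### Boundary scores and consensus

Because the update order is random, independent trials can return
different local optima. The caller runs `n_trials` trials (default 10)
with child seeds derived deterministically from the master seed, and
scores each of the $n+1$ borders by the fraction of trials in which its
two flanking bins received different labels; chromosome ends always
score 1. Borders scoring at least `cutoff` (default 0.9, i.e. at least
9 of 10 trials) become consensus boundaries, and consensus TADs are the
maximal runs between them. Runs consisting entirely of zero-coverage
bins are dropped, and zero-coverage bins at a run's edges are trimmed
and left unassigned — dead bins should not acquire domain membership by
adjacency. The cutoff comparison is inclusive (`>=`), matching the
"at least 9 of 10" reading.

A caution on interpretation: the boundary score measures the
*stochastic reproducibility of the optimizer on one fixed map*, not
statistical significance against count noise. On a map with no planted
structure the trials agree on the same noise-driven fragments, so
consensus boundaries appear there too; what distinguishes real structure
is the scale of the resulting domains (see the limitations section).

## Exact optimization by dynamic programming

Contiguity makes the search space small enough for exactness: with
$q_{ij}=(W_{ij}-\gamma E_{ij})/2N$, the optimal score $M[i,j]$ of the
sub-sequence $i..j$ is the maximum over all split points $r$ of
$M[i,r]+M[r{+}1,j]$ and of the whole-segment score
$\sum_{p,q\in[i,j]}q_{pq}$, filled by increasing length — three nested
loops, $O(n^3)$, analogous to the Nussinov algorithm for RNA secondary
structure. Whole-segment scores come from 2-D prefix sums so the last
option is O(1) per cell. Traceback from $M[1,n]$ recovers the optimal
partition. An exhaustive enumerator over all $2^{n-1}$ contiguous
partitions (refusing $n>16$) provides an independent oracle; the suite
checks DP–enumeration agreement to $10^{-12}$ on dozens of random maps,
and that no heuristic trial ever exceeds the DP optimum. The cubic cost
makes DP impractical beyond a few hundred bins, which is why the
heuristic is the production path. Enumeration ties are broken toward
fewer domains and then the lexicographically smallest boundary set, so
degenerate inputs (e.g. $W=E$, where every partition scores 0) resolve
deterministically to the single-domain partition.

## Comparing partitions

Agreement between two bin labelings is the normalized mutual
information $2I(X;Y)/(H(X)+H(Y))$, computed from the contingency table
with natural logarithms (the ratio is base-invariant): 1 for identical
partitions, 0 for independent ones. Bins unassigned in *both*
partitions are excluded; bins unassigned in exactly one are kept with a
distinct "unassigned" class on the missing side, so disagreement about
coverage is counted rather than silently dropped. If both labelings are
constant the entropies vanish and the partitions are identical, so the
value is defined as 1. Note NMI between two fine segmentations of the
same chain is substantially above 0 even for independent noise, a
granularity effect worth keeping in mind when reading absolute values.

```{r nmi}
normalized_mutual_information(c(1, 1, 2, 2), c(1, 2, 2, 2))
```

## The synthetic generator

All tests and benchmarks run on generated maps with known truth. The
expectation is
$\mu_{ij}=v_iv_j\,\max(|i-j|,1)^{-\alpha}\,\beta^{[\text{same domain}]}
\beta^{[\text{same sub-domain}]}$, scaled to a target depth, with
visibilities $v_i$ log-normal and counts Poisson-sampled on the upper
triangle and mirrored; the diagonal is zero, matching ICE-style
processed maps. This emulates power-law decay (default $\alpha=1$, the
canonical intermediate-distance exponent), heterogeneous coverage,
nested block structure, and count noise. It does **not** emulate
mappability artifacts, restriction-fragment granularity, copy-number
variation, compartment-scale checkerboards, or corner "loop" peaks —
so passing tests demonstrate correctness of the machinery on maps whose
generative model matches the null model's assumptions, not performance
on every pathology of real data.

Default fixture conditions, chosen once: enrichment $\beta=2$ and about
$10^4$ expected read pairs per bin (F200: 200 bins, 8 equal domains,
depth $2\times10^6$, seed 7; F500: 500 bins, 12 randomly sized domains,
visibility sigma 0.5, depth $5\times10^6$, seed 7; FNEST: 300 bins, 6
domains with 2–3 nested sub-domains each, $\beta=1.8$, depth
$3\times10^6$, seed 13). These sizes keep the full suite — including
the $O(n^3)$ exact solver on F200 and repeated consensus calls on
F500 — comfortably within interactive runtimes while leaving the
per-pair counts in a realistic range.

## Known limitations

* **Local optima at low signal-to-noise or very wide domains.** Growth
  of a segment must begin with a favorable two-bin merge. When the decay
  estimate absorbs most of the within-domain enrichment (which happens
  when a single domain spans a large fraction of the map, or depth is
  low), adjacent-pair gains at distance 1 are pure noise and the
  dynamics can converge to a fragmented state that no single endpoint
  move or pairwise merge can improve, even though the exact optimum
  merges the whole region. This is intrinsic to strictly greedy
  contiguous Louvain; the DP optimizer provides the check where it is
  affordable.
* **Self-estimated decay compresses the useful resolution band on
  synthetic maps.** Because $f$ is estimated from the same map, the
  average within-domain enrichment is absorbed into the null model;
  at $\gamma$ well above 1 essentially all pairs score negative and the
  partition degenerates to singletons. On the synthetic fixtures the
  informative range is roughly $\gamma\in[0.75, 1.5]$; real maps, with
  their much stronger near-diagonal signal, sustain a wider band.
* **Boundary scores are not significance tests.** See above; use the
  synthetic generator (or the DP optimum) to calibrate expectations for
  a given depth before interpreting consensus boundaries on real data.
* **Intra-chromosomal maps only.** The factorized null model is not
  defined here for inter-chromosomal blocks.

## Reproducibility

Every stochastic step flows from explicit seeds: generator seeds are
part of each fixture's definition, and the caller's master seed spawns
per-trial child seeds through one `sample.int` draw. Two calls with the
same seed are bit-identical end to end; text exports of the null model
round-trip bit-exactly (17 significant digits).
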