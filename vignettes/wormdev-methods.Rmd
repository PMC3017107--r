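---
title: "Methods: staging, wiring statistics and null models in wormdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging, wiring statistics and null models in wormdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wormdev analyzes how a neuronal network is laid down in time and space,
using the *C. elegans* nervous system as its model: every neuron has a known
birth time (minutes post-fertilization) and a known adult soma position, and
the adult wiring diagram is fixed and essentially invariant across animals.
That combination lets one ask, for any developmental time `t`, which of the
adult connections *could* already exist — both partners born — and whether
the temporal and spatial patterning of those "connection pairs" differs from
what random assignment of identities to the same wiring diagram would give.

```{r setup}
library(wormdev)
```

## The body model and staging

Soma positions come as 2D coordinates: anterior–posterior (`ap`, along the
body axis) and dorsoventral (`dv`). The body is modelled as a cylinder of
constant radius `r` (default 0.05 mm, i.e. 50 µm) and the third coordinate
is the circle cross-section solution `|z| = sqrt(r^2 - dv^2)`, signed by
laterality: left-side neurons positive, right-side negative, midline neurons
forced to `z = 0`. This is the unique lift consistent with neurons on the
dorsal or ventral line having no lateral offset. The sign convention is
arbitrary but fixed. Digitized 2D data can overshoot the idealized cylinder;
`|dv|` in excess of `r` by at most 1e-6 mm is clamped silently, larger
excesses clamp to the radius with a warning (the neuron then sits on the
dorsal/ventral line, `z = 0`). All lengths are stored in millimetres because
the wiring-length class thresholds are naturally stated in mm.

A *stage network* at time `t` is the sub-network induced on neurons with
`birth_time <= t`; a connection is present iff both adult endpoints are
present. The cutoff is inclusive so that a stage time quoted as "all
pre-hatching neurons" indeed contains a neuron born exactly at that minute.
The default stage ladder is 350, 400, 500, 800, 2000 and 2700 minutes, with
hatching at 840 minutes dividing births into an embryonic and a
post-embryonic phase. Presence of a connection pair says nothing about
synaptogenesis — both the staging and every "appearance" curve measure
neuron births only.

Connections are stored once per unordered neuron pair with a synapse kind
(gap junction, chemical, or the combination of both) and a directedness
flag. Gap and combination junctions are bidirectional by definition; a
chemical pair recorded in both directions collapses to one bidirectional
link, and a pair carrying both a gap junction and a chemical synapse
collapses to a combination. Degree counts arcs after expanding each
bidirectional link into two, so a bidirectional link contributes 2 to each
endpoint. Self-loops and explicitly excluded neurons (e.g. a neuron that
connects only through neuro-muscular junctions, which are outside scope)
are removed by `apply_exclusions()` before analysis.

## Wiring statistics

**Birth-time differences.** One `|Δbirth|` per link. The histogram uses
equal-width bins over `[0, max]`, half-open except the last; empty bins
report an `NA` mean rather than 0, so downstream plots cannot mistake an
empty bin for a population of simultaneous births.

**Phase and region fractions.** "What fraction of the connections made by
embryonic neurons stay within the embryonic phase?" is endpoint-weighted:
every link contributes once per embryonic endpoint, and we count the
contributions whose partner is also embryonic. The same weighting is used
for within-region fractions, for internal consistency. The simpler
link-level reading (within-phase links over links touching the phase) is
available via `method = "link"`; the two differ exactly when many links
have both endpoints in the phase.

**Hubs.** `hub_report()` takes an explicit comparator (`>=` or `>`) because
prose thresholds like "20 or more" and "more than 30" mix both readings; a
"late-forming neighbour" is a connected partner born at or after hatching.

**Length classes.** Soma-to-soma Euclidean distance in 3D, classified by
ten 0.12 mm bins: the first three are short (`d < 0.36` mm), the last three
long (`d >= 0.84` mm), the middle four medium. `d = 0.84` is assigned long
(bins are half-open `[lo, hi)`), and lengths beyond the binned range — which
synthetic data can produce — are long rather than an error, keeping the
classifier total.

**Circuits.** A connection pair belongs to every functional circuit either
endpoint belongs to, so pairs spanning two circuits count in both; each
circuit's appearance curve is normalized by its own adult pair count.

## Null models and significance

The primary null is the **identity shuffle**: the graph (and hence the
degree sequence) stays fixed while the identity bundles — position, side,
birth time, region, type, circuits — are permuted uniformly across nodes,
as one block per neuron. Permuting whole bundles preserves the coupling
between where a neuron sits and when it is born; only the assignment of
identities to network nodes is randomized. Any scalar metric is summarized
over an ensemble of 20 shuffles by default (mean and sample SD), and
compared with the observed value by a one-sample t-test,
`t = (obs - mean) / (sd / sqrt(n))` with `n - 1` degrees of freedom. The
orientation of the test (ensemble sample against observed constant) only
flips the sign of `t`. Exact p values are returned; thresholding is left to
the caller. Trial seeds derive deterministically from the master seed.

For topology baselines the null is instead **Erdős–Rényi G(n, m)**: exactly
`m` links chosen uniformly, matching node and link counts but not the
degree distribution. Clustering coefficient (Watts–Strogatz: mean local
clustering, degree-<2 nodes contributing 0 — the other convention excludes
them and yields a different C, so this is fixed and documented) and
characteristic path length are computed on the symmetrized simple graph.
Early-stage networks can be disconnected; L is taken over the largest
connected component and the component's coverage is reported alongside so
the approximation stays visible.

## The synthetic generator

`generate_connectome()` provides data with the statistical structure the
analyses assume plus *planted*, recoverable effects. Defaults describe the
study conditions: 279 neurons, 2,990 links, a 1.2 mm body of radius
0.05 mm, head/body/tail axial clusters (anterior 20%, middle, posterior
15% of the body; head-weighted 0.5/0.3/0.2), an embryonic birth window of
350–750 min holding 70% of neurons and a post-embryonic window of
900–2700 min, bilateral pairs (70% of neurons) mirrored in `z` and born
within 10 minutes of each other, and synapse kinds at the adult mix
(22.5% gap, 12.6% combination, the rest chemical with 18% reciprocal).

Pair weights are
`exp(-d / 0.25 mm) * exp(hub_early_bias * e_i * e_j) + long_range_early_bias * [long pair, both embryonic]`,
with earliness `e` the birth time rescaled so the earliest possible birth
maps to 1 and the last stage time to 0. Exactly `n_connections` links are
sampled without replacement, so analyses always see the intended edge
count. The defaults `hub_early_bias = 1.5` and `long_range_early_bias = 2`
were chosen once so that both planted effects are recovered essentially
always at the 200-neuron/2,000-link test scale, while keeping the long
class near a tenth of all links — of the same order as the real worm's
class mix. They are effect-strength coefficients for recovery testing, not
quantitative claims about *C. elegans*.

What the generator does *not* emulate: lineage structure (births are
i.i.d. within windows, not a branching process), axon trajectories,
synapse positions, pruning, and the worm's particular circuit memberships
(regions carry simple stand-in circuit labels). Passing recovery tests
therefore shows that the pipeline detects temporal/spatial wiring biases
of the planted kind at realistic scale — not that the real nervous system
was reproduced.

## Numerical choices and problem sizes

Stage cutoffs are inclusive; equal-width histogram bins are half-open with
a closed last bin; the degenerate all-zero histogram collapses to a single
`[0, 0]` bin. Correlations refuse zero-variance input rather than
returning 0. Ensembles with a failed trial are flagged rather than
silently shortened. The test suite checks the graph metrics against
O(n³) brute-force oracles (triangle enumeration, Floyd–Warshall) on
exhaustive batches of random graphs of up to 15 nodes, calibrates the
t-test's null p distribution at 1,000 replicates, and runs the planted
recovery checks at 200 neurons / 2,000 links over 20 seeds with 20-trial
shuffle ensembles — sizes chosen to make the statistical contracts sharp
while a full run of the suite stays well under a minute per file.

```{r example}
sim <- generate_connectome(generator_config(n_neurons = 80,
                                            n_connections = 300, seed = 1))
con <- sim$connectome
degree_birth_correlation(con)
phase_fractions(con)
small_world_series(con, n_random = 5, seed = 1)[, c("stage_time", "n_nodes",
                                                    "C", "L", "ratio_C")]
```

## Known limitations

Lengths are soma-to-soma straight lines, a lower bound on wire length.
The identity shuffle preserves the degree sequence but not any
position–degree coupling, so metrics that depend only on topology have
degenerate (zero-SD) ensembles and cannot be tested against this null.
The small-world indices symmetrize the directed network, following the
usual undirected formulation; a directed variant is out of scope. And
because connection presence is defined by births alone, nothing here
constrains when synapses actually form — late synaptogenesis between
early-born neurons is invisible to this analysis.
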