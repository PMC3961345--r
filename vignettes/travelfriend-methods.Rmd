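---
title: "Methods: coupled mobility and tie formation, its null models, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled mobility and tie formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(travelfriend)
```

## The coupled process

`run_tf()` simulates agents on a population raster. A time step is one
sweep of `N` single-agent activations drawn uniformly with replacement;
each activation has two stages.

*Travel.* With probability `p_v` the agent moves to the current location
of a uniformly chosen friend (by default an out-neighbour — someone the
agent follows; `visit_mode = "union"` uses the symmetrized neighbourhood).
Agents without friends always take the alternative: a random jump. The
jump length is drawn from a truncated power law with exponent magnitude
1.55 on [1, 20000] km (normal and uniform laws are available for the
variant experiments), and the landing point is drawn among the populated
raster cells whose centre lies in an annulus of width
`max(cell diagonal, 0.05 r)` around the target distance `r`, with
probability proportional to cell population, jittered uniformly inside the
chosen cell. If the annulus holds no population the length is redrawn (up
to ten times), then the populated cell whose centre distance is closest to
`r` is used; on a bounded country-scale raster this keeps the walk
well-defined near coasts. Agents stay where the visit took them until
their next activation; returning home is emergent (most friends live
there), not scripted.

*Friendship.* One Bernoulli(`p`) draw gates the creation of directed links
from the agent to every other agent inside the `delta_km` x `delta_km`
axis-aligned box centred on it (tangent-plane box, longitude span
corrected by `cos(lat)`; `neighbor_gate = "per_neighbor"` switches to an
independent draw per box-mate). Independently, a Bernoulli(`p_c`) draw
gates one directed link to a uniformly chosen non-self agent (redrawn
while the edge exists, at most 50 tries). Both actions can fire in one
activation. The run stops the moment the directed-link count reaches
`L_target`, truncating the last batch so the count is exact; a `max_sweeps`
safety cap flags partial runs.

Defaults: `p = 0.1` (the face-to-face linking rate), `delta_km = 5` (the
box size is a modelling choice at commuter scale; results are insensitive
to moderate changes), and free parameters `p_v`, `p_c` meant to be
calibrated. All randomness — in R and in the compiled core — flows through
R's generator, so `set.seed()` (or the `seed` arguments) makes runs
bit-reproducible.

## Geography

Distances are haversine on a sphere of radius 6371.0 km throughout; the
empirical literature rarely states its geodesic convention and the
haversine is monotone in the true geodesic, which is all the
distance-binned statistics require. Positions are always jittered
uniformly within raster cells rather than placed at centres, avoiding
artificial zero distances that would corrupt the short-distance bins.
Distances below 1 m are clamped to 1 m before log-binning, since a friend
visit co-locates two agents exactly.

`synth_population_grid()` builds Gaussian-cities worlds: a mixture of
isotropic Gaussian population kernels discretised to integer counts
(largest-remainder rounding, so totals are exact). It emulates the one
feature of real population rasters the model relies on — a few dominant
cities separated by near-empty space — and nothing else: no coastlines,
no road corridors, no power-law city-size tail unless requested through
`city_weights`. Tests passing on these worlds therefore show that the
machinery behaves as specified, not that the model reproduces any real
country's geography.

## Geo-social statistics

All statistics treat a pair as connected if either directed edge exists,
except reciprocity, which is conditional on a directed edge.

- `link_probability_curve()` — linked pairs over all pairs per distance
  bin; exact all-pairs enumeration up to 5000 nodes, Monte-Carlo with a
  `pair_budget` of 10^7 sampled pairs above (bounding bin error below
  0.01).
- `degree_distribution()` — symmetrized degrees by default, mass summing
  to one over all `N` nodes.
- `reciprocity_curve()` — fraction of directed edges in a bin whose
  reverse exists.
- `social_overlap()` — for connected `i`, `j`:
  `|G_i and G_j| / |(G_i or G_j) minus {i, j}|`; 1 when all friends are
  shared, 0 when none, undefined (excluded from averages) when the pair
  has no other neighbours. `overlap_curve()` bins the averages.
- `clustering_curve()` — closed triads over triads per bin of the triad
  distance, the mean of the two centre–leaf distances (`"max"` is the
  alternative); the sample-weighted bin average reproduces the global
  coefficient exactly, which the tests pin to machine precision.
- `disparity_distribution()` — per unique triangle,
  `D = (d_max - d_min) / d_max` over its three side lengths: 0 for
  equilateral geometry, approaching 1 when two users are co-located and
  the third distant. This form satisfies both stated boundary behaviours;
  it is the package's pinned contract.
- `scalar_summary()` — nodes with degree >= 1, mean undirected local
  clustering over those nodes (degree-1 nodes contribute 0), global
  clustering, global reciprocity.

Display binning defaults to 30 log bins (1 km to the 99.9th percentile
pair distance for the link-probability curve, data-covering bins for
edge-based curves).

## Calibration

`property_error()` compares a property between a reference and a model as
the mean over defined bins of `|a - b| / (|a| + |b|)` (0/0 terms count 0;
scalars have one term). It is symmetric, bounded in [0, 1], and
scale-free, which lets the eight properties — the link-probability curve,
the degree distribution, reciprocity, overlap and clustering versus
distance, the disparity histogram, the connected-node count and the mean
local clustering — be averaged with equal weight by `total_err()`.
Distribution-valued properties are evaluated on the reference's binning
(the model side is re-binned to it), which fixes the number of terms.

Comparison curves use 10 log bins (`n_bins`), deliberately coarser than
the display default: with ~10^3 links per network, 30-bin tails hold a
handful of links each and the normalized error is then dominated by
Poisson noise rather than by the parameters.

`latin_square_scan()` evaluates the model over `k` linearly spaced visit
probabilities and `k` logarithmically spaced random-link probabilities.
`cells = "design"` samples `k` cells, one per row and column (a Latin
square, the classic space-filling design); `cells = "all"` evaluates the
whole `k x k` grid — equivalently the union of the `k` disjoint cyclic
shifts of a Latin square — which a recovery experiment needs (below). Each
cell is simulated `replicas` times with derived seeds and its error
averaged; the minimizing cell is exposed as the `best` attribute.

### Identifiability of (p_v, p_c), and how the recovery experiment is built

Self-recovery experiments on synthetic references revealed a structural
feature worth documenting: the error surface has a narrow diagonal valley.
Lowering `p_c` stretches the run (the stop rule adapts the number of
sweeps), the heavy-tailed mobility then disperses agents further, and
encounter links between dispersed agents imitate the long-distance
signature of random links. At 500 agents the valley floor is flat to
within the replica noise over two to three cells, so a 7-cell design's
argmin locates the valley, not the generating cell. Three measures—all
exposed as ordinary arguments—give the experiment its power:

1. statistics are computed at the agents' initial (reference) positions
   (`measure_at = "initial"`), the analogue of users' last-known
   positions, which preserves the creation-distance signature of `p_c`;
2. the reference properties are pooled over three reference replicas
   (`pool_property_sets()`), suppressing the single-realization noise
   that otherwise shifts the whole surface coherently;
3. the full grid is scanned (`cells = "all"`).

On a continental six-city world (25–50° N, 125–70° W) with 500 agents and
3000 links, the argmin then falls on or next to the generating cell in 8
of 10 repetitions; the residual misses are the intrinsic valley tail at
very low `p_v` and `p_c` and are an honest statement about model
identifiability at this scale, not noise. On a single-region world the
cross-parameter signal equals the noise floor and no design recovers the
parameters.

`sensitivity_sweep()` re-runs the model along one parameter axis and
records the scalar summaries (and optionally all curves) per value and
replica.

## Null models

`run_s_model()` (geography only) places exactly `L_target` distinct
directed edges with ordered-pair weights `max(d, d0)^(-alpha)`
(`alpha = 0.7` by default, a typical link-probability decay; it is a free
parameter to be recovered from data). Sampling is an exponential race —
the `L` smallest `Exp(w)` arrival times — which is an exact weighted
sample without replacement at `O(n log n)` cost.

`run_l_model()` (structure only) drops geography: per sweep each agent
visits a uniformly chosen out-neighbour with probability `p_v` or idles,
and with probability `p_c` adds a random directed link; at sweep end every
unordered pair of a host's visitors creates each missing directed link
with probability `p_enc`, and each visitor's link to the host is
reciprocated with probability `q` if missing. Co-presence lasts one sweep.
Defaults `p_enc = q = 1`: the closure and reciprocation probabilities are
structural constants of the mechanism, and the mean-field integrator
consumes the same values. Clustering and reciprocity are tracked
incrementally (new-edge common-neighbour counts), so per-sweep series are
cheap and exact.

## Mean-field equations for the linking model

The integrator (`meanfield_integrate()`) advances expected counts with one
Euler step per sweep: degree counts `N_k` (union degree; in- and
out-degree are not distinguished), closed triads `T_c`, reciprocated and
non-reciprocated directed links `L_r`, `L_nr`, and the zero-out-degree
count `N_out0`. Writing `N_act` for active (degree > 0) nodes,
`K = sum_k k N_k`, and `C = T_c / T` with `T = sum_k N_k k(k-1)/2`:

- Per-edge visit rate: a neighbour of degree `k'` visits the host with
  probability `p_v / k'`; averaging `1/k'` over the edge-biased neighbour
  degree distribution gives `phi = p_v (N_act - N_out0) / K` (visitors
  must have out-neighbours, hence the `N_out0` correction).
- Encounters: a host of degree `k` receives `Binomial(k, phi)` visitors,
  so the expected co-visitor pairs per host are
  `S = sum_k N_k C(k,2) phi^2 / N_act` (`expected_encounters()`), and
  `E = S N_act` per sweep. `S` is zero with no visits or no hosts and
  non-decreasing in `p_v`.
- Closing links: an encounter creates the union link with probability
  `p_u = 1 - (1 - p_enc)^2`, discounted by `1 - C` for pairs already
  connected (two co-visitors are two random neighbours of the host, and
  `C` is precisely the probability such a pair is linked).
- Closed triads grow only through visits (random-link closures are
  neglected, their measured share being ~10%):
  `dT_c = 3 [ (M + m_bg + m_nb) p_u E (1 - C) + p_u^3 E3 (1 - C) ]` where
  `M = 1` is the host triangle (a lower bound by construction), `m_bg =
  sum_k N_k k^2 / N_act^2` the uncorrelated-wiring common neighbours of
  two uniformly chosen active nodes, `m_nb = (K2/K - 2) C^2` (`K2 = sum
  k^2 N_k`) the host's other neighbours linked to both co-visitors under
  independence, and `E3 = sum_k N_k k(k-1)(k-2)/6 phi^3` the same-sweep
  visitor triples, whose pair links close one extra triangle per triple.
- Links: random links enter non-reciprocated (`n p_c` per sweep);
  encounters create mutual pairs with probability `p_enc^2` (two
  reciprocated links) or a single direction with `2 p_enc (1 - p_enc)`;
  a visit along a non-reciprocated out-link converts it with probability
  `q`, at rate `q p_v (N_act - N_out0) L_nr / (L_r + L_nr)` (each
  conversion moves one link from `L_nr` and adds two to `L_r`).
- Degrees: the per-step promotion probability is
  `g_0 = 1 - (1 - p_c)^2` at degree 0 (creating or receiving a random
  link) and `g_k = g_0 + 2 p_u E (1 - C) / N_act` for `k >= 1` (the
  encounter-link incidences spread over the active nodes); the master
  equation `N_k <- N_k - g_k N_k + g_(k-1) N_(k-1)` conserves mass up to
  the `k_max` cutoff, with leakage monitored and an error raised beyond
  `1e-6 n`.
- Zero-out-degree correction: degree-0 nodes that receive a random link
  enter `N_out0` at rate `p_c (1 - p_c) N_0`; they leave by creating
  their own link (`p_c`) or by being visited and reciprocating
  (`q phi` per in-edge, with in-degree ~1 for such nodes).

Higher-order multi-link terms are neglected, as the mechanism warrants at
these parameter scales. Validation against ten simulation replicas
(`n = 2000`, `p_v = 0.5`, `p_c = 0.05`, 200 sweeps) puts the final
clustering coefficient and reciprocity within a few percent of the
simulation; the scarce-random-link regime (`p_c < 0.01`) is flagged
`expected_degraded` by `compare_to_simulation()` — there the degree–degree
correlations built up by repeated friend visits break the uncorrelated
approximation, the known weak spot of this analysis.

## Numerical and design notes

- Tie-breaks: equal-timestamp check-ins resolve to the last file
  occurrence; error-surface ties resolve to the first cell in row-major
  order.
- Degenerate inputs: zero-population rasters, all-`NODATA` grids, empty
  annuli, empty networks and mutually exclusive dyads (overlap 0/0) are
  either errors or excluded-by-definition cases, each pinned by a test.
- The `D` floor (1 m) keeps triangle disparity defined when visits
  co-locate nodes.
- Random-link draws retry at most 50 times, then forfeit that activation,
  so dense networks terminate.
- Problem sizes used by the test suite: worlds of 10^2–10^3 agents with
  10^2–10^3.5 links for behavioural checks, 2000 agents for the
  spatial-model slope recovery and the mean-field comparison, 500 agents
  for the calibration recovery experiment — the smaller countries' scale
  of the empirical datasets the model family targets.

## Limitations

- The identifiability valley above means point estimates of
  `(p_v, p_c)` from a single small network carry a direction of near
  indifference; report the valley, not just the argmin.
- The synthetic worlds do not reproduce empirical city-size distributions
  or coastline effects; empirical rasters in ESRI ASCII format drop in via
  `read_population_raster()`.
- Temporal statistics (growth of unique visited locations beyond the
  linearity check) are out of scope.
- The mean-field treatment covers the linking model only; the coupled
  model has no analytic counterpart here.
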