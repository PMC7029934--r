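---
title: "Modelling elver passage through studded eel tiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling elver passage through studded eel tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eelpass)
```

## The problem

Juvenile European eels (elvers, *Anguilla anguilla*) migrating upstream are
blocked by weirs and similar in-stream barriers. Eel passes — sloped ramps
lined with studded synthetic tiles — slow the near-bed flow enough for
elvers to swim up. Whether a given installation works depends on the
interplay of installation angle, unit discharge, pass length and the
swimming capability of the elvers expected to use it. `eelpass` provides
two agent-based models of that interplay on gridded near-bed velocity
fields, plus everything needed to feed and summarise them.

The package operates on a regular raster (0.5 mm cells by default) of the
time-averaged velocity magnitude sampled on a plane 3 mm above the tile
bed — the height at which near-bed speeds peak and which matches an
elver's body diameter. Row 1 of every grid is the upstream success line;
the last row is the downstream spawn line.

## Classification and connectivity

A field is classified against a threshold speed, normally the median burst
swimming speed of the elver length of interest: a cell is *passable* when
its speed is strictly below the threshold, *impassable* when the speed is
greater than or equal to it, and *boundary* when it holds no water (studs,
walls). Passable-area fractions summarise a classified field, but area
alone overstates usability: ascent requires a continuous chain of passable
cells. `has_continuous_path()` answers that with a breadth-first search
over the first-order Moore (8-neighbour) adjacency — deliberately the same
adjacency the movement models use, so "a path exists" is exactly "an
automaton could in principle ascend".

## The cellular-automata model

`run_ca()` spawns automata (default 1000) uniformly on the non-boundary
cells of the downstream edge and moves each one independently, one cell
per timestep, until it reaches the upstream edge or a cap of 10,000
timesteps. At each move the eight Moore neighbours are partitioned into
upstream (3 cells), cross-stream (2) and downstream (3) groups; boundary
and impassable cells are removed, and the destination is drawn uniformly
from the highest-priority non-empty group (upstream first in normal mode).
If every group is empty the automaton stays put, and the move still
counts.

Culs-de-sac would trap a purely greedy walker, so a stuck rule mirrors
observed fall-back behaviour: once an automaton's net streamwise progress
over its trailing 20 moves is 2 cells or fewer, it reverses its priorities
(downstream first) for exactly 30 forced fall-back moves, after which the
window buffer resets and normal ascent resumes. Three readings of this
rule were genuinely open and are resolved as follows:

* *Rolling window.* Progress is assessed every move once the window is
  full (the alternative, disjoint 20-move blocks, is available via
  `ca_config(stuck_mode = "block")`). An oscillating automaton trapped in
  a dead end covers a large gross distance but no net distance; a net
  measure with a rolling check catches it within one window.
* *Suspended assessment during fall-back.* Otherwise the rule would
  re-trigger immediately on exit, before the automaton has a full window
  of normal moves to establish a new route.
* *Domain edge.* An automaton forced downstream at the spawn row simply
  has no downstream neighbours; it cannot leave the domain, keeping the
  agent count fixed.

Ties inside a group are broken uniformly at random; a single global
generator is seeded once per run and consumed in fixed agent-major order,
so a run is bit-reproducible from its seed.

## The individual-based model

The CA model is homogeneous: all automata share one threshold, so results
polarise towards 0% or 100%. `run_ibm()` instead assigns each agent its
own burst swimming speed, drawn once at creation from a lognormal
distribution, and accounts for time. A destination is viable for an agent
exactly when that agent could out-swim it (burst speed strictly above the
water speed at the destination centroid, for upstream and cross-stream
moves), so each agent effectively carries its own classified field. Each
move costs

* upstream / cross-stream: `distance / (burst_speed − water_speed)`,
* downstream (fall-back): `distance / (burst_speed + water_speed)`,

with distance one cell edge for orthogonal moves and √2 cells for diagonal
ones (Euclidean centroid distance; `ibm_config(diagonal_factor = 1)`
switches to uniform cost). An agent whose accumulated swim time exceeds
the 20 s burst-endurance budget is exhausted and fails. Three further
choices the underlying mechanism leaves open:

* Water speed is the scalar magnitude at the destination centroid for
  every direction; no directional projection is attempted.
* Downstream fall-back moves are flow-assisted and still accrue time
  (symmetric with the upstream formula); `fallback_time_mode = "free"`
  makes them free for sensitivity analysis.
* An agent with no viable neighbour holds station and accrues no swim
  time that step — the budget measures bursting effort, and a holding
  elver is not bursting. The stuck rule eventually routes it elsewhere.

Passed agents record their ascent time, which converts to the maximum
pass length they could have ascended on the 20 s budget,
`L_max = simulated_length × 20 / ascent_time`, exploiting the fact that
flow conditions vary little along the pass. Failed and exhausted agents
contribute `L_max = 0`, so a design-chart target efficiency above the raw
pass rate correctly maps to "no length achieves this".

## The burst-speed model

Swimming-performance data for elvers are published as per-length quantile
triples (10th, 50th, 90th percentile burst speed). A lognormal has two
parameters, so the triple over-determines it; `fit_lognormal()` pins the
log-median (`meanlog = log(q50)`) — the median is the natural central
speed — and sets `sdlog` to the average of the two one-sided tail
estimates, which is the least-squares compromise in log-quantile space and
exact for log-symmetric triples. Quantiles at untabulated lengths are
linearly interpolated; extrapolation outside the measured length range is
refused rather than guessed.

The quantile table shipped in `inst/extdata/` is **synthetic**: the
original lookup tables are licensed and not reproduced. The placeholder
values grow smoothly with length (roughly 4–8 body lengths per second)
and were chosen once so that the qualitative regimes are realistic —
median speeds let all lengths ascend the validated installation while the
10th-percentile speeds of small elvers sit below its fast-lane velocities.
They carry no biological authority; replace the file for real
assessments.

## The synthetic flow-field generator

The downstream models need fields like those a CFD solver produces, so the
generator emulates the solver's *output* — not its physics — for the
small-stud sub-domain of a dual-density tile (tapered studs, 14.8 mm base
/ 11.7 mm top on 45.45 mm centres, 50 mm high; the large-stud variant
reuses the same machinery with its share of the 45:83 discharge split).

Bulk conditions come from a Manning-type closure,
`U = (1/n_cal) · h^(2/3) · sin(θ)^(1/2)` with `U·h = q_eff`, solved by 1-D
root finding. Two constants are calibrated once at the validated
installation (11°, nominal 3.33 × 10⁻³ m² s⁻¹, observed 0.299 m s⁻¹ over
5.58 mm): the roughness `n_cal ≈ 0.0460` and the sub-domain discharge
fraction `q_fraction ≈ 0.501` — the nominal unit discharge is shared
between the small- and large-stud lanes, so the modelled sub-domain
carries only part of it. Both are derived in `manning_calibration()`
rather than hard-coded. Outside the anchor the closure is an
interpolation device: smooth and monotone in angle and discharge, but not
validated pointwise.

The spatial pattern multiplies a unit shape by the bulk speed: a Gaussian
stagnation deficit ahead of each stud, an exponentially decaying wake
deficit behind it, stud footprints (tapered diameter interpolated to the
sampling height) and one-cell walls as nodata, then rescales so the
wetted mean equals `U` exactly — which is also what creates the
convergence maxima between stud columns. Stud rows are staggered so that
shielded lanes sit at the walls and centreline and fast lanes at one- and
three-quarter width, the pattern observed over small studs. The deficit
amplitudes (stagnation 0.7, wake 0.5 with a two-diameter decay length)
are free calibration constants, chosen once so the streamwise-averaged
spanwise profile at the anchor brackets the observed shielded-lane
minimum (≈0.26 m s⁻¹) against a mean of 0.299 m s⁻¹; the observed
fast-lane maximum (≈0.37 m s⁻¹) is underestimated (≈0.33) — a known
limitation of this kernel family. The depth field is anticorrelated with
speed (deep sheltered lanes, shallow fast lanes) and rescaled to close
`U·h = q_eff`. Optional multiplicative lognormal noise is off by default
and seeded when on.

What the generator does *not* emulate: vortex shedding and any
unsteadiness (fields are time-averages by construction), wake–stud
interaction, free-surface dynamics, and numerical artefacts of a real
solver. Tests passing on synthetic fields therefore validate the
*models*' mechanics and trends, not the hydrodynamic fidelity of any real
tile.

## Numerical and testing choices

* Grid files are plain delimited text with `#` headers and a negative
  nodata sentinel, so they round-trip bit-exactly and can never confuse
  nodata with a real speed.
* Classification uses strict `<` for passable; a cell at exactly the
  threshold is impassable. The same strictness makes a destination whose
  speed equals an agent's burst speed non-viable.
* The movement engines are compiled (Rcpp) for speed but draw from R's
  RNG, and a pure-R reference engine consumes the identical draw
  sequence; the suite asserts the two agree element-for-element, which
  guards the compiled code against silent divergence.
* Scattered-sample regridding is piecewise-linear on a Delaunay
  triangulation (`interp`), with convex-hull exteriors as nodata; it
  reproduces affine fields exactly, which the suite exploits as an
  oracle.
* Degenerate inputs error early and specifically: collinear regrid
  samples, empty averaging windows, all-boundary spawn rows, grids too
  coarse to resolve a stud, lengths outside the quantile table.
* Simulation sizes in the test-suite are scaled down (passes of
  0.04–0.125 m, 50–2000 agents) — chosen so the whole suite runs in
  seconds while binomial noise stays well inside the asserted slacks
  (e.g. 3 percentage points on trend comparisons at 400 agents, where the
  standard error is at most ~2.5).

## Known limitations

Agents occupy single 0.5 mm cells and may thread one-cell-wide passages a
real elver could not; exhaustion is a pure time budget that ignores drag
and recovery; crawling/climbing, predation, motivation and pass-finding
are out of scope; and all conclusions drawn from shipped data inherit the
synthetic quantile table's placeholder status.
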