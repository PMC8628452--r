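---
title: "Expression-constrained flux prediction with a fitted proportionality constant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-constrained flux prediction with a fitted proportionality constant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efluxpc)
```

## The model and its assumptions

Flux balance analysis treats metabolism as a linear program: find fluxes
$v$ maximizing the biomass reaction subject to steady-state mass balance
$S\,v = 0$ and bounds $lb \le v \le ub$. `efluxpc` tightens the bounds of
gene-associated reactions from one condition's transcriptome in two steps:

$$g_{\mathrm{norm},i} = \frac{g_i}{g_{\max}}\,\delta,$$

where $g_i$ is the (upstream-normalized) expression of gene $i$,
$g_{\max}$ the maximum over all genes in the condition, and $\delta$ a
single global proportionality constant (PC) in flux units; and a GPR
mapping in which isozymes (OR) add their scores and complex subunits (AND)
contribute their minimum. A reaction scoring $b$ is bounded to $(0, b)$ if
irreversible and $(-b, b)$ if reversible.

Three assumptions are doing the work. First, transcript abundance is an
upper-bound proxy for enzyme capacity, not a flux predictor in itself:
constraints cap flux, they do not force it. Second, a *single* PC stands in
for every gene-specific chain of effects (translation efficiency,
degradation, kinetics); this is a deliberate phenomenological
simplification that buys one extra degree of freedom, fitted to one
systems-level measurement, instead of thousands of unknowable ones. Third,
the cell is assumed to grow near-optimally given those caps, so biomass
maximization selects the operating point.

Because min and sum are positively homogeneous, multiplying all gene
scores by $\delta$ multiplies every reaction score by $\delta$: the
feasible polytope grows monotonically with $\delta$, predicted growth is
non-decreasing and continuous in $\delta$, infeasibility (if maintenance
demands exist) occupies a prefix of the PC axis, and a plateau appears
once every expression bound exceeds what other constraints allow. These
four facts — all exercised in the test-suite — are what make the PC
identifiable from a single growth measurement below the plateau.

## Calibration

`fit_pc()` scans a coarse grid (default 61 points over $[0, 600]$, the
range over which the growth curve of typical microbial datasets reaches
its plateau) and then bisects inside the bracketing interval. Two choices
deserve justification:

* **Left intersection.** Growth being non-decreasing, the set of PCs
  matching the measurement can be an interval (exactly so when the
  measurement equals the plateau value). The smallest matching PC is
  returned: it is the most-constrained model consistent with the data,
  i.e. the one that extracts the most information from expression.
  Consequently `fit_pc(..., measured = plateau growth)` returns the
  plateau onset.
* **Bisection runs to the δ-interval criterion** (default width
  `1e-3`), with the growth tolerance (default `1e-3` h⁻¹, below the
  precision of chemostat dilution-rate settings) used for bracketing and
  for the final fit/unreachable verdict. Stopping on the growth tolerance
  alone would be cheaper but surrenders PC accuracy wherever the growth
  curve is shallow ($d\mu/d\delta < 0.1$ makes a `1e-3` growth gap
  compatible with a PC error above `1e-2`), which would break the
  parameter-recovery guarantee the tests enforce. Each extra bisection
  step is one LP, so the cost is negligible.

Measurements above the plateau cannot be matched by any PC; the fit
reports `at-plateau-unreachable` with the plateau diagnostics rather than
returning the boundary value as if it fit. A model infeasible across the
whole range (e.g. maintenance demand exceeding what uptake allows) reports
`infeasible-everywhere`.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| PC range | `[0, 600]` | flux per unit normalized expression | wide enough that the plateau check can verify saturation; the scan warns if growth is still rising at the top |
| coarse step | 10 | PC units | 61-point scan; bisection supplies the precision |
| growth tolerance | `1e-3` | h⁻¹ | below chemostat dilution-rate precision |
| δ interval | `1e-3` | PC units | final bisection width; PC recovery to `1e-2` with margin |
| missing-gene policy | `"max"` | — | an unmeasured gene is treated as maximally expressed so it never over-constrains its reaction; `"zero"` and `"error"` available |
| objective fraction | 0.999 | — | sampling at strictly 1.0 collapses the polytope onto the optimal face; 0.999 keeps it full-dimensional while staying "at maximum growth" for practical purposes |
| sampler defaults | 10 000 points, thinning 200 | — | conventional ACHR settings for genome-scale work; tests and the acceptance script use smaller thinning on low-dimensional polytopes, where mixing is immediate |

Other resolved design points: $g_{\max}$ is computed per condition (the
conservative reading; a global maximum across conditions can be supplied
via `scale_expression(..., g_max =)` for cross-condition comparability);
probe sets collapsing to one gene are resolved by max before GPR
evaluation, never inside it; OR-sums are not capped even though a sum of
normalized values can exceed 1 — no cap is part of the scheme's
definition, and capping would break homogeneity; reactions curated to
$[0, ub]$ bounds count as irreversible for the $\pm b$ rule regardless of
any reversibility flag in the source file; exchange reactions are exempt
from expression constraints by default because their bounds carry measured
uptake limits and exchange pseudo-reactions have no genes
(`constrain_exchanges = TRUE` covers non-standard models that attach GPRs
to transport-like exchanges); and if a score undercuts a positive
irreversible lower bound (a maintenance demand), bounds are tightened to
the score with a warning and the solver, not the bound-setter, reports the
resulting infeasibility.

## Numerical choices

**LP kernel.** All flux LPs run through a single interface backed by a
dense two-phase primal simplex with Bland's anti-cycling rule
(`R/simplex.R`). The LPs this package generates are small but harshly
degenerate — blocked reactions give zero-width bounds, mass-balance rows
have zero right-hand sides — and Bland's rule trades speed for guaranteed
termination on exactly such inputs. Fixed variables are eliminated before
the solve; equality rows are sign-normalized; all bounds are finite
(non-finite inputs are clamped to ±10⁶), so unboundedness cannot occur.
The kernel is validated in the test-suite against brute-force
vertex enumeration. Dense tableau arithmetic is the right trade-off for
the fixture-scale models the package targets; genome-scale
reconstructions would want a sparse backend behind the same interface.

**Sampler.** `achr_sample()` implements artificial-centering hit-and-run:
directions are drawn as $y - s$ with $y$ a random warm-up column and $s$
the running centre (the mean of the warm-up points and all accepted
iterates); each new point replaces a random warm-up column and updates
$s$. Warm-up points are vertices of LPs with randomized objectives (first
minimizing and maximizing each coordinate, then random Gaussian
objectives), which spans the polytope faster than a plain hit-and-run
burn-in. Two numerical details matter:

* Directions are projected onto the null space of the equality constraints
  on *every* iteration (via a rank-tolerant SVD, since stoichiometric
  matrices carry conserved moieties). Without this, the tiny constraint
  error of stored points re-enters through direction vectors scaled by the
  step length and compounds geometrically — on a test segment the walk
  visibly left the constraint within a few hundred iterations. With it,
  feasibility stays at machine precision and a periodic minimal-norm
  reprojection of the iterate (every 1000 steps) handles the rest.
* The step interval along a direction is computed by a per-coordinate
  ratio test ignoring coordinates with $|d_i| \le 10^{-12}$; an empty
  interval beyond `1e-6` triggers clamping, reprojection and a warning
  rather than silent acceptance. A zero direction ($y = s$) is resampled.

A fully determined polytope (all fluxes pinned) is detected at warm-up,
warned about, and sampled as the single repeated point. Sampling is
bit-reproducible given the warm-up seed and settings.

## What the fixture generator emulates — and what it does not

`generate_toy_model()` builds linear pathways (substrate exchange →
transport → conversions → biomass sink) with optional overflow branches
ending in secretion exchanges, configurable GPR shapes (single gene,
two-gene complex, isozyme pair, mixed), a tunable fraction of reversible
steps, and an optional GPR-less maintenance drain whose positive lower
bound makes low-PC models genuinely infeasible.
`generate_synthetic_expression()` draws log-normal levels around a high
(100) and a low (1) mean with configurable coefficient of variation —
log-normal being a generic positive-valued model for expression; the
defaults (80 % active genes, CV 0.2) give profiles whose normalized scores
spread over the interval without collapsing to 0/1.

These fixtures reproduce the *structural* features the method's
correctness depends on: GPR evaluation, the bound rules, monotone growth
in the PC, plateau behaviour, identifiability below the plateau, and
overflow secretion at fixed growth. They do not emulate genome-scale
properties — thousands of coupled reactions, cofactor balancing, loops,
realistic biomass compositions, or correlated expression — so passing
tests demonstrate the algorithm's correctness, not predictive accuracy on
real organisms. The problem sizes exercised are deliberately small: chains
of 2–5 steps (≤ ~12 reactions), 61-point PC scans over 20 random models,
50 parameter-recovery fits, and 10⁴-point sampling runs on 2-dimensional
polytopes.

## Known limitations

* One global PC. Gene-specific constants would subsume kinetic diversity
  but are unidentifiable from a single phenotype; the container records
  the single δ and the algebra (homogeneity) only holds globally.
* Calibration needs a measured growth below the plateau; conditions whose
  network is unconstrained by expression (measurement at or above the
  plateau) yield only a lower bound on the PC (the plateau onset).
* FBA returns one arbitrary optimal vertex under degeneracy; all
  downstream flux predictions therefore come from the sampler, never from
  the single FBA solution.
* The sampler does not remove thermodynamically infeasible loops and
  offers no convergence diagnostics beyond the test harness's
  distributional checks.
* SBML support covers the fbc and COBRA-notes dialects that genome-scale
  reconstructions circulate in, not full SBML semantics (no units,
  rules, or events), and writing targets the package's own round-trip.
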