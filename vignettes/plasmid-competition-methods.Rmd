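---
title: "Methods: plasmid competition dynamics and streamlining detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasmid competition dynamics and streamlining detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidrace)
```

This vignette is the package's own account of its models, estimators and
numerical choices: what is assumed, which knobs matter, and what the
synthetic-data validation does and does not establish about real data.

## The competition model

We track densities (cells per unit volume) of four compartments in a
well-mixed population: plasmid-free cells $N_0$, cells carrying only the
wildtype plasmid $N_W$, only the mutant plasmid $N_M$, and co-infected
cells $N_{WM}$, with total $T$. Cells replicate at maximal rate $\rho$
with logistic crowding $1 - T/K$ and die at rate $\gamma$; plasmid
carriage discounts replication by a factor $1-c$. Conjugation is
mass-action: plasmid $i$ exerts a force of infection
$\lambda_i = \beta_i\,(N_i + N_{WM}/2)$ — co-infected cells conjugate at
the same overall rate as single carriers and transmit either plasmid
with probability 1/2. A plasmid-carrying cell is only $1-k$ times as
susceptible to a second plasmid as a free cell (entry exclusion). During
replication a co-infected cell may lose all copies of one variant
(probabilities $s_W$, $s_M$, $s_W + s_M \le 1$), reverting to single
carriage; and conjugation into a co-infected cell displaces the resident
variant with probability 1/2, returning the cell to single carriage of
the incoming plasmid. Optionally, plasmid-free cells flow in at rate
$\epsilon$.

The mutant's transmission advantages are expressed as fold-changes over
the wildtype: horizontal $a_H = \beta_M/\beta_W$ and vertical
$a_V = s_W/s_M$ (the *wildtype* is lost from co-infected cells more
often when $a_V > 1$). `with_advantages()` builds parameter sets this
way; the symmetric parametrisation guarantees structural neutrality: at
$a_H = a_V = 1$ with a symmetric initial state the two plasmids'
trajectories are identical to machine precision (this is a unit test).

### Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `rho` | maximal replication rate | 1/time | 1 |
| `c` | plasmid fitness cost | — | 0.1 |
| `gamma` | death rate | 1/time | 0.1 |
| `K` | carrying capacity | cells/volume | 1 |
| `beta_W`, `beta_M` | conjugation rate constants | volume/cell/time | 1 |
| `s_W`, `s_M` | per-replication loss probabilities | — | 0.1 |
| `k` | entry-exclusion strength | — | 0.99 |
| `epsilon` | influx of plasmid-free cells | cells/volume/time | 0 |

Time units are arbitrary throughout; no unit-conversion layer is
provided. All simulations start from the wildtype single-plasmid
equilibrium $N_W^\ast = K\,(1 - \gamma/((1-c)\rho))$ — $8/9 \approx
0.89$ at the defaults — plus a co-infected inoculum $N_{WM} = 0.01$.

### Why displacement-on-reinfection is part of the default model

The four base flux lines alone (available via
`coinfection_displacement = FALSE`) have a qualitative pathology: the
co-infected compartment acts as a refuge. Cells carrying the winning
plasmid are continually re-infected by the loser (at the residual rate
$1-k$), and segregational loss then regenerates pure carriers of the
loser. For weak advantages this balance settles into a *stable interior
equilibrium* — e.g. at $a_H = 1.2$, $a_V = 1$ the wildtype persists at
$N_W \approx 0.20$ indefinitely (the Jacobian there has strictly
negative eigenvalues; this coexistence is itself a regression test). The
displacement fluxes $(1-k)\,N_{WM}\lambda_i/2$ close that loop:
re-infection of co-infected cells then erodes the rarer variant, and any
non-null advantage leads to eventual replacement, with times that
shorten as the advantage grows. Since the latter behaviour is the
modelling result the package exists to explore, displacement is the
default and the reduced variant is retained as an explicit flag for
sensitivity analysis.

### Replacement times and sweeps

Replacement is an event: the first time wildtype-carrying cells
($N_W + N_{WM}$ by default; configurable to $N_W$ alone) fall below a
threshold, either an absolute density (default 0.01 cells per unit
volume) or a relative frequency of all cells (default 1%, used by the
per-parameter sweeps). The frequency criterion is taken relative to
*total* cells, including plasmid-free ones; with $\epsilon = 0$ and the
standard initial condition the two criteria classify runs identically
away from threshold-boundary cases (tested).

Runs that never cross before `t_max` return `Inf` — a deliberate
sentinel distinct from a crossing at `t_max`. The default horizon
`t_max = 1e5` time units is far above every finite replacement time on
the default advantage grid (the slowest corner cells sit near
$4\text{–}7 \times 10^4$).

`sweep_advantages()` scans the $(a_H, a_V)$ plane;
`sweep_influx()` scans $(a_H, \epsilon)$ at $s_W = s_M$;
`sweep_parameter()` repeats the advantage sweep at alternative values of
`beta_W`, `s_M` or `k`, keeping dependent rates consistent
($\beta_M = a_H\beta_W$, $s_W = a_V s_M$). Grid cells whose implied
$s_W + s_M$ exceeds 1 are marked invalid (`NA`) rather than silently
clamped.

### Numerical choices

Integration uses `deSolve`'s `lsodar` (adaptive, stiffness-switching)
with `rtol = 1e-8`, `atol = 1e-10`; replacement crossings are located by
the integrator's root finder on dense output, so event times do not
depend on the requested output grid. Event times agree within 1% with a
brute-force fixed-grid scan at 20,001 points (tested), and the
$a_H = 2$ replacement time is frozen as a regression value
(2249.8988). States are clipped to 0 only within $10\,\mathrm{atol}$ of
zero; larger negative excursions abort with an error instead of being
hidden. The all-zero state is absorbing (without influx), and with
$\epsilon = 0$ the total density never exceeds $\max(T(0), K)$ beyond
tolerance (property tests).

### Serial transfer

`simulate_serial_transfer()` extends the continuous model to daily
batches: integrate for `day_length` (default 24 time units), dilute all
compartments by `dilution_factor` (default 100), and optionally replace
a fraction of the inoculum with plasmid-free immigrants. With immigrant
ratio $r$ the new inoculum is $1/(1+r)$ parts diluted resident culture
and $r/(1+r)$ parts plasmid-free cells at the same total density — the
natural reading of mixing overnight cultures of similar density in an
$r{:}1$ ratio. Dilution alone is frequency-preserving (tested). This
mode is an extension for mirroring passage experiments and is not used
by the acceptance checks.

## Coverage deconvolution

A clone can carry a mixture of full-length plasmid copies and
streamlined copies from which the AMR region has been deleted. Per-base
unique-read depth then shows a step: the backbone is covered by all
copies, the AMR region only by full-length ones. With depths normalised
by the chromosome mean (copies per chromosome):

- backbone relative coverage $\approx n_{full} + n_{streamlined}$,
- AMR relative coverage $\approx n_{full}$,

so `estimate_mixture()` returns $n_{full} = $ AMR, $n_{streamlined} = $
backbone − AMR, the relative AMR frequency $r = $ AMR/backbone (capped
at 1) and the streamlined fraction $1 - r$. When noise puts AMR above
backbone, $n_{full}$ is clamped to the backbone value so that
$n_{full} + n_{streamlined}$ always equals the backbone relative
coverage exactly. Under the two-molecule model all streamlined copies
carry the derived `copA*` allele, so the allele frequency among reads
should equal the streamlined fraction; `copA_consistency()` returns the
residual, and across a synthetic panel the $r$-vs-frequency relation has
slope $-1$, intercept 1, $R^2 > 0.95$ (tested).

Coordinates are 1-based inclusive throughout; `read_depth_table()` reads
the standard 3-column depth dialect and converts nothing, treating
absent positions as depth 0. The default regions on the 99,378 bp
reference are backbone = {1–5570, 41387–99378} and AMR = {6200–15335,
15950–40664}; the gaps between them contain repeated IS sequence where
unique-read depth is unreliable, so they belong to neither region.
`region_set()` makes the intervals fully configurable, and BED input is
converted from 0-based half-open on read.

### Deletion calling

`detect_deletion()` median-smooths the depth (window 501 bases,
`stats::runmed`), places a threshold midway between the backbone level
(median of the smoothed depth) and the lower robust level (median of
smoothed values below the midpoint between the backbone level and the
profile minimum), and reports the longest contiguous below-threshold run
of at least 5,000 bases (all qualifying runs are exposed too). A call
requires the level separation to exceed twice the noise scale (MAD of
the smoothed depth outside the candidate run); uniform profiles—
noiseless or Poisson—yield no call. For a clean step the reported
boundaries are exact (the running median flips where the window majority
flips); under Poisson noise at ≥ 20× they stay within the smoothing
window. Calls are invariant to global depth scaling. The window default
(501) trades boundary resolution against noise at the depths typical of
these data; the minimum length (5 kb) is far below the ~35.6 kb deletion
of interest but large enough to ignore local dropouts.

## Assay estimators

**Transfer efficiency.** $\gamma_{transfer} = T/(D\,R\,t)$ in
mL/cell/h, computed from *endpoint* donor and recipient densities (a
geometric-mean variant of the denominator is a documented non-default
alternative; with negligible growth during a 1 h assay the two
coincide). When no transconjugant colony is observed, the density is
replaced by the 0.5-colony detection threshold and the estimate is
flagged as a censored upper bound; censored flags propagate to
aggregates. The estimator ignores transconjugant growth and
re-conjugation; against the mass-action generator at
$\gamma = 10^{-12}$, $D_0 = R_0 = 10^8$, $t = 1$ h this bias is below
the plating noise and recovery is within 10% (tested; the generator can
switch on growth and re-conjugation to quantify the bias).

**Growth rate.** The sliding log-linear window estimator: blank-subtract,
drop readings at or below a positivity floor ($10^{-4}$ above blank;
excluded points break window contiguity rather than being clamped), and
fit OLS of $\log(\mathrm{OD})$ on time over every window of $h = 8$
consecutive readings between 2 and 10 h post-inoculation, returning the
maximal slope with its window, slope standard error and $R^2$. $h$
counts readings (not hours), the convention of sliding-window growth-rate
fitting; it is configurable. The estimate is invariant to positive
scaling of the whole curve once the blank is zero.

**Proportions.** Selective/nonselective plate-count ratios, capped at 1.
Counts from the two plates are independent Poisson, so conditional on
their sum the selective count is binomial in $p = f/(1+f)$; the exact
Clopper–Pearson interval on $p$ is transformed back to the fraction
scale. Coverage of a true fraction 0.3 at ~100 colonies is ≥ 95%
nominally (tested at ≥ 90% to allow Monte-Carlo slack).

## Synthetic data: what it emulates, and what it does not

All generators are deterministic given a seed and record their ground
truth as an attribute, so estimator tests consume only the observable
part.

- `simulate_coverage()`: per-base Poisson (or negative-binomial,
  variance $= \textit{overdispersion} \times$ mean) depth around the
  two-level expectation; sharp deletion boundaries by default, as for an
  IS-bounded recombination deletion, with optional boundary blur for
  stress-testing the caller. Real depth has autocorrelated structure
  (GC, mappability, repeats) that is *not* modelled; passing tests
  demonstrate correctness of the estimators under the stated noise
  model, not robustness to mapping artefacts.
- `simulate_conjugation()`: mass-action kinetics integrated exactly,
  then Poisson colony counts at the configured dilutions (defaults:
  transconjugants plated undiluted at 0.1 mL, donors/recipients at
  $10^4$-fold dilution, 4 replicates, matching a typical 1 h assay
  design).
- `simulate_growth_curve()`: lagged-logistic OD with *proportional*
  Gaussian read noise (`noise_sd` is a CV; default scenario 0.5%).
  Proportional error is the appropriate working model within the
  reader's linear range, and error propagation through an 8-point,
  35-minute log-linear window shows why: an *additive* noise floor of
  the same magnitude makes the window slope unidentifiable at the low
  ODs where a logistic curve's log-slope is maximal, so no single-well
  window estimator could meet a 5% recovery target there. Real readers
  do have an additive floor at very low OD; the estimator's slope
  standard error and $R^2$ diagnostics are the handle for filtering
  such windows in real data.
- `simulate_allele_counts()` / `observables_from_trajectory()`:
  binomial read and colony sampling; the trajectory observable is the
  marked-plasmid-carrying fraction $(N_W + N_{WM})/T$, counting
  co-infected cells as marked.

## Problem sizes

The test suite and analysis scripts use a 20×20 advantage grid (the
largest sweep), 5×5 grids for per-parameter comparisons, 100-seed
Monte-Carlo loops for estimator recovery, and full-length (99,378 bp)
coverage profiles; the complete suite runs in well under a minute of
integration-dominated compute. Larger grids and horizons are a matter of
passing bigger arguments; nothing in the implementation is specific to
these sizes.

## Known limitations

- Two plasmid variants only; no explicit antibiotic selection, spatial
  structure, or stochastic (birth–death) dynamics.
- The coverage model is two-molecule: clones mixing three or more
  variants (e.g. intermediate `copA*` frequencies) are interpreted as
  two-component mixtures.
- The deletion caller assumes a single dominant deletion; overlapping or
  nested deletions merge into whichever run is longest (secondary runs
  are reported but not deconvolved).
- Upstream read mapping is out of scope: depth tables are taken at face
  value, and the unique-read flag is recorded, not verified.
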