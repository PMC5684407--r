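---
title: "Snapshot kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapkin)
```

## The measurement snapkin models

In a nanopore snapshot experiment a single RNA molecule, tethered in an
α-hemolysin pore, is released to refold on one side of the membrane for a
programmed *folding time* and then pulled back through the pore under a
small reverse voltage. The time from the voltage switch to the end of the
current blockade — the *unfolding duration* — fingerprints whichever
structure the molecule had reached: each folded state unfolds with an
approximately exponential lifetime whose mean is set by its stability.
Repeating the capture many times at several folding times yields, per
folding time, a sample of unfolding durations plus a count of "no-block"
events in which the molecule was still single stranded (SS).

For the H-type T2 pseudoknot this procedure resolves five states: SS, two
hairpin intermediates (HP1 with the native long helix plus non-native loop
pairs, and the fully non-native HP2), a misfolded pseudoknot-like trap
(TS), and the native pseudoknot (PK). snapkin implements the complete
analysis chain that turns event tables into a folding pathway: log-binned
duration histograms, exponential mixture fits, time-resolved state
populations, and master-equation rate estimation — together with a
generator that simulates the experiment from a known kinetic scheme so
every stage can be validated by parameter recovery.

## Dwell-time mixtures on a log-time axis

Unfolding durations span four orders of magnitude (milliseconds to
seconds), so histograms are built in `log10(t)` with, by default, 10 bins
per decade over 0.1 ms–100 s. Counts are normalised by the total event
count `N0`, so the per-bin masses `N/N0` sum to 1 and the histogram area
equals the total folded fraction. A single exponential lifetime with time
constant $\tau$ appears on this axis as the peaked density (per unit
$\ln t$)

$$f(t) = c\, e^{(\ln t - \ln\tau) - e^{(\ln t - \ln\tau)}},$$

with maximum $c/e$ at exactly $t = \tau$; a mixture of states sums such
components, and each amplitude $c_i$ equals the area under its component.
`fit_mixture()` minimises weighted least squares between the observed bin
masses and the *exact* per-bin integral of the mixture,
$\sum_i c_i(e^{-t_{lo}/\tau_i} - e^{-t_{hi}/\tau_i})$, rather than the
midpoint density — the correct treatment at finite bin width. The Poisson
variance proxy for the weights is applied in two stages: a first pass
weighted by observed counts, then a re-solve with weights frozen at the
first pass's expected counts. Observed-count weights alone are
inefficient for slow components (near-empty tail bins carry full weight,
inflating the slowest component's replicate-to-replicate spread by
roughly half again over the raw-data likelihood bound), while
parameter-coupled expected-count weights bias it upward; frozen
expected-count weights avoid both, as verified against the package's
maximum-likelihood mode in simulation. Optimisation is
Levenberg–Marquardt on log-scale parameters with multiple starts from a
log-spaced $\tau$ grid; label switching is broken by sorting $\tau$
ascending. In *global* mode one shared set of time constants is fitted
across all folding times with per-time amplitudes — the constraint that
identifies small components in sparsely populated snapshots.

Two conventions worth stating explicitly:

* **Dead time.** Events shorter than the RC-charging transient of the
  acquisition chain are unidentifiable; both the generator and the fit use
  the same default 0.5 ms threshold. Censored events are excluded from
  `N` and `N0`, and bins that straddle the dead time are excluded from the
  fit (they are partially censored and would otherwise bias the fastest
  component upward).
* **Histogram normalisation.** The y-axis is the per-bin fraction
  `N/N0` with `N0` the total event count of the histogram; the no-block
  count used for `P0` is a separate quantity (`p0_from_events()`).

Fractional populations follow from the amplitudes and the no-block
fraction $P_0$:

$$P_i = (1 - P_0)\, c_i \big/ \textstyle\sum_i c_i, \qquad P_{SS} = P_0 .$$

An optional maximum-likelihood mode fits the same mixture to the raw
durations (dead-time truncated); it is a statistically stronger
cross-check of the histogram fit, which remains the primary, convention-
matching path.

## Master-equation kinetics

The folding states form a continuous-time Markov chain. With the
population column vector $\vec P$, $d\vec P/dt = M \vec P$, where
$M_{ij} = k_{j \to i}$ for $i \ne j$ (column = source state) and
$M_{ii} = -\sum_{j \ne i} k_{i \to j}$, so columns sum to zero and total
population is conserved. The public API uses explicit `(from, to)` edge
naming throughout to keep the subscript convention out of user code.

`solve_populations()` solves the system spectrally,
$\vec P(t) = \sum_\mu c_\mu \vec n_\mu e^{\lambda_\mu t}$, with the
coefficients fixed by the initial populations. A connected scheme has
exactly one zero eigenvalue (the equilibrium mode) and all other
eigenvalues with non-positive real part. Rate matrices are not guaranteed
diagonalisable — an irreversible chain with equal rates is already
defective — so when the eigenbasis is singular or the reconstructed
solution fails conservation checks the solver falls back to a
scaling-and-squaring matrix exponential and flags this in the result's
diagnostics. Tiny negative round-off (below 1e-9) is clipped and each
time point renormalised.

The default five-state topology is `SS <-> HP1`, `SS <-> HP2`,
`HP1 <-> TS`, `HP1 <-> PK`: HP2 shares no helix with the other folded
states, so its only exchange is with SS, and the trap TS reaches the
native PK only by detrapping through HP1. The PK -> HP1 back-rate is
included by default — the populations visibly equilibrate on the 60-s
scale, which requires a finite return path — but can be clamped to zero
via `default_scheme(pk_reversible = FALSE)` or `fit_config(fixed_edges=)`.
The default rate constants are chosen to reproduce the reported branching
fractions exactly (SS: 84.7% / 15.3% to HP1 / HP2; HP1: 6.3% to PK,
18.1% to TS, 75.6% back to SS) on a time scale where all states approach
equilibrium near 60 s; the absolute rates themselves are otherwise
unconstrained by the printed record, so they are package defaults, not
measurements.

## Rate estimation and the buffer state

`fit_rates()` estimates the rate constants from folding-time-resolved
populations by minimising the RMSD fitness

$$F = \sqrt{ \sum_i \sum_t \left( P_E^{(i)}(t) - P_T^{(i)}(t) \right)^2 / N },$$

with $N$ the total number of (state, time) data points — for five states
at six folding times, $N = 30$.

Not every molecule participates in folding: a buffer fraction
$SS_0$ (impure or extension-blocked chains) reads out as no-block at every
folding time. Before comparison the apparent SS population is reduced by
$SS_0$ and the participating ensemble renormalised to $1 - SS_0$. The
renormalisation keeps the corrected populations a probability vector;
the subtraction alone would not. $SS_0$ is fitted as a free parameter by
default (bounded in `[0, 0.25]`), since the measurement itself determines
it only indirectly; it can be frozen with `ss0_fixed = TRUE`.

Rates are parameterised on a log scale within `[1e-4, 1e3]` s⁻¹ —
positivity by construction and a scale-free search. Each of (by default)
50 starts runs bounded quasi-Newton minimisation; starts are drawn
log-uniformly over the central decades, with the scheme's own rates as
the first start. A compact seeded genetic algorithm (tournament
selection, blend crossover, Gaussian mutation) is available as an
independent cross-check of the optimum (`use_ga = TRUE`); in testing both
optimisers agree to well under a percent on recovered rates. Because six
folding times constrain eight or nine parameters only weakly, the
condition number of the numerical Hessian at the optimum is always
reported, and recovery studies use a denser (30-point) time grid where
the problem is well conditioned. `nlminb` stall codes 7/8 on flat
directions are treated as convergence, since flatness is exactly what the
condition number reports.

`pathway_report()` converts a fitted scheme into per-state branching
tables, equilibrium populations, and a ranking of simple SS-to-PK routes
by path flux (the product of branching fractions along the route).

## What the generator emulates — and what it does not

`generate_event_table()` reproduces the statistical structure the
analysis assumes: per-molecule Bernoulli($SS_0$) buffer labels, exact
Gillespie trajectories of the scheme, state capture at the programmed
folding time, exponential unfolding durations with state-specific means
(defaults 2.5 / 20 / 210 / 3500 ms for HP1 / HP2 / TS / PK), dead-time
censoring, and the 1/2/5/10/30/60-s folding-time grid at 578 events per
time. Reproducibility is per event: sub-seeds derive arithmetically from
the master seed and the event counter, so identical configurations yield
byte-identical tables.

Deliberately *not* modelled: re-equilibration during the read-out pull
(the state is sampled strictly at the folding time), voltage-dependent
unfolding rates, baseline drift, and the acquisition chain's Bessel
filter (the RC transient is handled by masking, matching how such events
are discarded in practice). Non-exponential lifetime mixtures within one
state are also absent. Passing recovery tests therefore demonstrates that
the analysis chain inverts its own forward model at realistic sample
sizes — not that real traces are free of these further effects.

The trace layer (`synthesize_trace()`, `segment_levels()`,
`classify_event()`) carries the same caveat: real event detection was
done with commercial acquisition software whose thresholds are not on
record, so the segmenter here is a stated convention — running-median
change detection at 3× the noise SD sustained for 10 samples, RC-window
masking, half-open 0-based sample indexing, and level assignment within
±2 percentage points of I/I₀ (wider than the printed level SDs of
0.5–1.6). Two-level events place the deeper Level-4 dwell at the tail 20%
of the duration.

## Operating points and preset choices

`preset()` records the characterised systems: wild type with Mg²⁺
(2.5 / 20 / 210 / 3500 ms), wild type without Mg²⁺ (TS and PK destabilised
to 80 / 1900 ms), the polyU loop mutant (2.0 / 22 / 1000 ms, three
states), and the 12-bp reference hairpin (18 ms). Two generator settings
are package choices where the record is silent: the polyU 10-s snapshot
mixture weights (0.30 / 0.25 / 0.45, folded final state dominant, as
expected after 10 s of folding) and the default buffer fraction
$SS_0 = 0.042$.

## Numerical choices and test scale

Degenerate inputs: schemes with all-zero exit rates are valid (absorbing
states persist; every event reads no-block); disconnected schemes are
rejected by name in `equilibrium_distribution()`; amplitudes are bounded
below at 1e-8 so redundant mixture components collapse instead of
destabilising the fit; over-specified fits return a near-zero amplitude
for the surplus component.

Recovery studies in the test suite run at the experiment's own scale —
578 events per snapshot, 10 seeded replicates for the wild-type mixture
recovery, 232 events for polyU, 500 for the reference hairpin, and 50
multi-starts on a 30-point noiseless grid for rate recovery; the complete
suite of 600+ assertions runs in about two minutes on one core. With
these sizes the median recovered time constants fall within the
experimentally reported SDs (±2 / ±3 / ±25 / ±330 ms) and noiseless
branching fractions are recovered to well under one percentage point.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(events_per_time = 578, master_seed = 1)
events <- generate_event_table(cfg)
report <- run_analyze(events,
                      fit_cfg = fit_config(scheme = cfg$scheme,
                                           n_starts = 20, seed = 1))
report$mixture$components       # fitted time constants, ascending
report$pathway                  # branching, routes, equilibrium
autoplot(report$rate_fit)       # populations vs master-equation curves
```

## Known limitations

* With only six folding times the full five-state rate set is weakly
  identified; treat single-experiment rate estimates as order-of-magnitude
  and inspect the Hessian condition number and per-start spread.
* The histogram fit assumes well-separated time constants (the default
  components are spaced ≥ 8×); neighbouring lifetimes within a factor of
  ~3 will merge at realistic sample sizes.
* The buffer-state correction assumes $SS_0$ is constant across folding
  times.
* Durations at the dead-time boundary are discarded, not modelled by
  truncation, which slightly under-weights (but does not bias) the fastest
  component.
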