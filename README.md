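# snapkin

Snapshot kinetic analysis of single-molecule nanopore RNA folding events.

## The problem

A nanopore "snapshot" experiment tracks how a tethered RNA folds: the
molecule refolds for a programmed folding time *t*<sub>fold</sub>, is
pulled back into the pore, and the *unfolding duration* of the resulting
current blockade fingerprints the structure it had reached. Repeating the
capture across folding times yields, for each state, a population-vs-time
curve — and from those curves, the transition rate constants of the
folding pathway. For the T2 gene-32 pseudoknot this resolves five states:
single-stranded **SS**, hairpin intermediates **HP1** and **HP2**, a
misfolded trap **TS**, and the native pseudoknot **PK**.

snapkin is for single-molecule biophysicists who want this analysis chain
as tested, scriptable code: it fits log-binned unfolding-duration
histograms with exponential mixtures, converts amplitudes to fractional
populations, and recovers rate constants by master-equation fitting — and
it ships a synthetic-data generator so the whole chain can be validated
by parameter recovery at realistic sample sizes.

## The model

* **Dwell-time mixtures.** On a log-time axis an exponential lifetime
  with time constant τ has density
  *f*(*t*) = *c* e^((ln *t* − ln τ) − e^(ln *t* − ln τ)), peaking at
  *t* = τ with value *c*/e; a snapshot's histogram is fitted with a sum
  of such components (globally across folding times, shared τ, per-time
  amplitudes *c<sub>i</sub>*). Fractional populations follow as
  *P<sub>i</sub>* = (1 − *P*₀) *c<sub>i</sub>* / Σ *c<sub>i</sub>*, with
  *P*₀ the no-block (still-unfolded) fraction.
* **Master equation.** Populations obey d*P*/d*t* = **M** *P* with
  *M<sub>ij</sub>* = *k*<sub>j→i</sub> and columns summing to zero;
  snapkin solves this spectrally (matrix-exponential fallback for
  defective matrices) and estimates rates by minimising the RMSD fitness
  *F* = √(Σ<sub>i</sub>Σ<sub>t</sub>(*P*<sub>E</sub> − *P*<sub>T</sub>)²/*N*)
  with multi-start bounded optimisation, including a buffer fraction
  SS₀ of molecules that never fold.
* **Synthetic data.** Exact Gillespie trajectories of the scheme, state
  capture at *t*<sub>fold</sub>, exponential durations per state,
  dead-time censoring, and optional multi-level current traces with a
  segmentation/classification layer for the three signature classes
  (open pore, single-level, two-level).

## Worked example

Simulate a full experiment at the wild-type operating point and analyse
it end to end:

```r
library(snapkin)

cfg    <- generator_config(events_per_time = 578, master_seed = 1)
events <- generate_event_table(cfg)
report <- run_analyze(events,
                      fit_cfg = fit_config(scheme = cfg$scheme,
                                           n_starts = 20, seed = 1))
report
#> <snapshot_report> 6 folding times, 4 mixture components
#> Time constants (ms): 2.37, 20.9, 201, 3310
#> Rate-fit fitness F = 0.01299, ss0 = 0.019

report$pathway
#> Branching fractions:
#>   from  to      rate fraction
#> 1 SS    HP1   0.414    0.812
#> 2 SS    HP2   0.0959   0.188
#> 3 HP1   SS    0.566    0.678
#> 4 HP1   TS    0.204    0.244
#> 5 HP1   PK    0.0652   0.0782
#> ...
#> Routes to the native state (by flux share):
#>   route             flux flux_share
#> 1 SS -> HP1 -> PK 0.0635          1
```

The four fitted time constants (2.37, 20.9, 201, 3310 ms) recover the
generator's 2.5 / 20 / 210 / 3500 ms states from one simulated
experiment of 578 events per folding time, and the branching
fractions recover the generating pathway (SS splits ~81/19 toward
HP1/HP2 against a ground truth of 84.7/15.3) at single-experiment
precision — the rate stage is deliberately conservative with only six
folding times, and `glance(report$rate_fit)` reports the Hessian
condition number that quantifies this. `autoplot(report$rate_fit)` draws
the population kinetics with the fitted master-equation curves.

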