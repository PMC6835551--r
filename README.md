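# tojrace

Model-based analysis of **plateaus in visual temporal-order judgments
(TOJs)**. In a TOJ an observer reports which of two targets — a *probe*
and a *reference*, separated by a stimulus onset asynchrony (SOA;
negative = probe first) — appeared first. The psychometric function of
"probe first" responses is normally S-shaped, but with dense SOA grids
and many repetitions a flat central plateau can appear. This package is
for psychophysicists who want to test, by maximum likelihood and BIC,
*whether* such plateaus are present and *which mechanism* produces them.

## The models

All three models share an exponential encoding race with rates `vp`,
`vr` (events/ms; displayed Hz = 1000×). The probe is encoded first with
probability

```
Pp1st(vp, vr, SOA) = 1 − exp(−vp·|SOA|) + exp(−vp·|SOA|)·vp/(vp+vr)   SOA < 0
                   = exp(−vr·|SOA|)·vp/(vp+vr)                         SOA ≥ 0
```

(`vp/(vp+vr)` is the Luce choice ratio). On top of this race:

* **simple** — the bare race; strictly monotone, no plateau. The null
  model (2 free parameters with `tau` fixed at 0).
* **indecision** — a range-of-indecision model: arrival differences
  smaller than `delta` ms cannot be ordered; the resulting simultaneity
  percepts are resolved "probe first" with probability `1 − xi`. The
  response probability is
  `xi·Pp1st(s+delta) + (1−xi)·Pp1st(s−delta)`, `s = SOA + tau`.
* **reset** — an encoding-reset model derived from the theory of visual
  attention (TVA): if the second onset falls within the trial's
  ineffective-exposure window `t0_trial ~ N(t0, s0²)`, both races
  restart from a common origin. With reset probability `w`:
  `w·vp/(vp+vr) + (1−w)·Pp1st(s)`.

Fitting is binomial maximum likelihood over per-SOA counts with a
bounded, seeded multi-start simplex search; models are compared by BIC
(`k·ln(n_trials) − 2·logLik`; differences ≥ 10 read as strong
evidence). A synthetic-data layer reproduces the study designs (`exp1`:
21 SOAs × 240 repetitions = 5040 trials; `exp2_neutral` / `exp2_cued`:
uneven schedules), and independent per-trial Monte Carlo simulators
verify every closed form.

## Worked example

Fit all three models to the bundled synthetic dataset (sampled from the
reset model at 60/40 Hz, `t0 = 15`, `s0 = 18`; no human data ships with
the package):

```r
library(tojrace)
csv  <- system.file("extdata", "synthetic_exp1.csv", package = "tojrace")
dat  <- read_judgment_csv(csv)[["S1:neutral"]]
fits <- lapply(c("simple", "indecision", "reset"), function(m) fit_toj(dat, m))
fits[[3]]
#> TOJ model fit: 'reset' (binomial maximum likelihood)
#>  parameter    estimate display unit  role
#>         vp  0.05599175   55.99   Hz  free
#>         vr  0.03956701   39.57   Hz  free
#>         t0 15.31796488   15.32   ms  free
#>         s0 17.51096254   17.51   ms  free
#>        tau  0.00000000    0.00   ms fixed
#> logLik -1490.55  BIC 3015.2  (4 free parameters, 5040 trials)
compare_toj(fits)
#> TOJ model comparison (5040 trials; smaller BIC wins)
#>       model n_free   loglik     bic delta_bic evidence_vs_best
#>       reset      4 -1490.55 3015.20      0.00     inconclusive
#>  indecision      4 -1491.74 3017.58      2.38         positive
#>      simple      2 -1518.92 3054.89     39.69           strong
#> preferred: 'reset'
```

Reading the output: the recovered rates (56/40 Hz) and reset window
(15.3 ± 17.5 ms) sit next to the generating values; the plateau-free
simple race is rejected with strong evidence (ΔBIC ≈ 40), while the two
plateau mechanisms are barely distinguishable (ΔBIC ≈ 2.4) — plateau
*presence* is much easier to establish than plateau *mechanism*.

Other entry points: `toj_prob()` evaluates any model curve;
`simulate_judgments()` / `parameter_recovery()` run seeded simulation
and recovery studies; `plot()`, `predict()`, `residuals()`,
`simulate()`, `logLik()`/`BIC()` work on fits; `toj_cli()` (or
`Rscript inst/cli/toj.R`) exposes `simulate` / `fit` / `compare` /
`recover` subcommands over CSV/JSON/YAML files. The methods vignette
(`vignettes/plateau-models.Rmd`) documents the models, conventions and
numerical choices in full.

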