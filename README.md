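# psmforge

Three-state partitioned survival cost-effectiveness models, starting from
nothing more than the coordinates of published Kaplan–Meier curves.

## Who this is for

Health-economic analysts routinely need a partitioned survival model (PSM)
for a new oncology therapy, but the individual patient data (IPD) behind the
trial's progression-free survival (PFS) and overall survival (OS) curves are
almost never available. The standard workaround is a three-step pipeline,
each step usually done in a different tool:

1. **Reconstruct** approximate IPD from digitized KM coordinates plus the
   published numbers at risk;
2. **Fit and select** a parametric survival function for each endpoint in
   the control arm, extrapolating beyond trial follow-up;
3. **Run the PSM**: derive state occupancy from the two curves, attach
   costs and utility weights, discount, and compute incremental
   cost-effectiveness.

`psmforge` does all three in one package, plus Cox estimation of the
between-arm hazard ratio, a proportional-hazards diagnostic, granular
posology-to-cycle resource costing, and univariate (tornado) sensitivity
analysis. A synthetic-trial generator makes the whole pipeline testable
end-to-end with known ground truth.

## The model

With survival functions $S_{PFS}(t)$ and $S_{OS}(t)$, the cohort at time
$t$ (months) splits into three states:

- progression-free: $S_{PFS}(t)$
- post-progression: $S_{OS}(t) - S_{PFS}(t)$
- dead: $1 - S_{OS}(t)$

The control arm's curves are fitted by maximum likelihood to reconstructed
IPD, choosing among eight families (exponential, Weibull, gamma,
log-logistic, log-normal, Gompertz, generalized gamma, generalized F) with
AIC $= 2k - 2\ell$ reported for each. The intervention arm is derived under
proportional hazards: $H_{int}(t) = \mathrm{HR}\cdot H_{ctrl}(t)$,
equivalently $S_{int} = S_{ctrl}^{\mathrm{HR}}$, with the HR taken from the
template or estimated by Cox regression (Efron ties). The engine uses
monthly cycles, a half-cycle correction (trapezoid form), mid-cycle
discounting at $(1+r)^{-t/12}$, and reports undiscounted and discounted
costs, life years (LY), QALYs, increments and the ICER
$= \Delta\text{cost}/\Delta\text{effect}$. If extrapolation ever drives
$S_{OS}(t) < S_{PFS}(t)$ the engine halts with a `logical-inconsistency`
error rather than silently adjusting the curves; the DSA sweep records such
scenarios as `engine-failure` rows and carries on.

## Worked example

The repository ships a small synthetic template
(`inst/extdata/example_template/`, generated by `make_template()`; the
generating parameters are in its `truth.json`). It emulates a two-arm trial
with Weibull control-arm survival, HR 0.55 for OS and 0.28 for PFS, a
weight-based drug cost in each arm during PFS (2.52 and 3.78 100-mg units
every 3 weeks at 2720€ and 2194€ per unit) and utilities all 1, i.e.
life-year mode.

```r
library(psmforge)
tpl <- system.file("extdata", "example_template", package = "psmforge")
inputs <- read_template(tpl, horizon_months = 100,
                        dist_pfs = "weibull", dist_os = "weibull")
pipe <- run_pipeline(inputs)
print(pipe)
```

```
<psm_pipeline> HR: OS 0.5500, PFS 0.2800; fits: PFS weibull (AIC 732.8), OS weibull (AIC 395.3)
  PH test OS: p = 0.7831
  PH test PFS: p = 0.2073
<psm_results> horizon 100 months, discount 0.030
  intervention  cost    278374.56 (disc    266631.31)  LY  5.2187 (disc  4.7334)
  control       cost     89578.16 (disc     88123.46)  LY  3.8435 (disc  3.5429)
  incremental: cost 178507.86, LY 1.1905
  ICER (discounted): 149,944.5 per LY [ok]
```

Reading: over 100 months the intervention adds 1.19 discounted life years
at an extra discounted cost of 178,508€, an ICER of about 149,900€ per life
year gained. The PH-test p-values (both > 0.05) show no evidence against
the constant-HR assumption in this (synthetic) trial. The tornado view:

```r
tornado_order(pipe$dsa)[, 1:6]
#>                parameter  icer_low icer_high status_low status_high      width
#> 1                  hr_os  98848.74  261176.4         ok          ok 162327.638
#> 2 cost:drug_intervention  37960.93  149944.5         ok          ok 111983.619
#> 3                 hr_pfs 213390.22  111623.5         ok          ok 101766.733
#> ...
```

Note the asymmetry of the `hr_os` bar: pushing the OS hazard ratio toward 1
shrinks the life-year gain toward zero, so the ICER grows much faster on
that side — a known property of ratio outcomes in PSMs.

The AIC menu for choosing families, and CSV outputs:

```r
pipeline_fit_menus(inputs)$os      # 8 families, AIC-sorted
write_results(pipe$results, pipe$dsa, "out/")  # results.csv, trace.csv, dsa.csv
```

## Command line

```sh
inst/cli/psmforge run --template inst/extdata/example_template \
    --dist-pfs weibull --dist-os weibull --horizon 100 \
    --hr-source template --out out/ --plots
inst/cli/psmforge fit --template inst/extdata/example_template   # AIC menu
inst/cli/psmforge dsa --template inst/extdata/example_template --out out/
```

A template is a directory of CSVs (or one `.xlsx` workbook) with sheets
`surv_probs`, `n_at_risk`, `events` (optional), `hr`, `discount`, `costs`,
`resources_pfs`, `resources_pps`, `utilities`, `dsa` (optional); see the
shipped example and `?read_template`.

## Scope

No probabilistic sensitivity analysis, no time-varying hazard ratios or
utilities, no four-state models, and the cycle length is fixed at one
month. Curve digitization itself (reading pixels off a plot) is out of
scope: coordinates are inputs.
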