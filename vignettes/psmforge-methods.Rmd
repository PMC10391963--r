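---
title: "Methods: partitioned survival modelling from digitized Kaplan-Meier curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned survival modelling from digitized Kaplan-Meier curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmforge)
```

# The problem and the model

A three-state partitioned survival model (PSM) is the workhorse of
cost-effectiveness analysis in advanced cancer. It needs only two survival
functions per arm — progression-free survival (PFS) and overall survival
(OS) — and derives state occupancy directly from them:

$$\pi_{PF}(t) = S_{PFS}(t), \qquad
  \pi_{PP}(t) = S_{OS}(t) - S_{PFS}(t), \qquad
  \pi_{D}(t) = 1 - S_{OS}(t).$$

The PSM makes no structural claim linking progression to death: the two
curves are modelled as if independent. That frugality is its appeal — the
model can be built from published trial figures — and also its central
weakness: nothing prevents an extrapolated $S_{OS}$ from crossing below
$S_{PFS}$, which is biologically impossible. `psmforge` treats such a
crossing as a hard error (`logical-inconsistency`, reporting the first
failing month). We deliberately do not clamp $S_{PFS} \le S_{OS}$ or
transfer PFS gains into OS: those ad-hoc corrections are not principled,
and silently applying them would hide exactly the situation the analyst
most needs to see. In the univariate sensitivity analysis, a scenario that
trips the guard is recorded as an `engine-failure` row and the sweep
continues — a base case can be valid while extreme scenarios are not.

# IPD reconstruction

Published KM figures give coordinates $(t_m, S_m)$ (here: monthly) and a
risk table $n_j$ at times $T_j$. Reconstruction inverts the product-limit
estimator: at a coordinate time with $n$ currently at risk and running
reconstructed survival $S_{run}$, the event count is
$d = \operatorname{round}(n\,(1 - S_m/S_{run}))$ (nearest integer, ties to
even, never negative), after which $S_{run} \leftarrow S_{run}(1 - d/n)$.
Within each risk-table interval the number censored is found by a
deterministic integer search — starting from the value implied by the gap
between predicted and published numbers at risk, expanding $\pm 1$, ties
broken toward fewer censorings — so that the implied number at risk at the
next risk-table time reproduces the published value exactly. Censoring
times are placed at uniform quantiles strictly inside the interval (and
nudged off coordinate times), so risk-set ordering is never ambiguous.

Two conventions matter and are easy to get wrong:

* a drop recorded at coordinate month $m$ represents events in $(m-1, m]$,
  so an interval ending at risk-table time $T$ must process the click *at*
  $T$ before comparing with the published $n(T)$ — subjects whose events
  produced that drop are no longer at risk at $T$;
* beyond the last risk-table time, censoring is assumed absent unless the
  total event count was published, in which case tail censoring is chosen
  to match it; everyone still at risk at the last coordinate is censored
  there.

A risk table unattainable for any non-negative censoring count raises
`reconstruction-infeasible` naming the interval. The package's own QA bar
(there is no published tolerance for "good enough" reconstruction) is a
sup-norm deviation below 0.02 between the reconstructed KM curve and the
input coordinates for trials of 200+ subjects; the test suite enforces it
across seeded synthetic trials.

# Parametric families and fitting

Eight families are supported, in stable parameterisations chosen so that
the nesting identities are exact parameter substitutions: exponential
($\lambda$), Weibull ($S = e^{-(t/\sigma)^k}$), gamma (shape/rate),
log-logistic ($S = 1/(1+(t/\sigma)^k)$), log-normal, Gompertz
($h = a e^{bt}$, $b$ real), generalized gamma $(\mu, \sigma, Q)$ and
generalized F $(\mu, \sigma, Q, P)$. Negative Gompertz shape gives an
improper survival plateau $e^{a/b}$; this is permitted (it can be a
reasonable description of a cured fraction) but flagged in the fit notes.

Fitting maximises the right-censored log-likelihood
$\sum_{events}\log f(t_i) + \sum_{cens}\log S(t_i)$ by quasi-Newton
(L-BFGS-B) on an unconstrained scale (log transform for positive
parameters), from five fixed moment-based starting points. No randomness is
used anywhere in fitting, so results are bit-reproducible. The exponential
family uses its closed form $\hat\lambda = d/\sum t_i$.

**Numerical choices.** Reconstructed IPD has all event times tied on the
monthly grid. For the flexible families this creates genuine likelihood
degeneracy: with $\sigma \to 0$ and $|Q|$ large, a generalized gamma can
place a density spike on one tied atom and push the log-likelihood
arbitrarily high. We therefore bound the optimiser's box for the
generalized gamma and generalized F: $\sigma \in [0.05, 100]$ (log-time
scale; $\sigma = 0.05$ is already an implausibly peaked time-to-event
distribution) and $Q \in [-6, 6]$, $P \le 100$. These bounds exclude only
spike solutions, not clinically meaningful fits. When a line search ends
with a non-zero convergence code the fit is polished by Nelder–Mead and
only then, if still unconverged, flagged honestly (`converged = FALSE`;
such fits sort last in the AIC menu). A generalized F fit on fewer than 10
events carries a stability warning. Model choice is by AIC only — the menu
reports $2k - 2\ell$ per family — and the vignette's standing caveat
applies: AIC measures internal fit, never extrapolation plausibility.

# Hazard ratio and proportional hazards

The intervention arm is not fitted independently (that would require four
family choices and break the link to published hazard ratios). Instead the
control-arm cumulative hazard is scaled: $H_{int}(t) = \mathrm{HR}\cdot
H_{ctrl}(t)$, i.e. $S_{int} = S_{ctrl}^{\mathrm{HR}}$, applied through the
curve's cumulative-hazard contract so the rule is valid whatever family —
proportional-hazards or accelerated-failure-time metric — produced the
control curve.

The HR comes from the template when given; only the sentinel `"estimate"`
triggers Cox estimation from the reconstructed IPD, with no silent mixing
of sources. Cox fitting uses the Efron tie correction: monthly-grid
reconstruction produces heavy ties, where Breslow is noticeably biased
(Breslow is available behind an argument for cross-checking). The
proportional-hazards diagnostic is the scaled-Schoenfeld score test with a
Kaplan–Meier time transform (the standard default, swappable). A p-value
below 0.05 produces a prominent warning, not a stop: statistical tests are
not the only criterion, and judgement about extrapolation rests with the
analyst.

# Resource use and costs

Posology is expressed as phases of a schedule grammar: continuous rates
(per day / week / month) or administration events (every $k$ weeks, or
explicit day lists), with windows in days, weeks, months or treatment
cycles of stated length, and an optional cap in treatment cycles counted
from model start. Events are laid on a day timeline and binned into monthly
cycles; rates are apportioned by exact day counts, so no units are lost at
cycle boundaries (the tests assert conservation to 1e-9).

Conventions fixed here, because no standard text states them: one model
cycle = 365.25/12 = 30.4375 days and a week is 7 days; an administration
falling exactly on a cycle boundary belongs to the later cycle (half-open
binning). Post-progression consumption cannot vary over time, so PPS items
accept a single unbounded rate-type phase — anything else is rejected as
`invalid-schedule` rather than silently truncated. Per-cycle costs are
multiplied by state occupancy in the engine (standard cohort accounting):
a drug "given until progression" automatically stops paying as the PFS
state empties.

# Engine: cycles, half-cycle correction, discounting

Cycles are 1-based and monthly, cycle $c$ spanning $(c-1, c]$; the cycle
length cannot be altered. Events are treated as occurring half-way through
each month. Two readings of that statement exist and differ at $O(h^2)$:
the trapezoid form (per-cycle occupancy = mean of the boundary values, the
life-table convention) and literal midpoint evaluation at $c - 0.5$. Both
are implemented; trapezoid is the default, and a test verifies the two
agree to within 0.01 months of life expectancy over a 100-month horizon for
smooth curves. Discounting uses $(1+r)^{-t/12}$ evaluated at the cycle
midpoint $t = c - 0.5$, consistent with the half-cycle timing. Life years
and QALYs are reported in years (monthly sums divided by 12); setting all
three utility weights to 1 switches the model to life-year mode. The ICER
is computed on discounted totals (the undiscounted ICER is also reported,
since published worked examples do not always say which they print). Zero
incremental effect yields the sentinel `undefined`; dominance and negative
ratios are flagged, never masked — a negative ICER has no decision
interpretation on its own.

# Sensitivity analysis

The univariate DSA sweeps exactly the parameters the input format marks
analysable: hazard ratios, the discount rate, unit costs and the three
utility weights. Resource-use *quantities* are deliberately not swept.
Scenarios are strictly one-at-a-time; ranges must bracket the base value or
the template is rejected (`invalid-range`). Tornado ordering is by the ICER
range $|ICER_{high} - ICER_{low}|$; parameters with an undefined or failed
scenario are ordered after fully-valid ones by their one-sided excursion
and flagged, since a two-sided width does not exist for them.

# The synthetic-trial generator

`trial_spec()` + `simulate_trial()` produce ground-truth IPD: control-arm
event times from stated families, the intervention arm via the same
$S^{\mathrm{HR}}$ rule the engine assumes, and PFS coupled to OS as
PFS = min(OS, independent progression time). The coupling guarantees
per-subject PFS $\le$ OS — so generated data can never trip the engine's
ordering guard within follow-up — while matching the marginal families
approximately. This is a test device, not a clinical claim: real trials
exhibit dependence between progression and death, informative censoring,
and digitization error from reading pixels off a plot, none of which are
emulated. A green round-trip test therefore establishes that the
*algorithms* are faithful, not that reconstruction from a real, imperfectly
digitized figure carries no error.

Defaults describe the kind of trial the package's worked example models: a
second-line oncology comparison with ~260 subjects/arm, 30 months of
follow-up, Weibull control OS (shape 1.3, scale 45 months — median ~34
months) and a latent progression time with Weibull shape 1.1 and scale 10
months (control PFS median ~7 months), HR 0.55 for OS and 0.28 for PFS,
3% annual discounting, and every-3-weeks weight-based drug costs (2.52 and
3.78 100-mg units at 2720€ and 2194€) with a `next_line` post-progression
cost of 0€ base / 3000€ per month in DSA. These were chosen once, as a
realistic stated world, and are not tuned.

# Known limitations

* The PSM independence assumption: PFS gains do not propagate to OS, and
  long extrapolations can hit the OS-below-PFS guard — by design this
  halts rather than adjusts.
* Only constant hazard ratios; crossing or converging observed curves are a
  sign this tool should not be used for that comparison.
* No probabilistic sensitivity analysis: the dominant uncertainty in a PSM
  is usually the survival-family choice, which a parameter-only PSA
  misrepresents; deterministic results under several families are the
  honest substitute.
* Reconstruction quality degrades with sparse risk tables and coarse
  digitization grids; the 0.02 sup-norm bar is this package's own QA bar,
  not a published standard.
* The published tutorial dataset for the original worked example is not
  redistributable with this package, so the corresponding acceptance check
  requires a user-supplied download and otherwise reports failure.
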