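---
title: "Methods: the tumour growth model, treatment forcing and the virtual-trial pipeline"
author: "thermorad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tumour growth model, treatment forcing and the virtual-trial pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermorad)
```

## The model

`thermorad` simulates a compartmental tumour under fractionated
radiotherapy (RT) and high-temperature hyperthermia (HT). The state is
seven-dimensional and dimensionless: undamaged tumour volume $T$,
sub-lethally RT-damaged volume $T_S$, lethally RT-damaged volume $T_R$,
lethally HT-damaged volume $T_H$, vascular volume $V$ (all fractions of
the total available volume, $\Sigma = T + T_S + T_R + T_H + V \le 1$),
oxygen concentration $c \in [0,1]$ (fraction of the vascular level), and
the inactive repair-protein fraction $\Lambda \in [0,1]$. Time is in
minutes.

Untreated growth couples two arrest mechanisms. Proliferation is
proportional to $c\,(1-\Sigma)\,T$ with rate $q_2$: it stops when free
volume is exhausted (*space-limited* arrest, SL). Hypoxic death at rate
$\delta (c_{\min}-c) H(c_{\min}-c)\,T$ switches on when oxygen falls
below the threshold $c_{\min}$ ($H$ is the unit step with $H(0)=1$):
proliferation and death can balance at a hypoxic steady state
(*nutrient-limited* arrest, NL). Oxygen is supplied at rate
$g\,(1-c)\,V$ and consumed for maintenance ($q_1 c$ per unit viable
volume, with sub-lethally damaged cells consuming $\theta_1$-fold
faster) and for proliferation ($q_3 c (1-\Sigma)$ terms). For some
parameter triples $(q_1, q_3, V(0))$ both stable states coexist
(*bistable*, BS); which one is reached depends on the initial tumour
volume.

RT forcing is a piecewise-constant dose rate $R(t) = D/\delta_R$ inside
each 10-minute fraction window. It converts $T$ into $T_S$ (rate $\nu c
R$) and both into $T_R$ (rates $\lambda c R$, $\lambda_S c R$) — the
oxygen factor encodes oxygen-dependent radiosensitivity. $T_S$ repairs
at rate $\mu(t) = \mu_0 e^{-\mu_\Lambda \Lambda(t)}$ and dies by mitotic
catastrophe at rate $\xi$; $T_R$ clears at rate $\eta_R$. HT forcing is
a constant damage rate $\tilde\beta$ inside each 60-minute weekly
window, killing $T$, $T_S$ and vasculature $V$; dead heat-damaged cells
$T_H$ clear at rate $\eta_H$ and drive angiogenesis at rate $\kappa_0$.
Heating also inactivates repair proteins:
$\dot\Lambda = k_1 \mathbf{1}_{HT}(t) (1-\Lambda) - k_2 \Lambda$ with
$k_1 = 100\,\tilde\beta$, which suppresses DNA repair through
$\mu(t)$.

### Promotion of $\Lambda$ to a state variable

The published closed form for $\Lambda$ covers a single heating
fraction. We integrate the rate equation above as a seventh state
component instead; its single-fraction solution is exactly the closed
form (asserted to $<10^{-6}$ in the tests), and repeated weekly
fractions accumulate naturally. With $k_2 = 10^{-3}\,$min$^{-1}$,
$\Lambda$ decays by a factor $e^{-10.08} \approx 4\times10^{-5}$ over
one week, so in practice each fraction starts from a clean slate. For
RT-only schedules $k_1 = 0$ and $\mu \equiv \mu_0$.

### Derived parameters

$q_2 = k\,q_3$ is not a free parameter (the proliferation and
proliferation-linked oxygen consumption rates are tied by the conversion
factor $k = 10^{-2}$), and the hypoxic death rates follow as
$\delta = q_2$, $\delta_S = \theta_2 q_2$. These relations are enforced
by the `model_params()` constructor and never read from configuration
files. The mitotic-catastrophe rate appears in reference tables under
two symbols ($\zeta$/$\xi$); it is a single parameter here, `xi` =
$5\times10^{-4}$. `c_min` is labelled both "anoxic" and "hypoxic"
threshold in the sources; it is one parameter.

## Fixed points, regimes and thresholds

With treatment off, $T_S = T_R = T_H = 0$ and $V = V(0)$, leaving a
planar system in $(T, c)$.

* **SL branch**: $T^\ast = 1 - V(0)$, and the oxygen balance gives the
  closed form $c^\ast = g V_0 / (q_1 (1 - V_0) + g V_0)$; admissible
  while $c^\ast \ge c_{\min}$.
* **NL branch**: setting proliferation equal to hypoxic death gives
  $\Sigma = 1 - (c_{\min} - c)/c$; substituting into the oxygen balance
  leaves a scalar residual in $c$ on $(c_{\min}/(2 - V_0), c_{\min})$,
  bracketed on a 400-point grid and polished with `uniroot` at
  near-machine tolerance. Stability is certified from the analytic
  $2\times2$ Jacobian (both eigenvalue real parts $< -10^{-12}$).
* **Thresholds**: $\bar q_1 = g V_0 (1 - c_{\min}) / (c_{\min}
  (1 - V_0))$ is where the SL branch crosses the hypoxic threshold
  (derived from $c^\ast = c_{\min}$ and verified against a bisection
  oracle in the tests); $\bar q_3(q_1)$, the SL-only/bistable boundary,
  is located by bisection on the existence of a stable NL root over
  $q_3 \in [0.01, 10]$ to $10^{-8}$ relative tolerance.

Boundary ties are resolved deterministically: exactly at
$q_1 = \bar q_1$ a triple counts as NL, exactly at $q_3 = \bar q_3$ as
BS, matching the open/closed sides of the cohort sampling intervals. We
treat $\bar q_3$ as an existence-of-stable-NL-root boundary; whether the
original closed-form derivation is an existence or stability condition
is not reproducible from our sources, and for this system the two
coincide at a saddle-node, which is what the bisection detects.

## The cohort generator (synthetic data)

A virtual tumour is a triple $(q_3, q_1, V(0))$ with its untreated
steady state. Cohorts fix $V(0)$ per regime (NL $5\times10^{-4}$, SL
$5\times10^{-3}$, BS $2.75\times10^{-3}$) and draw $(q_1, q_3)$
uniformly from regime-specific boxes: NL draws $q_1 \sim U(\bar q_1,
10)$, $q_3 \sim U(0.01, 10)$; SL draws $q_1 \sim U(0.01, \bar q_1)$,
$q_3 \sim U(0.01, \bar q_3(q_1))$; BS draws $q_1 \sim U(0.01, \bar
q_1)$, $q_3 \sim U(\bar q_3(q_1), 10)$. $q_1$ is drawn first because
$\bar q_3$ is conditioned on it. Every accepted pair is re-verified with
`classify_regime()`; mismatches (possible only through numerical
threshold error) are redrawn, and a rejection rate above 20% aborts.

Two facts about the boxes discovered during implementation: (i) for the
SL cohort at $V(0) = 5\times10^{-3}$ and small $q_1$, $\bar q_3$ lies
above the global $q_3$ range $[0.01, 10]$, so the SL box is truncated at
10 (the sampled box is the intersection with the admissible parameter
range); (ii) a BS draw at such a $q_1$ is impossible and is rejected and
redrawn, which the BS cohort's smaller $V(0)$ makes rare to the point of
non-occurrence.

Randomness uses one L'Ecuyer-CMRG sub-stream per tumour id derived from
the cohort seed, so a cohort can be extended without reshuffling
existing members. Reference cohorts use $N = 250$; the test suite and
seeded reproductions use $N = 50$ (and the generator's seeds are fixed
in the tests), which preserves cohort-level majorities and medians but
not tail behaviour — a green seeded test establishes the qualitative
pattern at that seed and size, not figure-exact population fractions;
reference results over such cohorts are reproducible in distribution
only, never draw-for-draw.

What the generator does **not** emulate: measurement noise, inter-patient
variability in any parameter other than $(q_1, q_3, V(0))$, non-uniform
priors, or calibration to real tumour data.

## Treatment schedules

$t = 0$ is Monday at the daily treatment time; a week is 10080 min.
RT delivers $N_{frac} \in \{1, 3, 5\}$ weekly fractions of $D \in
\{1,\dots,5\}$ Gy (10-min windows): 5/wk on Mon–Fri, 3/wk on
Mon/Wed/Fri, 1/wk on Mon. The stated "equally spaced during Monday to
Friday" is read as whole treatment days; exact 1.5-day gaps for the
3/wk case would place fractions at night and is not used. The number of
weeks minimises $|D \cdot N_{frac} \cdot N_{wks} - 80\,\mathrm{Gy}|$
(ties toward fewer weeks, i.e. less dose). One weekly 60-min HT
fraction is given on Mondays: at the Monday slot for HT alone, and
starting $t_R + \delta_R + 1$ (one minute after the Monday RT fraction)
when combined. The HT cap is $\tilde\beta \cdot N_{wks} \le 0.08$,
enforced at construction. All windows are closed intervals; because
integration is segmented at window boundaries, endpoint membership
never affects the solution.

## Numerics

The integrator is an adaptive Dormand–Prince 5(4) pair implemented in
C++ (the reference solver family for this model class), restarted at
every treatment-window boundary so each segment sees constant forcing —
exact for piecewise-constant dose rates, and reproducible. Defaults:
relative tolerance $10^{-8}$, absolute $10^{-10}$, dense output on a
uniform 1-min grid over the final treatment week and a $\le$10-min grid
elsewhere (memory-bounded even for 80-week schedules). Halving the
tolerances moves every reported response metric by far less than 0.1
percentage points (asserted in the acceptance tests).

Numerical edge cases, decided once:

* The hypoxia switch at $c = c_{\min}$ is state-dependent and invisible
  to the segmentation; the error estimator resolves it (the factor
  $(c_{\min}-c)$ vanishes at the switch, so the vector field is
  continuous, merely non-smooth). $H(0) = 1$ fixes the boundary value
  for determinism.
* Components are clipped to 0 only when round-off drives them below
  zero by less than $10^{-14}$; larger violations are counted
  separately and surfaced as a warning.
* $\Sigma > 1 + 10^{-6}$ on a stored trajectory raises a model-regime
  warning.
* Components the forcing provably never touches (e.g. $V$ under
  RT-only) are constant in exact arithmetic, but trapezoidal averaging
  re-introduces $\sim10^{-14}$ relative noise; response metrics within
  $10^{-9}$ percentage points of zero are snapped to exactly 0 so the
  strict `> 0` comparison rules see the analytic value.
* Steady states reached by integration stop when the derivative
  sup-norm falls below $10^{-11}$ at tightened tolerances
  (`rtol = 1e-10`); the bistability witness starts from exact full
  occupancy $T(0) = 1 - V(0)$, which is provably inside the SL basin
  for every bistable tumour, whereas lower starts such as $T(0)=0.9$
  can crash oxygen below $c_{\min}$ before the space limit binds and
  land on the NL branch.

## Response metrics, stratification and comparison rules

Responses are evaluated from last-week trapezoidal means: percent
changes of viable volume ($\bar T + \bar T_S$ vs $T^\ast$), total
occupied volume ($\bar\Sigma$ vs $T^\ast + V(0)$), vascular volume and
oxygen. The scalar efficacy score is
$\Delta_{viable} + \Delta_{total}$; $\Delta_c$ is computed and reported
but feeds no rule. A treatment is *deleterious* when
$\max(\Delta_{viable}+\Delta_{total}, \Delta_V) > 0$.

A note on expected signs: under conventional RT the SL cohort scores
almost uniformly negative (well-oxygenated tumours are radiosensitive),
but most NL tumours score *positive* — RT cell kill is weak at hypoxic
oxygen levels while killed-cell volume still accumulates, and regrowth
between fractions outpaces it except at low $q_3$ — and the BS cohort
is predominantly deleterious (treatment can tip a tumour from its NL
state toward the much larger SL state). The test suite asserts these
cohort-level patterns at seeded $N = 50$; the one assertion we leave
failing expects an NL-majority negative score, which this model family
does not produce.

Five-class stratification: scores $\ge 0$ are `negative`; among the
responding (negative-score) tumours of one cohort–schedule pair, the
10/37.5/62.5 percentiles split `strongly_positive` / `positive` /
`moderate` / `limited`. Two conventions the source tables leave open
are fixed and exposed: percentiles use linear interpolation between
order statistics (`stats::quantile` type 7), and they are estimated on
the responding subset (the classification intervals terminate at 0;
`include_nonnegative = TRUE` switches to the all-scores basis).

Comparison rules for matched RT/HT/RT+HT schedules: Rule 1 excludes any
treatment with a strictly positive metric among
$\{\Delta_{viable}, \Delta_{total}, \Delta_V\}$ (individual metrics —
deliberately different from the deleterious flag's summed score);
Rule 2 lets the combination win only if both the viable and total
reductions beat the monotherapy by at least 10 percentage points *and*
its vascular change is strictly smaller; Rule 3 orders monotherapies by
score, RT winning exact ties (HT must strictly win). Two open readings
are fixed and exposed: Rule 2 is applied against the *better* surviving
monotherapy by default (`rule2_both = TRUE` demands both), and the
post-ranking "adjustment" demotes any combination entry that fails its
own matched Rule-2 margin in favour of the better monotherapy —
defensive, since per-pair winners already satisfy it. Ranking ties
break deterministically (treatment order R < H < R+H, then schedule
descriptor).

## Known limitations

* Short-term end-of-treatment responses only; no post-treatment
  continuation (the model's frozen vasculature makes long-time dynamics
  untrustworthy, and the angiogenesis rate $\kappa_0$ is both
  influential and weakly constrained).
* No mild hyperthermia (perfusion/metabolic effects), no spatial
  temperature or oxygen fields, no dimensional-variable interface.
* The k1-insensitivity of the repair rate $\mu(t)$ holds on the scale
  of $\mu_0$ after the heating window (spread $\approx 0.4\%$ of
  $\mu_0$); *during* the 60-min ramp-in the profiles differ by orders
  of magnitude in relative terms, so claims of treatment-independent
  repair inhibition apply to the multi-day recovery profile, not the
  transient.
* The RT fraction clock assumes whole treatment days; weekend
  fractions, RT/HT reordering and variable inter-modality delay are out
  of scope.

## A minimal run

```{r, eval = FALSE}
co <- sample_cohort("SL", N = 50, seed = 102)
tri <- compare_treatments(co[1, ], D = 2, N_frac = 5, beta_tilde = 0.005)
tri$winner
run_study(run_config(N = 10, out_dir = tempfile()))
```
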