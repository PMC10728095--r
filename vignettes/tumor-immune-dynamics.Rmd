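---
title: "Modeling fast and slow CTL killing under PD-1/PD-L1 checkpoint blockade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fast and slow CTL killing under PD-1/PD-L1 checkpoint blockade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ctldyn)
```

## The model

`ctldyn` simulates an in vivo tumor–immune system with three compartments:
high-antigen tumor cells $N$, low-antigen tumor cells $M$, and cytotoxic T
lymphocytes (CTLs) $T$, all in cells, with time in days. The two phenotypes
share one logistic niche and differ only in how visible they are to the
immune system:

$$
\begin{aligned}
\frac{dN}{dt} &= \alpha_n N \left(1 - \tfrac{N+M}{K}\right)
  - F \left[ p_1 \delta_{nf} T
  + (1-p_1)\, \frac{\delta_{ns} T}{\kappa_0 + (N+M) + \kappa_1 T} \right] N \\
\frac{dM}{dt} &= \alpha_m M \left(1 - \tfrac{N+M}{K}\right)
  - F \left[ p_2 \delta_{mf} T
  + (1-p_2)\, \frac{\delta_{ms} T}{\kappa_0 + (N+M) + \kappa_1 T} \right] M \\
\frac{dT}{dt} &= \mu
  + \left[ \frac{\alpha_{nt} N}{\kappa_2 + N}
  + \frac{\alpha_{mt} M}{\kappa_2 + M} \right] T
  - \delta_t T - \delta_n N T - \delta_m M T
\end{aligned}
$$

CTLs kill through two channels. The *fast* channel (perforin/granzyme,
detectable within minutes) is mass-action: each encounter at rate
$\delta_{nf} T$ kills. The *slow* channel (FasL/death-receptor, hours) is a
multi-prey Beddington–DeAngelis response: a CTL engaging any tumor cell is
unavailable to others, so the per-capita rate saturates both in effectors
($\kappa_1 T$) and in total tumor burden ($N + M$). The probabilities $p_1,
p_2 \in [0,1]$ say how often each phenotype dies by the fast channel;
high-antigen cells favor fast killing at baseline ($p_1 = 0.92$ vs
$p_2 = 0.33$).

The PD-1/PD-L1 checkpoint suppresses both kill terms through

$$
F = \frac{1}{1 + PL/k_{TQ}}, \qquad
P = \rho_p T, \quad L = \rho_l \left(T + \epsilon_c (N + M)\right),
$$

so suppression deepens as either the tumor or the infiltrate grows. A
perfectly blocked checkpoint is the idealization $F \equiv 1$
(`mode = "blocked"`). $F$ multiplies only the kill terms, not T-cell
proliferation: the checkpoint is modeled as inhibiting cytotoxic activity at
the synapse. The anti-PD-1 binding rate `mu_PA` is stored for completeness
but drives no dynamics — drug kinetics and dosing are out of scope.

### Choice of the slow-kill functional response

The slow channel's form was the one genuinely open modeling decision. The
candidates compatible with the parameter table were a pure
effector-saturation form $\delta_s T / (\kappa_0 + \kappa_1 T)$ and the
Beddington–DeAngelis family. We adopted the multi-prey Beddington–DeAngelis
form for three reasons. First, it is the canonical saturating cytotoxicity
description in the tumor–immune literature this model descends from
(the T-cell equation is Kuznetsov's, with $\kappa_2$, $\delta_n$, $\delta_t$
at Kuznetsov's values), and it needs no extra coefficient: $\kappa_0$ is the
half-saturation burden and $\kappa_1$ the dimensionless effector-saturation
weight. Second, tumor-burden dilution is what makes the two channels
*mechanistically different at scale*: against a large tumor the slow channel
is throughput-limited while the fast channel still scales with $T$, which is
exactly the fast-vs-slow contrast the model exists to study (a roughly
twenty-fold day-25 volume difference between all-fast and all-slow killing
under blockade). Third, without the burden term the two channels are nearly
interchangeable at realistic sizes and the model cannot produce the
published contrast or the baseline escape-with-relapse behavior; with it,
both emerge. The pure effector-saturation limit is recovered by
`slow_kill_rate(..., tumor = 0)`.

### Initial conditions

Figure-style runs start from a 1 mm³ inoculum (10⁶ cells at the package-wide
convention of 10⁶ cells/mm³) split 50/50 between phenotypes. The initial CTL
count is not stated in the source analyses; we start from $T(0) = 0$ — a
naive host whose tumor-specific effectors arrive through the recruitment
term $\mu$. We prefer this to the tumor-free homeostatic level
$\mu/\delta_t$ because homeostatic seeding makes the baseline blocked run
clinically eliminate its tumor, contradicting the reference behavior
(baseline blockade achieves a deep day-25 response but the tumor regrows to
carrying capacity by day 150); with $T(0)=0$ the package reproduces that
response-then-relapse course. `homeostatic_T()` and the `T_0` argument of
`inoculum_state()` expose the alternative.

```{r trajectory}
p <- baseline_params()
tr <- integrate_tumor(p, mode = "blocked", t_end = 150)
volume_at(tr, 25)
volume_at(tr, 150)
```

## Numerical integration and the detection-limit clamp

No ODE solver package is assumed; the integrator is an adaptive
Dormand–Prince 5(4) pair implemented in C++ (relative tolerance $10^{-8}$,
absolute tolerance $10^{-2}$ cells by default; cohort runs use $10^{-6}$
relative, which leaves all cohort-level fractions unchanged while roughly
halving runtime). Steps are clipped to land exactly on requested output
days, so day-25/150 readouts are solver outputs, not interpolations.

Tumors below 0.1 mm³ are clinically undetectable, so simulations carry a
terminal-style event: when the total burden first crosses 10⁵ cells from
above, the crossing is localized by bisection on a cubic Hermite interpolant
of the accepted step, the tumor compartments are frozen there (reported
volume exactly 0.1 mm³ from then on), and T continues to relax. A run that
*starts* below the limit is clamped at $t = 0$ rather than rejected. For
outcome classification a clamped run counts as a clinical elimination — the
tumor crossed below the detection limit — even though its reported volume is
held at the 0.1 mm³ boundary, which the dormancy interval $[0.1, 500]$ mm³
would otherwise claim.

Two threshold systems coexist deliberately, mirroring the source's usage:
*clinical* outcomes at days 25/150 (elimination < 0.1 mm³; dormancy 0.1–500;
escape > 500, `classify_clinical()`), and *steady-state* outcomes for
bifurcation work (elimination = exactly tumor-free; dormancy any persistent
state under 500 mm³; escape at or above it).

## Steady states, bistability and hidden attractors

On each boundary face ($N = 0$ or $M = 0$) the T equation is linear in $T$
given the tumor burden, so every branch equilibrium solves a scalar
equation; `find_equilibria()` scans it on a log grid (default 400 points up
to $10K$) with sign-change bracketing, boundary refinement against the
$T$-singularity (where the T-equation denominator vanishes and the
per-capita growth plunges), and Newton polish. This replaces the blind
multistart a 3-D root search would need: it is deterministic and exhaustive
at the scan resolution. Interior equilibria, which require the two
phenotypes' net kill rates to balance exactly, are searched by seeded
multistart Newton and arise only on degenerate slices. Stability is read
from the eigenvalues of a finite-difference Jacobian of the smooth
(unclipped) right-hand side; the tumor-free state's spectrum is available in
closed form and doubles as an oracle.

`classify_steady_state()` maps stable equilibria to outcome sets, and — a
feature equilibrium enumeration alone cannot provide — probes for stable
limit cycles by integrating from each unstable persistent equilibrium nudged
1% off its stable manifold. Oscillatory dormancy (relapsing–remitting
tumors cycling over several decades of volume) is real in this model at,
e.g., elevated $\alpha_{mt}$, and the probe attributes it to the dormancy
outcome. The long-run labeler averages whole 2000-day segments (phase-robust
for long-period cycles), floors the tumor compartments at a 10⁻⁶-cell
quasi-extinction level between segments (an underflow-to-zero would
otherwise absorb trajectories the continuum model would regrow), and
returns *no* label rather than a wrong one for runs still in transit after
12,000 days — transit through a fold ghost can be arbitrarily slow.

```{r equilibria}
glance(find_equilibria(p, "blocked"))
classify_steady_state(baseline_params(alpha_mt = 0.55), "blocked")$outcomes
```

## The virtual cohort generator

`sample_cohort()` draws a Latin hypercube: every model parameter over its
admissible range, plus the initial low-antigen fraction (uniform on
$[0,1]$) and the initial CTL-to-tumor-cell ratio (log-uniform on
$[0.01, 1]$), with the inoculum fixed at 1 mm³. Parameters whose range spans
at least two decades — and $\mu$, at 1.5 decades — are sampled
log-uniformly; linear sampling of a two-decade range would put 90% of the
mass in the top decade. Exactly one mouse falls in each of the $n$
equal-probability strata per dimension, and a fixed seed reproduces the
cohort bit-for-bit.

What the generator emulates is a heterogeneous mouse population with
independent tumor and immune attributes; what it does not emulate is any
correlation structure between attributes (an inflamed tumor likely has both
high $\mu$ and high $\alpha_{nt}$), measurement noise, or inter-mouse
variation in inoculum size. A green cohort test therefore establishes that
the pipeline reproduces outcome frequencies for *this* stated population,
not that the population matches any particular experiment. The initial
composition and immune-ratio ranges are not stated in the source; both are
plain `cohort_spec()` arguments, and the blocked-arm escape fraction in
particular is sensitive to the upper end of the ratio range (a population
extending to immune-inflamed ratios well above 1:1 escapes less and
eliminates more by day 150).

## Global sensitivity

`prcc()` implements partial rank correlation: rank-transform all columns,
regress out the other inputs from both the target input and the output, and
correlate the residuals, with a t-approximation p-value and
Benjamini–Hochberg correction across inputs (FDR 0.05). PRCC is the
standard companion to Latin hypercube designs and captures monotone global
influence; `global_sensitivity()` applies it to day-25 volume or
composition. Note that the fast-kill probabilities influence *composition*
monotonically but not cohort-wide *volume*: raising $p_i$ increases killing
only where the sampled fast rate exceeds the slow rate, so their volume
PRCC is legitimately near zero.

## Tolerances and reproducibility choices

- Solver: `rtol = 1e-8`, `atol = 1e-2` cells (state spans ten orders of
  magnitude); acceptance-level quantities are invariant to a 10× tightening.
- Event localization: 80 bisection steps on the Hermite interpolant;
  clamped compositions are rescaled so the frozen total is exactly 10⁵
  cells.
- Equilibrium acceptance: residual $\le 10^{-6}\max(1, \lVert x \rVert)$;
  duplicates merged at relative distance $10^{-6}$; stability margin
  $10^{-8}$/day, with `marginal` reported when no eigenvalue clears it.
- Bisection on $p_2$ thresholds to $10^{-3}$, after a coarse monotonicity
  check of the reduction curve.
- One global seed derives fixed per-stage substreams in `run_pipeline()`,
  so adding a stage never shifts another stage's draws.

## Known limitations

- Perfect, permanent blockade only ($F \equiv 1$); no drug kinetics.
- Deterministic continuum dynamics: extinction is a threshold convention,
  and sub-cell tumor burdens are meaningful only as transients.
- Region maps classify by equilibrium enumeration plus cycle probing, not
  formal continuation; region boundaries are resolved to the sweep grid.
- The cohort's independence assumption above.
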