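---
title: "Two-state concerted modulation of enzyme kinetics: model, fitting procedure and design notes"
author: "allokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state concerted modulation of enzyme kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

## The model

The package describes an enzyme that interconverts rapidly between two
conformational states, A and B, each with Michaelis--Menten kinetics of its
own ($k_{catA}, K_{mA}$ and $k_{catB}, K_{mB}$), while a modulator binds
cooperatively to $n$ concerted activating sites and, optionally, to $m$
competitive inhibitory sites present only in state B. The motivating system
is the chymotrypsin-like activity of the 20S proteasome under cationic
porphyrin modulators, where state A dominates the resting enzyme and the
modulator progressively stabilizes the higher-affinity, slower-turnover
state B.

Each ligation class carries its own allosteric constant, $L_U = [B]/[A]$
for the substrate-free enzyme and $L_L = [B\!\cdot\!S]/[A\!\cdot\!S]$ for
the substrate-bound one, and the modulator has four association constants
($K_{AU}, K_{BU}, K_{AL}, K_{BL}$, per $\mu$M) distinguishing state and
substrate occupancy. The canonical concerted-model constraints are built
in: association constants do not depend on how many modulator molecules are
already bound, turnover rates are unchanged by modulator binding
($\sigma_A = \sigma_B = 1$), and the inhibitory site does not exist in
state A ($K_{AI} = 0$). The observed catalytic parameters are population
averages over binding polynomials $(1 + K L)^n$:

$$
{}^{obs}k_{cat} =
\frac{k_{catA}\,(1+K_{AL}L)^n + L_L\,k_{catB}\,(1+K_{BL}L)^n}
     {(1+K_{AL}L)^n + L_L\,(1+K_{BL}L)^n},
$$

$$
{}^{obs}K_m = {}^0K_m\,
\frac{(1+K_{AU}L)^n + L_U\,(1+K_{BI}L)^m\,(1+K_{BU}L)^n}
     {(1+K_{AL}L)^n + L_L\,(1+K_{BL}L)^n},
$$

and a direct population-weighted specificity constant

$$
\left(\frac{k_{cat}}{K_m}\right)_{obs} =
\frac{\tfrac{k_{catA}}{K_{mA}}(1+K_{AU}L)^n +
      L_U \tfrac{k_{catB}}{K_{mB}} (1+K_{BI}L)^m (1+K_{BU}L)^n}
     {(1+K_{AU}L)^n + L_U (1+K_{BI}L)^m (1+K_{BU}L)^n}.
$$

### The two specificity representations

The direct specificity expression is *not* algebraically the ratio
${}^{obs}k_{cat}/{}^{obs}K_m$ unless the scheme is degenerate (identical
substrate-free and substrate-bound constants and Michaelis constants). The
two differ qualitatively when an inhibitory site is present: the ratio
collapses as $1/(1+K_{BI}L)^m$ at high modulator (the Michaelis constant
diverges while turnover stays bounded), whereas the direct form saturates
at $k_{catB}/K_{mB}$ and cannot describe a competitive efficiency
collapse. A catalytic profile estimated by double-reciprocal analysis
yields the ratio by construction, so **the package fits the ratio
representation by default** and treats the direct form as an alternative
(`efficiency = "eq_direct"`) plus a permanent diagnostic:
`efficiency_consistency()` reports the maximum relative gap between the
two curves, and every report shows both. On the anchored human-like
fixture the gap reaches tens of percent, which is why the choice of
representation is surfaced rather than hidden.

## From velocities to catalytic profiles

Initial velocities on a (substrate $\times$ modulator) design are reduced
to per-concentration estimates by the classical unweighted
Lineweaver--Burk regression $E_0/v = (K_m/k_{cat})(1/S) + 1/k_{cat}$,
restricted to the linear range $S \le 25\ \mu$M (`S_cut`, the default
reflecting the loss of double-reciprocal linearity above that substrate
concentration in the motivating assays). A nonlinear Michaelis--Menten fit
is available as the cross-check (`michaelis_menten_fit()`), replicates are
averaged before regression (per-replicate fitting behind a flag), and a
linearity flag is raised when the full-range transformed regression drops
below $r^2 = 0.98$ while the retained range does not. The threshold is a
package choice: clean Michaelis--Menten data pass it everywhere, while the
substrate-inhibition option (below) fails it on the 5--100 $\mu$M range in
the modulator-activated regime, where the low observed $K_m$ makes the
uncompetitive curvature visible.

Because the reciprocal transform is strongly heteroscedastic — at low
modulator, where $K_m \approx 60\ \mu$M, the extrapolated intercept
carries 15--30% error at 5% velocity noise — the profile carries
delta-method standard errors of $k_{cat}$, $K_m$ and $k_{cat}/K_m$, and
the model-fitting stages weight their relative residuals by these relative
standard errors (floored at $10^{-4}$ so that noiseless profiles keep a
finite scale). Unweighted relative least squares is what remains when a
profile has no standard-error columns.

## The staged constrained fit

`fit_modulation()` mirrors how the observed curves constrain the scheme:

1. **Turnover stage.** ${}^{obs}k_{cat}(L)$ pins $k_{catA}$, $k_{catB}$,
   $K_{AL}$, $K_{BL}$ and $L_L$. These are then frozen.
2. **Affinity stage.** ${}^{obs}K_m(L)$ and the specificity curve jointly
   pin ${}^0K_m$, $K_{AU}$, $K_{BU}$, $L_U$ and, when $m \ge 1$,
   $K_{BI}$ (with $K_{mA}$ tied to ${}^0K_m$; under the ratio
   representation $K_{mB}$ does not enter and is reported as the
   saturating-modulator limit of the observed $K_m$, status `derived`).

Both stages minimize weighted relative residuals with bounded
Levenberg--Marquardt on log-transformed parameters, from a deterministic
multi-start grid (8 starts) seeded at the interpolated transition
midpoint; the best solution is kept, and parameters at a box bound are
flagged. The boxes encode positivity plus one modelling convention:
$L_U, L_L \le 1$, i.e. state A is the majority reference state of each
ligation class. Without that convention, label-swapped mirror solutions
(state roles exchanged) hijack noisy fits.

### Identifiability, the linkage constraint, and multiple exact roots

Under the ratio representation the observed-$K_m$ curve exposes exactly
$n+m+1$ polynomial coefficient combinations of the unbound-state
parameters. For $n = 3, m = 0$ that matches the four floated parameters
and the stage is just identified. For $n = 2, m = 1$ it does not (four
combinations, five parameters): a continuum of parameter sets reproduces
the data exactly. When that happens the affinity stage imposes the linkage
relation $\gamma = \delta$ — the B/A affinity gain of the modulator is the
same for substrate-free and substrate-bound enzyme, so
$K_{BU} = K_{AU} K_{BL}/K_{AL}$ — and reports $K_{BU}$ as `derived`. The
yeast-like and mutant fixtures are constructed to satisfy this relation.

Even the just-identified constrained system is polynomial and can have
more than one exact positive root (two, for the yeast-like fixture; both
reproduce every observable to machine precision). Among numerically exact
solutions the stage returns the canonical one with the largest allosteric
constant, i.e. the smallest A/B free-energy gap — the most conservative
conformational bias that accounts for the data, the same philosophy as the
minimal-$(n,m)$ rule. The number of distinct exact roots encountered is
kept in the stage diagnostics.

Two further facts about identifiability are worth stating plainly, because
they bound what any fit of this model to such a design can claim:

* When the transition sits inside the assay window but the anchored
  allosteric constant is very small (the human-like $L_L \approx
  4\times10^{-5}$), the binding term is deep in saturation at every
  measured point ($K_{BL} L \gg 1$), so only the product $L_L K_{BL}^n$ is
  well determined. At 5% velocity noise, the recovered $L_L$ alone can
  wander over many decades at statistically indistinguishable RSS; the
  turnover rates, by contrast, are recovered robustly. The residual
  bootstrap makes this visible as very wide intervals on the individual
  binding constants.
* A flat turnover curve (equal state turnover rates, as in the
  gate-disrupted mutant) leaves $K_{AL}$, $K_{BL}$, $L_L$ without any
  stage-1 information. The supported workflow for such enzymes is the one
  used for the mutant fixture: constrain the turnover rates to be equal
  (`equal_kcat = TRUE`) and carry the modulator binding constants over
  from the wild-type fit (`fixed = ...`), flotating only ${}^0K_m$, $L_U$
  and $L_L$.

### Site-number selection

`select_site_numbers()` runs both stages for every candidate
$(n, m) \in \{1..4\} \times \{0..2\}$ and selects the smallest pair in
lexicographic order whose total RSS is within 5% (`rss_margin`) of the
global best — the minimal structure that accounts for the data. Any RSS
below `rss_floor` ($10^{-6}$) is treated as numerically exact, so an
over-parameterized candidate cannot displace a minimal structure that
already fits perfectly; noiseless fits of the generating structure land
many orders of magnitude below the floor while structural misfits land far
above it. On noisy profiles the margin rule tends to over-select (three
extra parameters cut a noise-dominated RSS by more than 5%); the
small-sample Akaike criterion is available as `criterion = "aicc"` and is
the better-calibrated choice there, but structure selection fundamentally
wants clean or replicate-averaged profiles: the package's selection
studies are run on noiseless synthetic profiles.

Residual-bootstrap confidence intervals (`bootstrap_confidence()`)
resample the stages' relative residuals, rebuild profiles around the
fitted curves, and refit at the selected structure warm-started at the
fitted parameters; they are seed-reproducible and percentile-based.

## Thermodynamic linkage

`gibbs_free_energy()` converts equilibrium constants with
$\Delta G^0 = -RT\ln K$, $R = 8.314\times10^{-3}$ kJ mol$^{-1}$K$^{-1}$.
The sign convention is fixed and labelled everywhere: $\Delta G(A \to B) =
-RT\ln L$, so positive values mean A is favored, and every ladder row
carries explicit favored-state labels for both the substrate-free and
substrate-bound enzyme. `energy_ladder()` resolves the transition by
modulator occupancy $i$:
$\Delta G^{unbound}_i = -RT\ln(L_U\gamma^i)$ and
$\Delta G^{bound}_i = -RT\ln(L_L\delta^i)$ with
$\gamma = K_{BU}/K_{AU}$, $\delta = K_{BL}/K_{AL}$; the ratios are used at
full precision and rounded only for display. The default temperature is
310.15 K (37 °C assay); it is pinned by the linkage arithmetic itself,
since $RT\ln 4000 = 21.4$ kJ/mol holds at 310.15 K but not at 298.15 K.

```{r ladder}
ladder <- energy_ladder(fixture_scheme("H20S_LIKE"))
print(ladder)
```

For the human-like scheme the substrate-free gap is 32.7 kJ/mol, reduced
by 6.6 kJ/mol upon substrate binding; each modulator binding step
contributes $RT\ln\gamma = 21.4$ kJ/mol (substrate-free) or
$RT\ln\delta = 23.9$ kJ/mol (substrate-bound), so triple occupancy flips
the equilibrium to $-31.5$ kJ/mol in favor of B (the recomputed value;
$-31.4$ if the per-step figure is first rounded to 21.4). Note that a
4000-fold ratio corresponds to 21.4 kJ/mol while 23.9 kJ/mol corresponds
to $\approx 1.06\times10^4$; attributing "about 4000-fold" to both ratios
is a rounding that the package reports as computed, not resolved.

## The synthetic assay generator

`generate_dataset()` emulates the fluorogenic-substrate assay at the
initial-rate level: 2 nM enzyme, substrate grid 5--100 $\mu$M (the 50 and
100 $\mu$M levels exist for linearity demonstrations and are excluded from
fitting by `S_cut`), modulator grid 0 and 0.1--10 $\mu$M, three
replicates, 310.15 K. Noise is multiplicative Gaussian with a 5% default
coefficient of variation (a stand-in; the true experimental scatter of the
motivating data is not known), truncated at zero and requiring an explicit
seed; generation is byte-deterministic per seed and leaves the global RNG
stream untouched. An optional uncompetitive substrate-inhibition term
$v = E_0 k_{cat} S / (K_m + S(1+S/K_{si}))$ — a phenomenological
generator-side device, not part of the allosteric scheme — produces the
loss of double-reciprocal linearity above 25 $\mu$M substrate that the
linearity diagnostics are built to catch. Fluorescence traces are not
simulated; the analysis consumes initial rates.

Three anchored fixtures drive the validation studies:

* `H20S_LIKE` — $n=3, m=0$; $L_U = e^{-32.7/RT}$, $L_L = e^{-26.1/RT}$,
  $\gamma = 4000$, $\delta = e^{23.9/RT}$. Filler values ($K_{AU} = 0.01$,
  $K_{AL} = 0.005\ \mu$M$^{-1}$, $k_{catA} = 1.0$, $k_{catB} = 0.5$
  s$^{-1}$, ${}^0K_m = K_{mA} = 60$, $K_{mB} = 10\ \mu$M) put the
  activation midpoint near 0.5 $\mu$M and completion near 3 $\mu$M.
* `Y20S_LIKE` — $n=2, m=1$, $K_{BI} = 2\ \mu$M$^{-1}$; fillers chosen so
  activation completes by $\approx$1--2 $\mu$M, the observed $K_m$ dips
  and then rises under the competitive site within the 0--10 $\mu$M
  window, and $\gamma = \delta$ holds (the affinity stage's
  identifiability constraint for this site structure).
* `A3DN_LIKE` — the gate-disrupted mutant: $L_U = e^{-8.3/RT}$, equal
  state turnover rates, Michaelis constants above wild type, binding
  constants identical to the yeast-like fixture.

What passing these studies shows — and what it does not: the generator
reproduces the deterministic structure, the heteroscedastic error
propagation and the substrate-inhibition phenomenology of the assay, so
the round-trip results validate the estimation machinery. It does not
emulate pipetting-correlated errors, fluorescence calibration drift,
progress-curve curvature or day effects, so recovery rates on real plates
should be expected to be somewhat worse than the synthetic ones.

## Numerical choices and degenerate inputs

* Optimizer: `minpack.lm::nls.lm`, log-scale boxes
  ($K \in [10^{-7}, 10^{5}]\ \mu$M$^{-1}$, $k_{cat} \in [10^{-5},
  10^{4}]$ s$^{-1}$, $K_m \in [10^{-3}, 10^{5}]\ \mu$M,
  $L \in [10^{-16}, 1]$), `ftol = ptol = 1e-15`, up to 800 iterations,
  8 deterministic starts.
* Velocities of zero (or below) are rejected from reciprocal fits with a
  message; a non-positive intercept is flagged non-physical but returned.
* Profiles flat in modulator trigger the degenerate turnover path rather
  than a spurious fit; groups that cannot be fitted are skipped and
  logged, not fatal.
* The study problem sizes used throughout the package's tests and
  validation scripts are the assay's own: 9 modulator levels, 5 fitted
  substrate levels, 3 replicates, 12 candidate structures, 20-seed noise
  studies and 100--200 bootstrap replicates.

## Known limitations

* Parameter identifiability is the honest bottleneck, not optimization:
  individual binding constants on the saturated side of a transition, and
  $L_L$ for the human-like anchors, are determined only in combination.
  Report intervals, not point values, for those.
* The linkage constraint $\gamma = \delta$ is an assumption, invoked only
  when the data cannot do better; enzymes that violate it and have
  $n+m+1 < 5+[m\ge1]$ cannot be fully resolved by this design.
* The competitive branch is confined to state B by construction; an
  A-state inhibitory site can be loaded (with a warning) but the forward
  equations do not model it.
* Progress curves, substrate depletion and product inhibition are out of
  scope; inputs are initial rates.
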