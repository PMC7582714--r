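# allokin

Two-state concerted allosteric modulation of enzyme kinetics: forward
modelling, rate estimation, staged constrained fitting and free-energy
linkage analysis, with a synthetic-assay generator for validation.

## The problem

Some ligands change an enzyme's steady-state kinetics not by competing at
the active site but by shifting a fast equilibrium between conformational
states. The motivating system is the chymotrypsin-like activity of the 20S
proteasome: a cationic porphyrin binds cooperatively to several surface
sites and stabilizes a second functional state with higher substrate
affinity and lower turnover, so the observed k<sub>cat</sub>,
K<sub>m</sub> and k<sub>cat</sub>/K<sub>m</sub> all move steeply over a
narrow modulator range. `allokin` is for enzymologists who have
initial-velocity data on a (substrate × modulator) design and want to fit
that behaviour with a two-state concerted (MWC-type) model.

## The model

States A and B interconvert rapidly; each follows Michaelis–Menten
kinetics (k<sub>catA</sub>, K<sub>mA</sub>; k<sub>catB</sub>,
K<sub>mB</sub>). The modulator at concentration L binds n concerted
activating sites with state- and substrate-dependent association constants
K<sub>AU</sub>, K<sub>BU</sub>, K<sub>AL</sub>, K<sub>BL</sub>, and
optionally m competitive inhibitory sites confined to state B
(K<sub>BI</sub>; K<sub>AI</sub> = 0). With allosteric constants
L<sub>U</sub> = [B]/[A] (substrate-free) and L<sub>L</sub> (substrate-bound),
the observed turnover is

    obs_kcat(L) = [kcat_A (1+K_AL L)^n + L_L kcat_B (1+K_BL L)^n] /
                  [(1+K_AL L)^n + L_L (1+K_BL L)^n]

with analogous population-weighted expressions for the observed
K<sub>m</sub> and specificity constant. Free energies follow
ΔG⁰ = −RT ln K; the A↔B transition is resolved by modulator occupancy i as
ΔG_i = −RT ln(L γ^i), γ = K<sub>BU</sub>/K<sub>AU</sub>
(δ = K<sub>BL</sub>/K<sub>AL</sub> substrate-bound).

The analysis pipeline is: Lineweaver–Burk double-reciprocal regression per
modulator concentration (restricted to the linear range S ≤ 25 µM, with
delta-method standard errors and a substrate-inhibition linearity
diagnostic) → staged constrained fit (turnover curve first, then the
affinity curves with stage-1 parameters frozen) → minimal-structure
selection of (n, m) → occupancy-resolved free-energy ladder.

## Worked example

Simulate a noiseless assay from the human-like fixture scheme (2 nM
enzyme, substrate 5–100 µM, modulator 0–10 µM, three replicates), estimate
the catalytic profile, and fit with site-number selection:

```r
library(allokin)

scheme  <- fixture_scheme("H20S_LIKE")
assay   <- generate_dataset(scheme, noise = noise_options(cv = 0))
profile <- catalytic_profile(assay)
round(as.data.frame(profile)[1:4, 1:5], 4)
#>   modulator_uM kcat_obs_per_s km_obs_uM eff_obs r_squared
#> 1          0.0         1.0000   59.9978  0.0167         1
#> 2          0.1         0.9950   59.5160  0.0167         1
#> 3          0.3         0.9191   50.8552  0.0181         1
#> 4          0.5         0.7733   33.9747  0.0228         1

fit <- fit_modulation(profile)
fit
#> Two-state concerted allosteric modulation fit
#>   selected sites: n = 3 activating, m = 0 inhibitory
#>   turnover stage:  RSS = 5.89e-11, R^2 = 1.00000
#>   affinity stage:  RSS = 4e-10, R^2(Km) = 1.00000, R^2(eff) = 1.00000
#>   specificity representation: ratio
#>   max relative gap between specificity representations: 0.0174
#>   kcat_A = 1 /s, kcat_B = 0.5 /s, Km0 = 60 uM
#>   K_AL = 0.005, K_BL = 53, K_AU = 0.01, K_BU = 40 (1/uM)
#>   L_U = 3.109e-06, L_L = 4.019e-05
```

The selection lands on three concerted activating sites and no inhibitory
site, and every floated parameter returns at its generating value: the
turnover drops from 1 to 0.5 s⁻¹, the Michaelis constant from 60 µM toward
its saturating-modulator limit of ~2 µM, and the allosteric constants say
the resting enzyme is almost entirely in state A. The corresponding
free-energy ladder:

```r
energy_ladder(fit$scheme)
#> A <-> B free-energy ladder (kJ/mol); positive = A favored
#>   temperature: 310.15 K
#>  occupancy dG_unbound favored dG_bound favored_S
#>          0       32.7       A     26.1         A
#>          1       11.3       A      2.2         A
#>          2      -10.1       B    -21.7         B
#>          3      -31.5       B    -45.6         B
```

The substrate-free A→B gap is 32.7 kJ/mol, 6.6 kJ/mol smaller when
substrate is bound (26.1); each binding step contributes RT ln γ = 21.4
kJ/mol, so the third modulator molecule flips the equilibrium to −31.5
kJ/mol in favor of the activated state. For noisy data the same calls
apply (`noise_options(cv = 0.05, seed = ...)`), with
`bootstrap_confidence()` for intervals — see the methods vignette
(`vignettes/two-state-modulation.Rmd`) for what is and is not identifiable
at realistic noise.

A yeast-like fixture (`Y20S_LIKE`, n = 2 plus one competitive inhibitory
site) and a gate-disrupted-mutant fixture (`A3DN_LIKE`) are included, as
are CSV/JSON serialization (`read_velocity_csv()`, `write_scheme()`, ...),
a programmatic pipeline (`run_command()`) and a thin CLI (`exec/allokin`)
with `simulate`, `estimate`, `fit`, `ladder` and `report` commands.

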