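---
title: "Models and methods: multiple-quantum methyl relaxation and chemical exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: multiple-quantum methyl relaxation and chemical exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqrelax)
```

## The physical problem

A $^{13}$CH$_3$ methyl group in a selectively labelled, perdeuterated protein
supports a rich set of coherences. Besides the zero- and double-quantum
(ZQ/DQ) coherences selected by methyl-TROSY experiments, the four-spin
double-quantum (DQ$'$) and quadruple-quantum (QQ) coherences evolve at
$\omega_C \mp 3\omega_H$ and, like ZQ/DQ, relax with *zero* contribution from
intra-methyl dipolar interactions. That makes them unusually long-lived for
such high-order coherences — and unusually informative, because their
exchange-induced broadening is up to nine times more sensitive to $^1$H
chemical shift differences than that of ZQ/DQ.

When the methyl exchanges between a major state A and a sparsely populated
state B (population $p_B$, rate $k_\mathrm{ex}$), each coherence acquires an
exchange contribution to its transverse relaxation. In the fast limit this is

$$R_\mathrm{ex} = (\xi_C + n\,\xi_H)^2 B_0^2, \qquad
  \xi_X = \sqrt{\tfrac{p_A p_B}{k_\mathrm{ex}}}\,\gamma_X\,\Delta\delta_X
  \times 10^{-6},$$

with $n = -1, +1, -3, +3$ for ZQ, DQ, DQ$'$, QQ. Because ZQ and DQ are
symmetric under $\xi_C \leftrightarrow \xi_H$, two-spin data alone cannot
separate the $^1$H and $^{13}$C shift differences; the four-spin coherences
break that symmetry, so the field dependence of all four Hahn-echo (HE) rates
pins $(\xi_H, \xi_C)$ down to an overall sign.

The package implements this analysis end to end: forward rate calculators,
the two-state exchange engine, the HE field-dependence analysis with
$(\xi_H,\xi_C)$ constraint lines and $\chi^2$ surfaces, CSA control
measurements (quartet lineshape and IPAP fits), and a global joint fit of HE
and CPMG data, together with a synthetic-data generator with known ground
truth.

## Rate model

The total transverse relaxation rate of each coherence is additive:

* **Dipolar** (`dipolar_contribution`): zero intra-methyl contribution; sums
  over external protons and deuterons with fixed coefficient tables per
  coherence, scaled by $\tau_c$. Couplings carry the $P_2(\cos\theta)$
  geometry factor (`dipolar_coupling`).
* **CSA** (`csa_contribution`):
  $(4/45)(\gamma_C\Delta\sigma_C + n\,\gamma_H\Delta\sigma_H)^2 B_0^2
  S^2_\mathrm{axis}\tau_c$.
* **Exchange**: fast-limit Table form (`exchange_contribution_fast`) or, in
  the joint fit, the general closed-form expression
  $$R_\mathrm{ex} = \mathrm{Re}\left\{\tfrac12\left[k_\mathrm{ex} +
  i\Delta\omega - \sqrt{(k_\mathrm{ex}+i\Delta\omega)^2 -
  4ik_\mathrm{ex}p_B\Delta\omega}\right]\right\},$$
  the slowly decaying eigenvalue of the two-site Bloch–McConnell
  Liouvillian (`rex_closed_form`), cross-checked numerically by
  `rex_eigenvalue` (agreement $\le 10^{-8}$ relative over wide random grids).

A note on sign conventions: the sum/difference combinations are defined as
$R_\mathrm{MQ} = (R_\mathrm{ZQ}+R_\mathrm{DQ})/2$ and
$\Delta R_\mathrm{MQ} = (R_\mathrm{ZQ}-R_\mathrm{DQ})/2$. Substituting the
fast-exchange terms gives $\Delta R_\mathrm{MQ,ex} = -2\xi_C\xi_H B_0^2$;
`mq_combine` implements the definitions literally and the tests assert this
(internally consistent) sign rather than the opposite sign sometimes quoted
for the same quantity.

## CPMG propagation

`cpmg_profile` simulates relaxation dispersion by propagating the two-site
amplitude vector through the echo train $[\tau-\pi-\tau]^N$ with ideal
pulses. The pulse count is $N = \nu_\mathrm{CPMG} T$ (an integer by
construction of the frequency list) and the inter-pulse spacing is $T/N$,
the only spacing that tiles the full relaxation period — frequency lists are
therefore multiples of $1/T$ (25 Hz for the default $T = 40$ ms).

* **MQ**: basis $\{$ZQ$-$, ZQ$+$, DQ$-$, DQ$+\}$; an ideal $^{13}$C $\pi$
  pulse is the permutation ZQ$\pm \leftrightarrow$ DQ$\mp$. Amplitude
  starting on one coherence hops between a block pair, so the train reduces
  to alternating $2\times2$ complex propagators (closed-form matrix
  exponentials), combined by exact matrix powers.
* **SQ$_H$**: a $^1$H $\pi$ pulse conjugates the transverse coherence; the
  antilinear element is propagated through its real $4\times4$
  representation.

Two consequences of the physics are worth knowing. First, $^{13}$C pulses
cannot refocus the $^1$H shift difference, so an MQ dispersion plateaus at
$R_{2,0} + R_\mathrm{ex}(\Delta\omega_H)$, not at the bare baseline — this
is why the $^1$H SQ experiment complements the MQ one. Second, ideal-pulse MQ
trains show a genuine sub-0.1 s$^{-1}$ even/odd pulse-count staggering, and
the choice of starting coherence (DQ$+$ vs ZQ$+$, the `start` flag) changes
finite trains at a similar level even though the two cycle propagators share
their eigenvalue spectrum (they are $XY$ vs $YX$ products); the flag's
default is `"DQ"` and the `"avg"` option averages the two signals.

The independent oracle for the SQ experiment, `sq_cpmg_closed_form`,
diagonalises the two-element cycle propagator analytically (quadratic-formula
eigenvalues and spectral projectors) — the exact closed-form two-state
dispersion solution. We implemented the exact form rather than the classic
dominant-eigenvalue approximation because the latter deviates from exact
propagation by up to $\sim$0.15 s$^{-1}$ at intermediate pulsing rates
(confirmed with a Monte-Carlo jump simulation, which also pins the timing
convention); the test suite checks propagation against both the closed form
($\le 0.1$ s$^{-1}$) and the Monte-Carlo oracle.

## Hahn-echo field-dependence analysis

`fit_decay` fits $A e^{-RT}$ by profiling the amplitude in closed form and
minimising over the rate in one dimension — exact for the model class and
free of starting-value pathologies; errors come from the Gauss–Newton
curvature, and a 1000-seed Monte-Carlo test confirms 3$\sigma$ calibration.
`regress_field` is inverse-variance weighted linear regression of rates on
$B_0^2$ with known errors, so the covariance is $(X^TWX)^{-1}$ without
residual rescaling. `subtract_csa` removes the computed CSA coefficient and
propagates first-order errors from the slope, CSA values and
$S^2_\mathrm{axis}\tau_c$.

`xi_surface` evaluates, at each grid point, the per-coherence coefficient
$\beta = \beta_\mathrm{CSA} + (\xi_C + n\xi_H)^2$ and profiles the
per-coherence $R_{2,0}$ out in closed form (weighted mean of
$r - \beta B_0^2$), rather than refitting numerically — exact, fast, and
fully vectorised over the grid. Negative measured $\beta_\mathrm{ex}$ is not
clipped; since $(\xi_C+n\xi_H)^2 \ge 0$ it simply raises the $\chi^2$ floor.
The default grid spans $\pm1.5\times$ the largest $|\sqrt{\beta_\mathrm{ex}}|$
at $301\times301$ points. Confidence contours use the two-parameter
$\Delta\chi^2$ thresholds 2.30 (68 %) and 6.18 (95 %); the source data do
not state their contour convention, so the two-parameter choice is our
documented decision. A 200-replicate simulation at 2 % rate noise confirms
$\ge 90$ % containment of the truth by the 95 % region.

Diagnostics: for consistent two-state fast exchange the four constraint-line
pairs `xi_constraint_lines` are concurrent at $\pm(\xi_H,\xi_C)$
(`xi_line_intersections`); inconsistent data — e.g. a third state with
uncorrelated $^1$H/$^{13}$C fluctuations — leave the lines non-concurrent
and the $\chi^2$ minimum positive.

## CSA control measurements

`quartet_lineshape` implements the relaxation-weighted $^1$H-coupled HSQC
multiplet: four $^{13}$C Lorentzians at $\pm\pi J, \pm3\pi J$ with
intensities $3+3\Delta$ (outer) and $3-\Delta$ (inner),
$\Delta = e^{-4\eta_{HHHH}\tau}\cosh(2\eta_{HHHC}\tau)$, $\tau = 1/(2J)$,
and line-specific decays built from $\eta_{CHCH}$ and $\eta_{CHC}$
(`eta_rates`). $S^2_\mathrm{axis}\tau_c$ is encoded in the inner/outer
intensity ratio and $\Delta\sigma_C$ in the up-/downfield decay asymmetry
($e^{-6\eta_{CHC}T}$ between the outer lines). The Lorentzian is
$L(\omega;\omega_0,R) = R/(R^2 + (\omega-\omega_0)^2)$ (normalisation
absorbed into the amplitude). `fit_quartet_cluster` fits all peaks of a
cluster jointly on the shared grid with positions fixed from a decoupled
reference spectrum; $J$ is bounded to 100–150 Hz and initialised at 125 Hz.
The $(S^2_\mathrm{axis}\tau_c, \Delta\sigma_C)$ pair has a secondary optimum
of opposite asymmetry, so the fitter restarts from a small sign/magnitude
grid and keeps the best solution. Peaks are grouped by single-linkage within
0.05 ppm ($^1$H) $\times$ 2.4 ppm ($^{13}$C) strips (`cluster_peaks`).

`ipap_h_csa` fits the $^{13}$C $|\alpha\rangle$/$|\beta\rangle$ sub-spectrum
decays, forms $\eta_H = (R_\alpha - R_\beta)/2$ and inverts the CSA–dipole
cross-correlation expression for $\Delta\sigma_H$, propagating both rate
errors and the $S^2_\mathrm{axis}\tau_c$ uncertainty.

## Global joint fit

`global_fit` couples all HE rates (four coherences, all fields) and CPMG
profiles (MQ at two fields, $^1$H SQ at one, by default) to a shared
two-state model per cluster using Levenberg–Marquardt on error-weighted
residuals. Free parameters: per cluster $\log_{10}k_\mathrm{ex}$ and $p_B$;
per methyl $\Delta\delta_C \ge 0$ (fixing the global sign convention) and
$\Delta\delta_H$; one field-independent $R_{2,0}$ per (methyl, HE coherence);
one baseline per (methyl, CPMG experiment, field). The dipolar $R_{2,0}$ is
field-independent, while CPMG constant-time baselines are not comparable
across experiments, hence the separate parameterisation — a documented
choice where the convention is genuinely open. CSA parameters and
$S^2_\mathrm{axis}\tau_c$ are fixed inputs, never co-fitted, since separate
experiments determine them.

Numerical choices: multi-start over $k_\mathrm{ex} \in [10^2, 10^5]$ s$^{-1}$
(log-spaced) and $p_B \in \{0.02, 0.1\}$; the relative sign of
$\Delta\delta_H$ against $\Delta\delta_C$ is a discrete branch that LM steps
cannot cross, so after the best start converges each methyl's
$\Delta\delta_H$ is greedily sign-flipped and refit (`sign_refine`).
Standard errors come from the inverse Gauss–Newton Hessian ($\chi^2$
curvature) at the optimum; correlations above 0.95 are flagged — in the
fast-exchange regime $p_B$ and the shift differences ride a ridge that HE
data alone cannot resolve, visible as a $\sim$10–100$\times$ larger Hessian
condition number than the joint fit. `back_calculate_xi` converts fitted
parameters to $(\xi_H,\xi_C)$ for comparison with the HE-only surface.

## Synthetic data and what the tests show

The generator (`gen_he`, `gen_cpmg`, `gen_pseudo3d`) adds Gaussian noise to
*amplitudes/intensities*, not to rates: rate errors then emerge from the
fitting chain exactly as in a real pipeline. Two presets mirror the regimes
the methods target: a "slow-cluster" ($p_B = 0.029$,
$k_\mathrm{ex} = 872$ s$^{-1}$) and a "fast-cluster"
($k_\mathrm{ex} = 6900$ s$^{-1}$); no population is reported for fast
two-site clusters of this kind, so the preset uses $p_B = 0.05$ as a
realistic fast-exchange population. Each preset has two methyls with shift
differences of 0.8/0.5 ppm ($^{13}$C) and $-0.12$/0.08 ppm ($^1$H), CSAs and
$S^2_\mathrm{axis}\tau_c$ (8–10 ns) typical of a small domain, exchange-free
rates of 14–34 s$^{-1}$, four fields (600/700/800/950 MHz) with realistic
per-field delay lists, and 28 CPMG frequencies from 25 Hz to 2 kHz over a
40 ms period.

`true_he_rates` offers two compositions: `"eigenvalue"` (general regime; the
joint-fit model class) and `"fast"` (Table-form fast limit; the
field-regression model class is then exact by construction). Geometry tests
use the latter, recovery tests the former.

Problem sizes in the routine test run are scaled for a single CPU: the
calibration studies use 100 joint-fit replicates (with 14 CPMG frequencies
and starts on the known sign branch, isolating interval calibration from
global-search robustness), 200 surface replicates, and 1000 decay-fit
replicates. The generator emulates exponential amplitude decays, two-state
dispersions, and noise-free lineshapes of the stated model classes; it does
not emulate pulse imperfections, off-resonance effects, spectral overlap
beyond Lorentzian superposition, baseline or phase distortions, or
FID-level processing. Passing tests therefore demonstrate correctness of the
estimators under the stated noise model, not robustness to those
instrumental effects.

## The CSA-impact summary

For a worked parameter set ($\Delta\delta_C = 1.5$ ppm,
$\Delta\delta_H = 0.2$ ppm, $p_B = 0.1$, $k_\mathrm{ex} = 5000$ s$^{-1}$,
$S^2_\mathrm{axis}\tau_c = 50$ ns, valine-type CSAs
$34.2$ and $0.29$ ppm) the acceptance script reports the relative impact of
each CSA on the measured rates as the CSA-only $B_0^2$ coefficient (at
$|n|=1$) divided by the ZQ/DQ-mean exchange coefficient
$(\xi_C^2 + \xi_H^2)$: about 10 % for the $^{13}$C CSA and about 0.01 % for
the $^1$H CSA. The message is quantitative but simple — neglecting the
$^{13}$C CSA would bias exchange estimates at the ten-percent level, so
residue-type average values (contributing $\sim$1 % uncertainty) suffice for
most purposes, while the $^1$H CSA is negligible except at the highest
fields.

## Known limitations

* Two-state exchange only; three-state behaviour is detected only
  diagnostically (non-concurrent constraint lines, elevated $\chi^2$ floor).
* Ideal pulses: no off-resonance or miscalibration effects in the CPMG
  propagation.
* Absolute signs of the shift differences are not determined (the model is
  invariant under joint negation; reports fix $\Delta\delta_C \ge 0$).
* The quartet model assumes a single effective $J_{CH}$ per peak and
  Lorentzian lines; apodisation and processing effects are not modelled.
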