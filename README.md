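# mqrelax

Analysis of chemical exchange in ¹³CH₃ methyl groups from multiple-quantum
NMR relaxation. The package is written for spectroscopists who measure
Hahn-echo (HE) transverse relaxation rates of methyl zero-, double-,
four-spin double- and quadruple-quantum coherences (ZQ, DQ, DQ′, QQ) at
several static fields, optionally alongside CPMG relaxation dispersion, and
want to turn those measurements into populations, exchange rates and
per-nucleus chemical shift differences of sparsely populated states.

## The model

For two-state exchange A ⇌ B (minor population $p_B$, rate
$k_\mathrm{ex}$), each methyl coherence with ¹H frequency coefficient
$n \in \{-1,+1,-3,+3\}$ acquires a fast-exchange broadening

$$R_\mathrm{ex} = (\xi_C + n\,\xi_H)^2 B_0^2,\qquad
\xi_X = \sqrt{p_A p_B/k_\mathrm{ex}}\;\gamma_X\,\Delta\delta_X\times10^{-6}.$$

ZQ/DQ data are symmetric in $(\xi_H,\xi_C)$; adding the four-spin DQ′/QQ
rates (9× more sensitive to ¹H shift differences) breaks the symmetry and
determines both, up to a global sign. Beyond the fast limit the package uses
the exact closed-form broadening
$R_\mathrm{ex}=\mathrm{Re}\{[k_\mathrm{ex}+i\Delta\omega-\sqrt{(k_\mathrm{ex}+i\Delta\omega)^2-4ik_\mathrm{ex}p_B\Delta\omega}]/2\}$
(the slow eigenvalue of the Bloch–McConnell Liouvillian) and numerical
propagation of CPMG echo trains in the {ZQ−, ZQ+, DQ−, DQ+} or {Hx, Hy}
bases with ideal pulses.

Main function families:

| area | functions |
|---|---|
| forward rates | `csa_contribution`, `exchange_contribution_fast`, `dipolar_contribution`, `mq_combine` |
| exchange engine | `rex_closed_form`, `rex_eigenvalue`, `cpmg_profile`, `sq_cpmg_closed_form` |
| HE analysis | `fit_decay`, `regress_field`, `subtract_csa`, `xi_surface`, `xi_line_intersections` |
| CSA controls | `eta_rates`, `quartet_lineshape`, `fit_quartet_cluster`, `ipap_h_csa` |
| joint fit | `global_fit`, `exchange_parameters`, `back_calculate_xi` |
| synthetic data | `truth_preset`, `gen_he`, `gen_cpmg`, `gen_pseudo3d` |
| I/O | `read_rate_table`, `read_cpmg_table`, `read_spectrum_grid`, `read_run_config`, `write_manifest` |

## Worked example

Simulate a two-methyl cluster exchanging at $k_\mathrm{ex} = 872$ s⁻¹ with
$p_B = 0.029$, fit the decays, and jointly fit HE + CPMG:

```r
library(mqrelax)

truth <- truth_preset("slow-cluster")
he  <- he_rate_table(gen_he(truth, sigma_rel = 0.02, seed = 11))
cp  <- gen_cpmg(truth, sigma_rel = 0.02, seed = 12)
fit <- global_fit(he, cp, truth_cluster_table(truth), truth_csa_table(truth))
fit
#> <mq_fit> chi2 = 156.4 on 180 dof
#>   cluster c1: kex = 867.8 +/- 83.2 s^-1, pB = 0.02937 +/- 0.00284
back_calculate_xi(fit)
#>   methyl_id      xi_C       xi_H
#> 1        M1 0.3136030 -0.1792228
#> 2        M2 0.1977662  0.1188217
```

The fitted exchange rate and population recover the generating values
(872 s⁻¹, 0.029) well within their standard errors, and the back-calculated
normalised shift differences match the truth
(ξ_C, ξ_H) = (0.306, −0.182) and (0.191, 0.122) for the two methyls.

The HE-only geometric analysis of one methyl:

```r
tab  <- true_he_rates(truth, rex_mode = "fast"); tab$err <- 1
m1   <- truth$methyls[1, ]
sys1 <- methyl_system(m1$s2tau_ns * 1e-9, dsigma_C = m1$dSigmaC_ppm,
                      dsigma_H = m1$dSigmaH_ppm)
s <- xi_surface(tab[tab$methyl_id == "M1", ], sys1)
s
#> <xi_surface> 301 x 301 grid; min chi2 = 6.69 at (xi_H, xi_C) = +/-(0.1792, -0.3157)
plot(s)   # 68 % / 95 % contours around the +/- minima
```

The surface minimum sits at the generating (ξ_H, ξ_C) = (−0.182, 0.306) up
to grid resolution, with the mirrored solution at the opposite sign.

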