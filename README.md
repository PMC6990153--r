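# ikrfit

Tools for characterising the kinetics of the rapid delayed-rectifier
potassium current (IKr, the hERG channel current) from whole-cell
voltage-clamp recordings, built around a two-gate Hodgkin–Huxley model:

```
I_Kr = g_Kr · a · r · (V − E_K)

da/dt = (a∞ − a)/τ_a        τ_a = 1/(k₁+k₂)   a∞ = k₁·τ_a
dr/dt = (r∞ − r)/τ_r        τ_r = 1/(k₃+k₄)   r∞ = k₄·τ_r

k₁ = p₁·e^{p₂V}   k₂ = p₃·e^{−p₄V}   k₃ = p₅·e^{p₆V}   k₄ = p₇·e^{−p₈V}
```

Nine strictly positive parameters (p₁…p₈ kinetics, p₉ = g_Kr) are
estimated from current traces by four complementary routes:

1. **Direct summary fit** — algebraic inversion of steady-state /
   time-constant summary curves (Boltzmann fits + log-linear rate
   regressions + closed-form conductance scaling); deterministic, one
   simulation total.
2. **Simulated summary fit** — CMA-ES against summary curves extracted
   from *simulated* step protocols with the identical analysis pipeline.
3. **Whole-trace fit, step protocols** — CMA-ES against the raw currents
   of four conventional step protocols (228 s of recording), simulated
   exactly by piecewise exponentials.
4. **Whole-trace fit, sine-wave protocol** — CMA-ES against a single 8 s
   step-plus-three-sines protocol.

The package also provides: protocol builders and a capacitance-blanking
mask, an adaptive Dormand–Prince simulator with dense output (C++), the
summary-curve extraction pipeline, the normalized-RMSE error measures
(`e_m1`…`e_m4`, `e_ap`), bounded log-transformed CMA-ES with multi-start
and reliability reporting, an AP-waveform validation protocol, a
synthetic-cell generator with known ground truth, and a cross-validation
workbench. See `vignettes/fitting-ikr-models.Rmd` for the science and
the design decisions.

## Worked example

Generate a synthetic cell with known truth, fit it with the direct
summary fit and the sine-wave whole-trace fit, and validate on the AP
waveform protocol:

```r
library(ikrfit)

prot <- default_protocols(dt = 1)              # coarse sampling for speed
prot$Pr7 <- build_pr7(list(dt = 0.2))
prot$Pr6 <- generate_ap_waveform(seed = 11, dt = 1)
cell <- generate_cell(synthetic_spec(seed = 11, protocols = prot))
print(cell$summary)
#> Summary curves (points): act_ss 7 | inact_ss 8 | tau_act 9 | tau_inact 17 | iv 9

m1 <- method1_fit(cell$summary, prot$Pr5, cell$conditions)
ms4 <- multi_start(make_objective(cell, 4), n_repeats = 5,
                   config = cmaes_config(max_iters = 450), seed = 1,
                   starts = rbind(seeded_start_from_method1(m1),
                                  sample_start_points(4, seed = 2)),
                   method = 4)
round(as.numeric(ms4$best$params) / as.numeric(cell$truth) - 1, 3)
#> [1]  0.051 -0.020 -0.025  0.004  0.005  0.021  0.019 -0.007 -0.010

round(c(e_ap(m1, cell), e_ap(ms4$best$params, cell)), 4)
#> [1] 0.1309 0.1198
```

The whole-trace fit lands within ~5% of the generating parameters (the
activation pre-factor p1 is the least identifiable quantity from the
short sine-wave recording; the 228 s step-protocol fit pins it to ~1%).
The AP-waveform validation error of the direct summary fit (0.131) sits
above the whole-trace fit's (0.120), which is at the iid-noise floor —
the cell was generated with noise at 2% of the sine-protocol current
range. The numbers above are what the code prints for these seeds;
rerun the block to reproduce them.

## Command line

```sh
Rscript -e 'ikrfit::ikr_cli()' synth --out cell/ --seed 1
Rscript -e 'ikrfit::ikr_cli()' fit --method 4 --cell-dir cell/ --repeats 10 --out fit.json
Rscript -e 'ikrfit::ikr_cli()' score --method ap --params fit.json --cell-dir cell/
```
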