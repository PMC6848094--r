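# hepflux

Quantitative analysis of hepatic pyruvate metabolism from ¹³C NMR data of
isolated perfused livers.

Livers perfused with [U-¹³C]lactate/[U-¹³C]pyruvate distribute ¹³C through
the TCA cycle; the fine structure (singlet/doublet/triplet/quartet
multiplets) of the glutamate C2, C3, C4 and lactate C2 resonances encodes
the relative fluxes through pyruvate dehydrogenase (PDH), pyruvate
carboxylase (PC) and pyruvate cycling (PyC, the carboxylation/
decarboxylation loop through PEPCK/pyruvate kinase or malic enzyme).
`hepflux` implements:

- a **steady-state isotopomer model** of the hepatic carbon-transition
  network (PDH, PC, citrate synthase, the TCA turn with symmetric
  succinate/fumarate scrambling, pyruvate cycling, LDH exchange), solved as
  a fixed point of the label-balance equations over all 2ⁿ labeling states
  per pool;
- a **multiplet predictor and flux-fitting engine**: bounded multi-start
  nonlinear least squares recovering `f_acetyl_labeled` (labeled acetyl-CoA
  fraction), `f_pyr_medium` (medium share of the pyruvate pool),
  `y_pc = V_PC/V_TCA` and `y_pyc = V_PyC/V_TCA` from measured multiplet
  areas;
- **absolute-flux scaling** from hepatic oxygen consumption:
  MVO₂ = ΔpO₂ × αO₂ × flow / weight, V_TCA solved from a configurable O₂
  stoichiometry, and V_PDH/V_PC/V_PyC = relative fluxes × V_TCA, plus the
  cycling indices V_PyC/(V_PC + V_PDH) and (C2D₂₃ + C2D₁₂)/total C2;
- a **hyperpolarized [1-¹³C]pyruvate simulator/quantifier**: pulsed
  acquisitions (default 50 spectra, 2 s apart, 20° pulses) of a
  unidirectional first-order exchange network with T₁ decay, Lorentzian
  spectral rendering, window integration and hydrate-excluded normalized
  fractions with the bicarbonate/lactate ratio;
- a **synthetic cohort generator** (four groups: lean/DIO × control/PDK2-4
  double knockout) reproducing the group-level flux structure, so every
  stage is testable without experimental data.

## Worked example

Forward-predict multiplets at lean-control-like fluxes, fit them back, and
scale with oxygen data:

```r
library(hepflux)

fl <- relative_fluxes(f_acetyl_labeled = 0.49, f_pyr_medium = 0.19,
                      y_pc = 2.78, y_pyc = 1.85)
pred <- predict_multiplets(fl)
round(pred$glu_C4, 3)
#>     S   D34   D45     Q
#> 0.000 0.000 0.723 0.277
round(pred$lac_C2, 3)
#>     S   D12   D23     Q
#> 0.093 0.174 0.214 0.519
```

C4 shows no singlet (C5 is always co-labeled with C4: both carbons come
from the same acetyl unit) and a D45/Q split set by the C3 enrichment; the
lactate C2 doublets (D12 + D23 = 0.39) are the signature of label returned
by pyruvate cycling.

```r
tab <- do.call(rbind, lapply(names(pred), function(cb)
  data.frame(liver_id = "liver1", group = "lean-control", carbon = cb,
             component = names(pred[[cb]]), fraction = unname(pred[[cb]]),
             sd = 0.01)))
fit <- fit_relative_fluxes(tab, n_starts = 8, seed = 1)
fit
#> Relative-flux fit (acetyl dilution)
#> f_acetyl_labeled     f_pyr_medium             y_pc            r_cyc
#>           0.4900           0.1900           2.7800           0.6655
#>            y_pyc       f_pdh_frac
#>           1.8500           0.4900
#> weighted SSQ: 8.071e-17  starts at optimum: 8

mvo2 <- oxygen_consumption(list(pO2_afferent = 560, pO2_efferent = 399,
                                flow = 8, liver_weight = 1.5))
v_tca <- tca_flux_from_mvo2(mvo2, fit)     # 0.431 umol/min/gww
af <- absolute_fluxes(fit, v_tca, mvo2 = mvo2)
c(v_pdh = af$v_pdh, v_pc = af$v_pc, v_pyc = af$v_pyc)
#>  v_pdh   v_pc  v_pyc
#>  0.211  1.197  0.797
cycling_degree(af)                          # 0.57
```

The generating parameters are recovered to four decimals from noiseless
data, and roughly half of the TCA-cycle carbon turnover is spent cycling
pyruvate in and out of the four-carbon pool.

A full cohort goes through `run_pipeline()`:

```r
spec <- cohort_spec(seed = 1)                       # 4 groups x 4 livers
ds   <- generate_multiplet_dataset(spec)
perf <- generate_perfusion_records(spec, truth = ds$truth)
res  <- run_pipeline(list(multiplet_table = ds$table,
                          perfusion_records = perf, seed = 1))
res$group_summary                                    # mean +/- SD per group
res$group_tests                                      # Welch / ANOVA + Tukey
```

`generate_hp_dataset()` + `sum_spectra()` + `integrate_peaks()` +
`normalize_fractions()` do the same for the hyperpolarized read-out.

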