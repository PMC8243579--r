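# iegkinetics

Kinetic modelling of immediate-early-gene (IEG) fluorescence dynamics for
identifying and segregating neuronal ensembles in longitudinal in vivo
imaging.

## The problem

Immediate early genes such as *cfos* are transcribed rapidly and
transiently when a neuron is activated, so a fluorophore expressed under
the *cfos* promoter turns each nucleus into a slow reporter of recent
activity. Imaging the same cortical field for hours after a behavioural
event yields one fluorescence time course per nucleus. Because protein
synthesis and degradation follow consecutive first-order kinetics, the
**shape** of that time course tells you not just *whether* a neuron was
activated but *when* — and whether it was activated once or twice. That
turns a single fluorophore into a multi-event activity tag: cells
responding to two context exposures an hour apart can be separated from
cells responding to only one of them, and the resulting ensembles can be
compared across days.

`iegkinetics` implements the full analysis chain:

1. **Kinetics core** — closed-form single-activation (SAC) and
   double-activation (DAC) expression profiles and derived quantities
   (peak time, rise/decay times).
2. **Synthetic data** — trace, population, and 4D image-stack generators
   with recorded ground truth, emulating the two imaging protocols
   (single-exposure session sampled 20–180 min; dual-exposure session
   sampled 90–300 min, exposures 60 min apart).
3. **Trace extraction** — ROI centre-of-mass re-centering, mean-intensity
   z profiles, Gaussian z-peak estimation, and annulus background
   subtraction, converting stacks + ROI tables into traces.
4. **Model fitting** — Levenberg–Marquardt least squares of both
   profiles, adjusted R², least-squares AIC, and per-session model
   selection.
5. **Ensemble classification** — context activation flags, the
   eight-category context-representation table, ensemble fractions and
   overlap versus chance, DAC-fraction comparisons, amplitude-binned
   reactivation probability.
6. **Population statistics** — rate-constant histograms with one- versus
   two-component Gaussian fits chosen by AIC.
7. **Pipeline / CLI** — `cmd_simulate()`, `cmd_extract()`, `cmd_fit()`,
   `cmd_classify()`, `cmd_report()` over CSV/TIFF/YAML/JSON files, and an
   `ieg-pipeline` script.

## The model

A single activation event at `t = 0` drives the scheme
mRNA →(k_f) protein →(k_d) degraded protein, giving fluorescence

```
F1(t) = A · k_f / (k_f − k_d) · (exp(−k_d t) − exp(−k_f t))
```

with the analytic limit `A k_f t exp(−k_f t)` when `k_f = k_d`. A neuron
activated a second time at `t_d` superposes a shifted copy sharing the
same amplitude and rates:

```
F2(t) = F1(t) + [t ≥ t_d] · F1(t − t_d)
```

The profile peaks at `T_max = ln(k_f / k_d) / (k_f − k_d)`; `1/k_f` and
`1/k_d` are the characteristic rise and decay times. A cell counts as
activated when its best fit has adjusted R² > 0.5; SAC vs DAC is
arbitrated by the least-squares AIC `n ln(RSS/n) + 2(p+1)`.

## Worked example

```r
library(iegkinetics)

p <- kinetic_params(amplitude = 1200, kf = 0.0369, kd = 0.016)
p
#> Single activation kinetic parameters
#>   amplitude: 1200 D.U.
#>   kf: 0.0369 /min  (rise time 27.1 min)
#>   kd: 0.016 /min  (decay time 62.5 min)
time_to_peak(p)
#> [1] 39.98195

# simulate one noisy trace on the single-exposure grid and refit it
tr  <- gen_trace("SAC", p, is1_protocol(), noise_model(scale = 0.05, seed = 42))
fit_sac(tr)
#> SAC fit for 'roi_1' (converged)
#>   estimates: amplitude = 1250.8, kf = 0.03559, kd = 0.016312
#>   n = 17, RSS = 4573.2, Adj-R-sq = 0.9901, AIC = 103.1108

# dual-exposure session: arbitrate one-event vs two-event profiles by AIC
trd <- gen_trace("DAC", dual_activation_params(1200, 0.0369, 0.016, 60),
                 is2_protocol(), noise_model(scale = 0.05, seed = 42))
res <- fit_session(trd, c("SAC", "SAC_DELAYED", "DAC"))
res$selected$model_kind
#> [1] "DAC"

# a cell fitting SAC in session 1 and DAC in session 2 is present in all
# three context exposures (category 1 of 8)
classify_cells(data.frame(roi_id = "cell_0001",
                          is1_kind = "SAC", is2_kind = "DAC"))
#>      roi_id   a1   a2    b category
#> 1 cell_0001 TRUE TRUE TRUE        1
```

The fitted amplitude is the model amplitude `A` in detector units (D.U.),
the rates are in min⁻¹; `a1`, `a2`, `b` flag activation by context A
(session 1), context A (session 2) and context B respectively.

The whole pipeline runs from the shell:

```sh
Rscript inst/scripts/ieg-pipeline all --seed 1 --out-dir ieg_out --verbose
```

writing traces, per-cell fit tables (amplitude, rates, their standard
errors, t_d, Adj-R-sq, AIC), the classification CSV, ensemble-fraction
JSON, histograms and reactivation bins.

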