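# cardiolab

A lumped-parameter simulator of human cardiovascular mechanics for
teaching and scripted experiments. It models the heart chambers as
time-varying elastances (Suga–Sagawa framework), the valves as ideal
diodes, and the arteries as Windkessel compliances, advanced by a
deterministic explicit recursion at a fixed 1 ms step. A rate-dependent
ECG timing generator (quadratic interval functions of the cycle length)
triggers the mechanical activity and yields the diastolic heart fraction.

Two configurations are built in:

* **IHL** — an isolated left heart (5 compartments) filled from a
  constant-pressure venous source, for preload/afterload/contractility
  experiments (Frank–Starling curves, pressure–volume loops);
* **CCL** — a closed double circulation (10 compartments) with all four
  chambers and the systemic and pulmonary beds, conserving total blood
  volume exactly.

At its core, each chamber obeys

    P(t) = E(t) · max(V(t) − V0, 0),
    E(t) = Emin + a(t) · (Emax_eff − Emin),   Emax_eff = (c/100) · Emax_ref

with a raised-cosine activation a(t) driven by the ECG trigger schedule,
each vessel obeys `P = max((V − Vu)/C, 0)`, and each valve passes
`q = max(ΔP, 0)/R`. Seven user-facing parameters with published defaults
and closed limits are exposed: CVP (IHL), heart rate, LV/RV
contractility, total peripheral resistance, aortic compliance, total lung
resistance and blood volume (CCL). See
`vignettes/cardiolab-methods.Rmd` for the full model description.

## Worked example

```r
library(cardiolab)

params <- default_parameters("CCL")   # heart rate 70, blood volume 5.2 l, ...
ss <- run_to_steady_state(params)
ss$cycle
#> [1] 13
ss$metrics
#> <summary_metrics> hr 70 min^-1
#>   EDV 133.6 ml  ESV 57.8 ml  SV 75.9 ml  EF 0.57
#>   CO 5311 ml/min  BP 120/84 mmHg  pulse pressure 36 mmHg  DHF 0.55
```

The closed loop settles in 13 cycles at a resting operating point:
end-diastolic volume 133.6 ml, stroke volume 75.9 ml, cardiac output
5.3 l/min, aortic pressure 120/84 mmHg, and 55% of the cycle spent in
mechanical diastole. A steady-state sweep reproduces the falling stroke
volume of an isolated heart paced faster at constant preload:

```r
sweep_parameter(default_parameters("IHL"), "hr", seq(40, 160, 40),
                metrics = c("sv", "co"))
#>    hr       sv       co
#> 1  40 85.67264 3426.906
#> 2  80 55.77536 4462.029
#> 3 120 40.66025 4879.230
#> 4 160 31.77372 5083.795
```

Stroke volume falls with rate (shorter diastolic filling) while cardiac
output still rises — the behaviour of a denervated heart without
sympathetic support. Traces (`run_model()`), live parameter changes
(`set_parameter()`), the synthesized ECG (`synthesize_ecg_cycle()`) and
the atrioventricular-plane animation geometry (`avpd_geometry()`) are
documented in the help pages.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/cardiolab run --model ccl --duration 30 --out trace.csv --summary summary.json
Rscript inst/cli/cardiolab sweep --model ihl --param hr --values 40:160:10 --metrics sv,co --out sweep.csv
Rscript inst/cli/cardiolab ecg --hr 70 --out ecg.csv
Rscript inst/cli/cardiolab atrial --hr 160
Rscript inst/cli/cardiolab info
```

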