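# oxyvib

Accelerometer-based vibration monitoring of the membrane oxygenator during
venovenous ECMO (extracorporeal membrane oxygenation).

Oxygenator thrombosis is a feared circuit complication. The conventional
surveillance metric — the transmembrane pressure drop ΔP_oxy — responds late
and depends on where the clot sits in the fiber bundle. A triaxial
accelerometer clamped to the oxygenator housing senses clot- and
turbulence-related changes in vibration energy, which can shift *before*
ΔP_oxy does. `oxyvib` is for signal-processing and perfusion researchers who
want to analyze such recordings, and for methodologists who want a fully
synthetic, ground-truthed testbed for the approach.

## What it computes

For axis signals g_x, g_y, g_z (in g, sampled uniformly at f_s):

1. **Omnidirectional norm** g_xyz = √(g_x² + g_y² + g_z²);
2. **Brick-wall bandpass**: FFT, zero every coefficient outside 10–375 Hz,
   inverse FFT with conjugate-symmetric (purely real) reconstruction;
3. **Windowed RMS**: non-overlapping 30-s windows, each summarized as
   √mean(x²) — the vibration metric **RMS_oxy**, with the per-subject percent
   change from its phase baseline, **ΔRMS_oxy**.

Cohort reporting uses median (min–max) cells with **exact paired Wilcoxon
signed-rank tests** (full enumeration of the signed-rank null via dynamic
programming; mid-ranks for ties; zeros dropped by default; significance at
p ≤ 0.05). With n = 7 all-increased pairs the exact two-sided p is
2/2⁷ = 0.015625, printed as 0.02.

A synthetic cohort generator emulates a two-phase porcine protocol —
a pump-speed sweep (flows 3.5/4.0/4.5 L/min) and an anticoagulation-reversal
phase with a configurable thrombosis gain and a transmembrane-pressure
response lagging the vibration response — with per-subject ground truth, so
the whole pipeline is testable without animal data. `detection_lead_time()`
measures how far vibration leads pressure in crossing matched fractional
thresholds.

## Worked example

Simulate a 7-subject cohort (shortened phases for speed), run the chain, and
print the cohort report:

```r
library(oxyvib)

cfg <- run_config(
  mode = "simulate",
  sim  = sim_config(n_subjects = 7, level_duration_s = 120,
                    pre_reversal_s = 120, post_reversal_s = 1800,
                    seed = 11))
run <- run_pipeline(cfg)
print(run)
```

```
<oxyvib_run 004ca27f: 7 subjects, 378 metric rows>

== pump_speed block ==
metric        baseline              medium                          high                          
--------------------------------------------------------------------------------------------------
rms_oxy       0.343 (0.266 - 0.38)  0.393 (0.321 - 0.469)  p=0.02*  0.571 (0.526 - 0.753)  p=0.02*
delta_p_oxy   12.2 (12 - 12.3)      18.7 (18.7 - 18.8)  p=0.02*     25.5 (25.4 - 25.6)  p=0.02*   
ecmo_flow     3.52 (3.51 - 3.52)    4.01 (4.01 - 4.02)  p=0.02*     4.47 (4.46 - 4.47)  p=0.02*   
heart_rate    78 (73 - 103)         85.7 (80.5 - 112)  p=0.02*      85.3 (80.3 - 111)  p=0.02*    
map           76.8 (68.8 - 85.4)    77.2 (69.4 - 85.7)  p=0.03*     76.8 (68.4 - 84.6)  p=0.22    
cvp           7.31 (5.81 - 8.56)    7.37 (5.78 - 8.63)  p=1.00      7.43 (5.97 - 8.74)  p=0.02*   
mpap          20.3 (18.7 - 22)      20.3 (18.7 - 22.2)  p=0.94      20.5 (18.6 - 22.3)  p=0.38    
spo2          99.7 (99.6 - 99.8)    99.7 (99.6 - 99.8)  p=0.94      99.7 (99.6 - 99.7)  p=0.47    
act_s         214 (193 - 237)       214 (193 - 237)  p=1.00         214 (193 - 237)  p=1.00       
drms_oxy_pct                        20.8 (14.3 - 28.9)  p=0.02*     94.9 (66.2 - 107)  p=0.02*    

Data as median (min - max); * p <= 0.05 (exact Wilcoxon signed-rank vs 'baseline').

== reversal block ==
metric        baseline              t15                             t30                           
--------------------------------------------------------------------------------------------------
rms_oxy       0.342 (0.266 - 0.38)  0.353 (0.283 - 0.405)  p=0.02*  0.346 (0.273 - 0.392)  p=0.02*
delta_p_oxy   12 (11.9 - 12.2)      9.82 (9.65 - 9.86)  p=0.02*     13.5 (13.4 - 13.7)  p=0.02*   
ecmo_flow     3.5 (3.5 - 3.51)      3.3 (3.3 - 3.31)  p=0.02*       3.2 (3.2 - 3.21)  p=0.02*     
heart_rate    77.1 (72.6 - 103)     77.3 (72.6 - 103)  p=0.94       77.3 (72.8 - 103)  p=0.22     
map           76.8 (68.7 - 85.4)    75.7 (67.4 - 83.8)  p=0.02*     75.6 (67 - 83.4)  p=0.02*     
cvp           7.22 (6 - 8.57)       7.33 (5.83 - 8.66)  p=0.38      7.52 (5.99 - 8.83)  p=0.69    
mpap          20.3 (18.5 - 22.1)    20.6 (18.6 - 22)  p=0.22        20.5 (18.6 - 21.9)  p=0.81    
spo2          99.7 (99.6 - 99.8)    99.7 (99.6 - 99.8)  p=0.30      99.6 (99.6 - 99.7)  p=0.30    
act_s         214 (193 - 237)       171 (154 - 189)  p=0.02*        122 (110 - 135)  p=0.02*      
drms_oxy_pct                        6.31 (2.23 - 8.43)  p=0.02*     2.62 (0.101 - 3.76)  p=0.02*  

Data as median (min - max); * p <= 0.05 (exact Wilcoxon signed-rank vs 'baseline').

Detection lead (pressure crossing minus vibration crossing):
 subject t_rms_cross t_dp_cross lead_s crossed_rms crossed_dp
  subj01         810       1710    900        TRUE       TRUE
  subj02         750       1710    960        TRUE       TRUE
  subj03         720       1710    990        TRUE       TRUE
  subj04         750       1710    960        TRUE       TRUE
  subj05         780       1710    930        TRUE       TRUE
  subj06         750       1710    960        TRUE       TRUE
  subj07         750       1710    960        TRUE       TRUE
```

Reading it: the vibration metric rises with pump speed (median RMS_oxy
0.343 → 0.393 → 0.571 g; median ΔRMS_oxy +20.8% and +94.9%, both at the
minimal exact p = 0.02), flow and ΔP_oxy follow the protocol operating
points, and ACT — unchanged in every subject — gives the degenerate
p = 1.00. The reversal block shows the headline effect: a significant
RMS_oxy increase 15 min after the reversal event (median ΔRMS_oxy +6.31%,
p = 0.02) while ΔP_oxy has not yet risen above its baseline, and the
detection table shows vibration crossing its threshold roughly 900–990 s
before pressure in every subject — the configured pressure lag. Re-running
with the same seed reproduces every output byte for byte.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/oxyvib.R run --simulate --subjects 7 --seed 11 --out out/
```

## Package layout

- `R/` — recordings & timelines I/O, DSP chain, exact statistics, simulator,
  pipeline
- `tests/testthat/` — unit, property and end-to-end suites with independent
  oracles (O(n²) DFT matrix, explicit 2ⁿ enumeration, scalar-loop RMS)
- `vignettes/oxygenator-vibration.Rmd` — model, calibration math, design
  decisions and limitations
- `inst/cli/oxyvib.R` — command-line wrapper (`simulate`, `process`, `run`)
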