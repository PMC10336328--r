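# clotsim

In-silico modelling of histotripsy-enhanced catheter-directed thrombolysis
in venous thrombus.

Catheter-directed infusion of rt-PA (recombinant tissue plasminogen
activator) is the frontline therapy for critical venous thrombosis, but the
drug is confined to the immediate vicinity of the catheter by the dense
porous thrombus and by rapid quenching through PAI-1.  Histotripsy — focused
ultrasound that mechanically ablates tissue via cavitation bubble clouds —
lyses red blood cells and liquefies the treated region, raising its
diffusivity.  `clotsim` is for researchers in therapeutic ultrasound and
thrombosis modelling who want to quantify how that liquefaction reshapes
intra-thrombus drug delivery and fibrinolysis, and how the answer depends on
thrombus composition (fibrin-dominant, RBC-dominant, or mixed).

The package implements the full serial pipeline on synthetic histology
sections:

1. **Synthetic histology** — labelled fibrin/red-cell/background pixel grids
   with controllable fibrin fraction and patch clustering scale
   (`generate_section()`, portable label-mask I/O).
2. **Acoustic field** — elliptical-Gaussian focal model of a 1.5-MHz source
   with −6 dB widths 4.3 × 0.7 mm (`pressure_field()`).
3. **Monte Carlo ablation** — per-pixel intrinsic-threshold nucleation,
   `P(nucleate) = Φ((p⁻ − 26.8)/1.2)`, analytic Kelvin–Voigt maximum bubble
   radius

   ```
   R_max = R0 + sqrt(2 P0 ξ / 9ρ) · τ · (ξ P0 / 3 p_EFF + 1)^(1/3),
   p_EFF = P0 (1 + 4G/3P0),   ξ = (p⁻ − P0)/P0 − 6G/P0
   ```

   with the elastic modulus `G` averaged over a 500-µm neighbourhood
   (fibrin 14 MPa, red cells 4 kPa, liquefied 0), red-cell pixels inside
   bubble footprints relabelled as ablated, and hemoglobin tallied at
   0.03 ng per ablated 7.4-µm pixel (`run_treatment()`).
4. **Drug transport** — explicit FDTD solution of the perfusion–diffusion
   equation on an annular polar grid around the 0.84-mm catheter,

   ```
   ∂C/∂t = D_r ∂²C/∂r² + (D_θ/r²) ∂²C/∂θ² − v(r) ∂C/∂r − k₂ C_p C
   ```

   with porous-media dispersion in intact thrombus, 10× diffusivity in
   liquefied regions, outward advection `v(r) = U·r_min/r` (U = 0.87 cm/s at
   the catheter surface) and PAI-1 quenching (`solve_transport()`).
5. **Fibrinolysis** — closed-form FDP kinetics
   `C_FDP = C_FIB (1 − exp(−k₁k₄ C C_Pm t / (k₃ C_AP)))` over a 20-min
   exposure, plus the relative-FDP metric (`fdp_map()`, `relative_fdp()`).
6. **Statistics** — ANOVA/Tukey HSD, Pearson correlation, and the z-score
   linear regression coefficient coupling hemolysis to fibrinolysis
   (`dose_response_stats()`).

The methods vignette (`vignettes/clotsim-methods.Rmd`) documents the model
assumptions, the numerical scheme, every tunable parameter, and the design
decisions taken where the published description was open.

## Worked example

```r
library(clotsim)

## an RBC-dominant synthetic section (85% red cells) on a 10-mm field
s <- generate_section(target_fibrin_fraction = 0.15, extent = 10,
                      pixel_size = 29.6, seed = 42)
s
#> <histology_section> 338 x 338 pixels @ 29.6 um (10.00 x 10.00 mm)
#>   thrombus area 70.11 mm^2, fibrin fraction 0.150 (RBC_DOMINANT)

## 1000 histotripsy pulses at 36 MPa peak negative pressure, 10 repeats
f <- pressure_field(source_spec(peak_negative_pressure = 36), s)
tr <- run_treatment(s, f, n_pulses = 1000, n_repeats = 10, seed = 1)
tr
#> <treatment_result> 1000 pulses x 10 repeats @ 36 MPa
#>   final ablation area 2.19 +/- 0.012 mm^2
#>   hemoglobin: histotripsy 1.2e+03 ng, catheter 1.21e+03 ng

## steady rt-PA field through the ablated thrombus, then fibrinolysis
g <- polar_grid(r_min = 0.084, r_max = 0.55, dr = 0.002)
base  <- solve_transport(grid = g, section = s)
lysed <- solve_transport(grid = g, section = s, ablated_mask = tr$masks[[1]])
lysed
#> <concentration_field> 232 x 50 nodes, t = 0.447 s (steady at 0.447 s)
#>   C in [0, 668] nM; penetration 1.18 mm

relative_fdp(fdp_map(lysed, s)$total, fdp_map(base, s)$total)
#> [1] 1.000062
```

Reading the numbers: a 36-MPa exposure carves a ~2.2 mm² lesion through the
focal zone (close to the hemolysis caused by inserting the catheter itself);
quenched infusion reaches steady state in under a second of simulated time
and penetrates ~1.2 mm into intact thrombus; and liquefaction produces a
strictly positive — though, under this parameterisation, small — increase in
total fibrin degradation, which grows monotonically with pressure.  Sweeping
28–40 MPa couples hemolysis and fibrinolysis with a z-score regression
coefficient near one for RBC-dominant thrombus:

```r
cfg <- experiment_config(
  sections = list(list(target_fibrin_fraction = 0.15, extent = 10,
                       pixel_size = 29.6)),
  pressures = seq(28, 40, 2), n_pulses = 1000, n_repeats = 10, seed = 3)
dose_response_stats(run_experiment(cfg))$lrc
#>         1
#> 0.9708269
```

A thin command-line wrapper for cohort generation and full sweeps is
installed at `inst/scripts/clotsim.R`.

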