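# bmissde

Size-specific dose estimates for abdominal CT from body mass index.

## The problem

The dose figures a CT scanner reports — CTDI<sub>vol</sub> and DLP — are
normalised to a standard acrylic phantom and say how much radiation the
scanner emitted, not how much an individual patient absorbed. The
size-specific dose estimate (SSDE) corrects for patient size:

> SSDE = f(D_E) × CTDI_vol

where the conversion factor *f* depends on the patient's **effective
diameter** D_E = √(D_AP × D_LAT), the diameter of the circle with the same
cross-sectional area as the patient at the mid-scan level. Measuring D_AP
and D_LAT with electronic callipers on the localiser images is awkward,
slow and operator-dependent. For adult abdominal CT, effective diameter is
strongly predictable from BMI alone:

> D_E [cm] = 0.76 × BMI [kg/m²] + 9.4  (r = 0.88, fitted for BMI 17.4–38.8)

and the conversion factor for the 32-cm body phantom decays exponentially
with diameter, f(D_E) = a·e^(−b·D_E). This package implements that chain —
BMI (or height + weight, or measured diameters) → effective diameter →
conversion factor → SSDE — with the exponential coefficients calibrated by
log-linear least squares to a packaged 36-row reference table (BMI 15–50),
giving a = 3.694, b = 0.0366 and a maximum calibration residual of 0.006.

It is intended for medical physicists and radiology researchers who want a
reproducible, scriptable SSDE estimator and a way to exercise the whole
validation analysis without access to patient data: a seeded synthetic
cohort generator emulates the anthropometric and dose correlation structure
of an adult abdominal CT population (BMI 24.6 ± 4.8 kg/m², diameter
correlations 0.78/0.96/0.92, exponential tube-current-modulation dose
proxy), and a statistics layer recomputes the study-style summary tables,
correlation matrices, regression refits and BMI-group contrasts.

## Worked example

```r
library(bmissde)

# one patient: abdominal CT, scanner reported CTDIvol = 6.26 mGy, BMI 24.6
d_e <- de_from_bmi(24.6)            # 28.096 cm
f   <- conversion_factor(d_e)       # 1.320
ssde_from_ctdi(6.26, f)             # 8.265 mGy
```

So a patient of average build received an estimated mean dose of about
8.3 mGy at the centre of the scan volume — roughly a third more than the
phantom-normalised 6.26 mGy the console displayed, because the patient is
smaller than the 32-cm reference phantom.

```r
print(default_conversion_model())
#> Exponential CTDIvol->SSDE conversion model (32-cm phantom)
#>   f(d_e) = 3.6944 * exp(-0.036626 * d_e)
#>   calibrated on 36 rows, max |residual| = 0.0058

# synthetic cohort + validation analysis
cohort <- generate_cohort(cohort_params(n = 5000, seed = 7))
build_validation_report(cohort)
#> Cohort validation report (n = 5000)
#>   mean +- SD:
#>     bmi              24.57 +- 4.83
#>     d_ap_cm          25.05 +- 4.64
#>     d_lat_cm         31.59 +- 4.13
#>     d_e_cm           28.08 +- 4.18
#>     d_ratio           1.23 +- 0.13
#>     ctdi_vol_mgy      6.82 +- 4.59
#>     dlp_mgycm       323.48 +- 218.95
#>     ssde_mgy          8.31 +- 4.01
#>   D_E ~ BMI refit: slope 0.762, intercept 9.35 (R^2 = 0.775)
#>   r(BMI, D_E) = 0.880
#>   CTDIvol, BMI<25 vs >=25: 4.26 vs 9.96 mGy (Welch p = 0)
```

The refit recovers the generating regression and the BMI–diameter
correlation the generator was calibrated to; the BMI-group dose contrast
emerges from the exponential dose-versus-diameter proxy rather than being
imposed per group.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "bmissde.R", package = "bmissde"))')
Rscript "$CLI" convert --ctdi-vol 6.26 --bmi 24.6
Rscript "$CLI" table -o conversion_table.csv
Rscript "$CLI" simulate -n 5000 --seed 7 -o cohort.csv
Rscript "$CLI" validate cohort.csv -o report.json
Rscript "$CLI" calibrate --table conversion_table.csv
```

Exit code 0 on success, 2 on validation/schema/usage errors; diagnostics go
to stderr, data to stdout.

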