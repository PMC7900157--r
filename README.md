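# aortaflow

Quantification of peak-systolic aortic hemodynamics after surgical aortic
valve replacement (AVR), for people comparing 4D flow MRI measurements with
CFD predictions of the same patient. Both modalities ultimately deliver the
same object — a steady, voxelized, three-component velocity field with a
lumen mask — and `aortaflow` computes the standard clinical and research
parameters from it:

- **v_max**, the maximum velocity magnitude in the transvalvular jet, and
  the simplified-Bernoulli maximum pressure gradient
  **Δp_max = 4·v_max²** (Δp in mmHg, v in m/s);
- **SFD** (secondary flow degree): mean in-plane velocity divided by mean
  through-plane velocity on a vessel cross section;
- **NFD** (normalized flow displacement): distance between the lumen
  centroid and the forward-flow-weighted "center of flow", normalized by
  the hydraulic diameter D_h = 4A/P — both evaluated on three standard
  planes (sinotubular junction, mid-ascending aorta, directly proximal to
  the brachiocephalic artery);
- **EOA / IEOA / PPM**: Gorlin-type effective orifice area
  EOA = Q/(51.6·√Δp) (Q in ml/s), indexed by body surface area, with
  patient-prosthesis-mismatch classification (none > 0.85, moderate
  0.65–0.85, severe < 0.65 cm²/m²);
- **Re** at the narrowest prosthesis cross section,
  Re = 4ρQ/(π·μ_∞·D), with the orifice diameter obtained by scaling the
  nominal prosthesis size (19–29 mm) by a calibrated internal ratio;
- **Murray's-law outflow splits** for the supra-aortic branches (flow ∝ d³
  for the carotid/subclavian pair, with the brachiocephalic artery carrying
  as much as the other two together);
- **Carreau–Yasuda** shear-thinning blood viscosity;
- **streamline tracing** (arc-length RK4 with trilinear interpolation) for
  qualitative flow comparison;
- a **comparison layer** for paired cohorts: OLS regression with the
  unadjusted R² and residual RMSE, median/IQR summaries, and
  prosthesis-size agreement between virtual planning and actual surgery.

Since patient data cannot be shipped, the package includes a synthetic-data
module that is itself first-class, tested code: an idealized aorta
(straight ascending segment, circular arch, straight descending segment)
carrying an analytic valve jet with controllable peak velocity,
eccentricity, bluntness and swirl, for which v_max, SFD and NFD have closed
forms. Fields can be degraded to 4D-flow-MRI-like data (box-average
resampling to 2.80 × 2.25 × 2.25 mm voxels plus seeded Gaussian velocity
noise), so every estimator can be validated against known ground truth
under both CFD-like and MRI-like conditions.

## Worked example

```r
library(aortaflow)

geo <- build_idealized_aorta()                     # adult-scale aorta
gen <- generate_velocity_field(geo,
  jet_spec(v_peak = 2.4, offset_fraction = 0.25, swirl_ratio = 0.3),
  grid_spacing = 1e-3, seed = 7)                   # CFD-like fine field
mri <- degrade_to_mri(gen$field,
  noise_spec(noise_sd = 0.05 * 2.4, seed = 7))     # MRI-like counterpart

patient <- patient_record("IV", q_peak_ml_s = 539, bsa_m2 = 2.19,
                          size_vi_mm = 25, size_as_mm = 23)
analyze_case(mri, geo, patient = patient, prosthesis = prosthesis_model(23))
#> Hemodynamic report (IV)
#>   v_max = 2.76 m/s, dp_max = 30.5 mmHg
#>   SFD: stj=0.336, mid_aa=0.333, pre_bca=0.343
#>   NFD: stj=0.116, mid_aa=0.117, pre_bca=0.120
#>   EOA = 1.89 cm^2, IEOA = 0.86 cm^2/m^2 (none PPM), Re = 10654

gen$truth
#> Jet ground truth (seed 7): v_max = 2.401 m/s
#>   SFD: stj=0.300, mid_aa=0.300, pre_bca=0.300
#>   NFD: stj=0.125, mid_aa=0.125, pre_bca=0.125
```

Reading the output: the MRI-grade field recovers NFD and SFD close to the
analytic truth, while the strict voxel maximum (2.76 vs 2.40 m/s) is
inflated by additive noise — exactly the behavior that makes v_max the
parameter to treat carefully in noisy acquisitions (`max_velocity()` takes
an optional percentile guard). Δp_max is always 4·v_max² by construction,
and the Reynolds number 10654 matches the packaged cohort value for a
size-23 prosthesis at 539 ml/s.

The packaged ten-patient cohort table is available for the tabular
statistics:

```r
t2 <- read_patient_table(aortaflow_example("table2.csv"))
size_agreement(t2)
#> $mae_mm      [1] 1.8
#> $n_identical [1] 3
```

A thin command-line pipeline (`generate`, `analyze`, `compare`, `trace`)
over the same functions lives at `inst/cli/aortaflow.R`; fields travel as
ASCII VTK image data (`.vti`), streamlines as VTK polydata (`.vtp`),
reports and configs as JSON/CSV, and every run writes a manifest with the
effective configuration, its MD5, and all seeds.

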