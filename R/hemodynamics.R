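# Hemodynamic parameters: jet maximum velocity, simplified-Bernoulli maximum
# pressure gradient, secondary flow degree (SFD), normalized flow
# displacement (NFD), effective orifice area and its body-surface-area index
# with patient-prosthesis-mismatch class, prosthesis-orifice Reynolds number,
# Murray's-law outflow split, and Carreau-Yasuda blood viscosity.

#' Blood rheology parameters
#'
#' Carreau-Yasuda shear-thinning parameters and density for blood:
#' zero-shear viscosity `mu0`, infinite-shear viscosity `mu_inf`, power
#' constant `n`, transition parameter `a`, relaxation time `lam` (s), and
#' density `rho` (kg/m^3). Defaults are the values commonly used for blood
#' in aortic CFD.
#'
#' @param mu0 Zero-shear viscosity (Pa s).
#' @param mu_inf Infinite-shear viscosity (Pa s).
#' @param n Power-law constant (dimensionless, in (0, 1)).
#' @param a Yasuda transition parameter (dimensionless, > 0).
#' @param lam Relaxation time (s).
#' @param rho Density (kg/m^3).
#' @return A list of class `"rheology_params"`.
#' @export
rheology_params <- function(mu0 = 0.16, mu_inf = 0.0035, n = 0.2128,
                            a = 0.64, lam = 8.2, rho = 1050) {
  if (!(mu_inf > 0 && mu0 > mu_inf))
    stop_af("need 0 < mu_inf < mu0", class = "aortaflow_validation")
  check_number(lam, "lam", positive = TRUE)
  check_number(a, "a", positive = TRUE)
  if (!(n > 0 && n < 1))
    stop_af("n must be in (0, 1)", class = "aortaflow_validation")
  check_number(rho, "rho", positive = TRUE)
  structure(list(mu0 = mu0, mu_inf = mu_inf, n = n, a = a, lam = lam,
                 rho = rho),
            class = "rheology_params")
}

#' Carreau-Yasuda viscosity
#'
#' Shear-thinning apparent viscosity
#' `mu(g) = mu_inf + (mu0 - mu_inf) * (1 + (lam g)^a)^((n - 1)/a)`,
#' monotone non-increasing in the shear rate `g`, with `mu(0) = mu0` and
#' `mu -> mu_inf` as `g -> Inf`.
#'
#' @param shear_rate Shear rate(s), 1/s, `>= 0` (vectorized).
#' @param params A [rheology_params()].
#' @return Viscosity in Pa s.
#' @export
#' @examples
#' carreau_yasuda_viscosity(c(0, 100, 1e6))
carreau_yasuda_viscosity <- function(shear_rate,
                                     params = rheology_params()) {
  if (!is.numeric(shear_rate) || any(is.na(shear_rate)) ||
      any(shear_rate < 0))
    stop_af("shear_rate must be >= 0", class = "aortaflow_validation")
  params$mu_inf + (params$mu0 - params$mu_inf) *
    (1 + (params$lam * shear_rate)^params$a)^((params$n - 1) / params$a)
}

#' Reynolds number at the prosthesis orifice
#'
#' `Re = rho vbar D / mu_inf` with the mean orifice velocity
#' `vbar = q / (pi D^2 / 4)`, i.e. `Re = 4 rho q / (pi mu_inf D)`, evaluated
#' with the infinite-shear viscosity at the narrowest cross section of the
#' prosthesis.
#'
#' @param q Volumetric flow rate (m^3/s).
#' @param diameter Orifice diameter (m).
#' @param params A [rheology_params()].
#' @return Dimensionless Reynolds number.
#' @export
#' @examples
#' d23 <- prosthesis_internal_diameter(23)
#' reynolds_number(539e-6, d23)  # ~10,653
reynolds_number <- function(q, diameter, params = rheology_params()) {
  check_number(q, "q", positive = TRUE)
  check_number(diameter, "diameter", positive = TRUE)
  4 * params$rho * q / (pi * params$mu_inf * diameter)
}

#' Maximum velocity in the valve jet
#'
#' Maximum Euclidean velocity magnitude over lumen voxels, optionally
#' restricted to an arclength window along the vessel (the default analysis
#' region is valve plane to mid-ascending aorta, where the transvalvular jet
#' lives).
#'
#' @param field A [velocity_field()].
#' @param region Either `NULL` (whole lumen), a numeric interval
#'   `c(s_min, s_max)` of centerline arclengths (requires `geometry`), or a
#'   logical array matching the field dims.
#' @param geometry An `aorta_geometry`, needed when `region` is an arclength
#'   interval.
#' @param quantile_guard Optional probability in (0, 1]: report this speed
#'   quantile over the region instead of the strict maximum. A guard such
#'   as 0.999 damps the noise inflation of the maximum on noisy
#'   acquisitions; the default (`NULL`) is the strict maximum, matching
#'   clinical reporting.
#' @return Maximum speed (m/s).
#' @export
max_velocity <- function(field, region = NULL, geometry = NULL,
                         quantile_guard = NULL) {
  speed <- field_speed(field)
  sel <- field$mask
  if (is.array(region)) {
    sel <- sel & region
  } else if (is.numeric(region) && length(region) == 2L) {
    if (is.null(geometry))
      stop_af("an arclength region requires `geometry`",
              class = "aortaflow_validation")
    s_map <- field_arclengths(field, geometry)
    sel <- sel & !is.na(s_map) & s_map >= region[1] & s_map <= region[2]
  } else if (!is.null(region)) {
    stop_af("region must be NULL, c(s_min, s_max), or a logical array",
            class = "aortaflow_validation")
  }
  if (!any(sel))
    stop_af("region contains no lumen voxels", class = "aortaflow_empty_region")
  if (is.null(quantile_guard)) return(max(speed[sel]))
  if (!is.numeric(quantile_guard) || quantile_guard <= 0 ||
      quantile_guard > 1)
    stop_af("quantile_guard must be in (0, 1]",
            class = "aortaflow_validation")
  unname(quantile(speed[sel], quantile_guard, type = 7))
}

#' Simplified-Bernoulli maximum pressure gradient
#'
#' The clinical estimate `dp_max = 4 v_max^2`, with `v_max` in m/s and the
#' result in mmHg. This is the conventional transvalvular gradient used in
#' guidelines, not the physically recovered pressure drop.
#'
#' @param v_max Maximum jet velocity (m/s), `>= 0`.
#' @return Pressure gradient (mmHg).
#' @export
#' @examples
#' bernoulli_dp(2.1)  # 17.64 mmHg, rounds to 18
bernoulli_dp <- function(v_max) {
  if (!is.numeric(v_max) || any(is.na(v_max)) || any(v_max < 0))
    stop_af("v_max must be >= 0", class = "aortaflow_validation")
  4 * v_max^2
}

# Sample the velocity of `field` on a cross section; returns through-plane
# (signed, along the section normal) and in-plane speed per lumen sample.
section_velocities <- function(field, section) {
  v <- interp_velocity(field, section$points)
  vth <- as.vector(v %*% section$normal)
  vin_vec <- v - outer(vth, section$normal)
  list(through = vth, inplane = row_norms(vin_vec))
}

#' Secondary flow degree on a cross section
#'
#' SFD = (area-weighted mean in-plane speed) / (area-weighted mean absolute
#' through-plane velocity). Both means are taken point-wise over the lumen
#' samples of the section (mean of magnitudes, so that symmetric swirl does
#' not cancel).
#'
#' @param field A [velocity_field()].
#' @param section A `cross_section` from [lumen_cross_section()] or
#'   [place_standard_sections()].
#' @return Dimensionless SFD `>= 0`.
#' @export
secondary_flow_degree <- function(field, section) {
  sv <- section_velocities(field, section)
  w <- section$weights
  den <- sum(w * abs(sv$through)) / sum(w)
  if (den <= 0 || !is.finite(den))
    stop_af("mean through-plane velocity is zero; SFD undefined",
            class = "aortaflow_undefined")
  (sum(w * sv$inplane) / sum(w)) / den
}

#' Normalized flow displacement on a cross section
#'
#' The flow displacement is the in-plane distance between the vessel center
#' (unweighted area centroid of the lumen samples) and the center of flow
#' (centroid weighted by forward through-plane velocity; retrograde samples
#' are excluded from the weighting). NFD is this distance normalized by the
#' hydraulic diameter `D_h = 4A/P` of the section.
#'
#' @inheritParams secondary_flow_degree
#' @param weighting `"forward"` (default) weights by positive through-plane
#'   velocity only; `"signed"` uses the signed through-plane velocity.
#' @return Dimensionless NFD in `[0, 1)`.
#' @export
normalized_flow_displacement <- function(field, section,
                                         weighting = c("forward", "signed")) {
  weighting <- match.arg(weighting)
  sv <- section_velocities(field, section)
  w_geom <- section$weights
  wf <- if (weighting == "forward") pmax(sv$through, 0) else sv$through
  tot <- sum(w_geom * wf)
  if (tot <= 0)
    stop_af("no net forward through-plane flow; NFD undefined",
            class = "aortaflow_undefined")
  cof <- colSums(section$uv * (w_geom * wf)) / tot
  center <- colSums(section$uv * w_geom) / sum(w_geom)
  sqrt(sum((cof - center)^2)) / section$hydraulic_diameter
}

#' Effective orifice area from flow rate and pressure gradient
#'
#' Gorlin-type continuity estimate `EOA = q / (51.6 sqrt(dp))` with `q` in
#' ml/s, `dp` in mmHg and EOA in cm^2. The constant is exposed so an
#' alternative form can be substituted.
#'
#' @param q_peak_ml_s Peak systolic flow rate (ml/s).
#' @param dp_max_mmhg Maximum pressure gradient (mmHg), `> 0`.
#' @param constant Gorlin constant (default 51.6).
#' @return EOA in cm^2.
#' @export
#' @examples
#' effective_orifice_area(300, 16)  # 1.4535 cm^2
effective_orifice_area <- function(q_peak_ml_s, dp_max_mmhg,
                                   constant = 51.6) {
  check_number(q_peak_ml_s, "q_peak_ml_s", positive = TRUE)
  if (!is.numeric(dp_max_mmhg) || length(dp_max_mmhg) != 1L ||
      is.na(dp_max_mmhg) || dp_max_mmhg <= 0)
    stop_af("dp_max_mmhg must be > 0; EOA undefined at zero gradient",
            class = "aortaflow_undefined")
  q_peak_ml_s / (constant * sqrt(dp_max_mmhg))
}

#' Indexed effective orifice area
#'
#' EOA normalized by body surface area: `IEOA = EOA / BSA` (cm^2/m^2).
#'
#' @param eoa_cm2 Effective orifice area (cm^2).
#' @param bsa_m2 Body surface area (m^2), `> 0`.
#' @return IEOA in cm^2/m^2.
#' @export
indexed_eoa <- function(eoa_cm2, bsa_m2) {
  check_number(eoa_cm2, "eoa_cm2", positive = TRUE)
  check_number(bsa_m2, "bsa_m2", positive = TRUE)
  eoa_cm2 / bsa_m2
}

#' Classify patient-prosthesis mismatch from IEOA
#'
#' Standard echocardiographic thresholds: IEOA above 0.85 cm^2/m^2 is no
#' PPM, below 0.65 cm^2/m^2 is severe PPM, and the closed interval
#' `[0.65, 0.85]` is moderate PPM.
#'
#' @param ieoa IEOA (cm^2/m^2), `> 0` (vectorized).
#' @return Factor with levels `none`, `moderate`, `severe`.
#' @export
#' @examples
#' classify_ppm(c(0.9, 0.7, 0.6))
classify_ppm <- function(ieoa) {
  if (!is.numeric(ieoa) || any(is.na(ieoa)) || any(ieoa <= 0))
    stop_af("ieoa must be > 0", class = "aortaflow_validation")
  cls <- ifelse(ieoa > 0.85, "none", ifelse(ieoa < 0.65, "severe",
                                            "moderate"))
  factor(cls, levels = c("none", "moderate", "severe"))
}

#' Murray's-law outflow split for the aortic arch branches
#'
#' Distributes the arch flow `q_in - q_desc` among the supra-aortic branches
#' under two constraints: the brachiocephalic artery (BCA) receives the same
#' flow as the left common carotid (LCC) and left subclavian (LSA) together
#' (so BCA gets half the arch flow), and the LCC/LSA split follows Murray's
#' law, proportional to diameter cubed.
#'
#' @param q_in Inlet flow rate (m^3/s).
#' @param q_desc Descending-aorta outlet flow rate (m^3/s), `< q_in`.
#' @param d_lcc,d_lsa Diameters of LCC and LSA (m).
#' @return A list of class `"outflow_split"` with `q_in`, `q_desc`, `q_bca`,
#'   `q_lcc`, `q_lsa` (m^3/s). Conserves mass exactly:
#'   `q_in = q_desc + q_bca + q_lcc + q_lsa` and `q_bca = q_lcc + q_lsa`.
#' @export
#' @examples
#' murray_outflow_split(400e-6, 300e-6, d_lcc = 0.008, d_lsa = 0.0095)
murray_outflow_split <- function(q_in, q_desc, d_lcc, d_lsa) {
  check_number(q_in, "q_in", positive = TRUE)
  check_number(q_desc, "q_desc", positive = TRUE)
  check_number(d_lcc, "d_lcc", positive = TRUE)
  check_number(d_lsa, "d_lsa", positive = TRUE)
  if (q_desc >= q_in)
    stop_af("q_desc must be smaller than q_in",
            class = "aortaflow_validation")
  q_arch <- q_in - q_desc
  q_bca <- q_arch / 2
  wl <- d_lcc^3 / (d_lcc^3 + d_lsa^3)
  q_lcc <- q_bca * wl
  q_lsa <- q_bca - q_lcc
  structure(list(q_in = q_in, q_desc = q_desc, q_bca = q_bca,
                 q_lcc = q_lcc, q_lsa = q_lsa),
            class = "outflow_split")
}

#' Patient record
#'
#' Per-patient inputs for the analysis pipeline: peak systolic inlet flow
#' rate (ml/s), body surface area (m^2), and the nominal prosthesis sizes
#' chosen during virtual intervention and actual surgery (mm).
#'
#' @param patient_id Identifier.
#' @param q_peak_ml_s Peak systolic inlet flow rate (ml/s).
#' @param bsa_m2 Body surface area (m^2); may be `NA` if IEOA is not needed.
#' @param size_vi_mm,size_as_mm Nominal prosthesis sizes (mm).
#' @return A list of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, q_peak_ml_s, bsa_m2 = NA_real_,
                           size_vi_mm = NA_real_, size_as_mm = NA_real_) {
  check_number(q_peak_ml_s, "q_peak_ml_s", positive = TRUE)
  for (sz in c(size_vi_mm, size_as_mm))
    if (!is.na(sz) && !sz %in% PROSTHESIS_SIZES_MM)
      stop_af("prosthesis sizes must be in {",
              paste(PROSTHESIS_SIZES_MM, collapse = ", "), "}",
              class = "aortaflow_validation")
  structure(list(patient_id = patient_id, q_peak_ml_s = q_peak_ml_s,
                 bsa_m2 = bsa_m2, size_vi_mm = size_vi_mm,
                 size_as_mm = size_as_mm),
            class = "patient_record")
}

#' Full hemodynamic analysis of one case
#'
#' Runs the whole parameter pipeline on a velocity field: places the three
#' standard cross sections, finds the jet maximum velocity (by default in
#' the region between the valve plane and the mid-ascending section),
#' converts it to the simplified-Bernoulli gradient, evaluates SFD and NFD
#' on each section, estimates EOA from the gradient and the patient's flow
#' rate, indexes it by body surface area, classifies patient-prosthesis
#' mismatch, and computes the prosthesis-orifice Reynolds number.
#'
#' @param field A [velocity_field()].
#' @param geometry The `aorta_geometry` the field covers.
#' @param patient A [patient_record()] (or `NULL` to skip EOA/IEOA/Re).
#' @param prosthesis A [prosthesis_model()] (or `NULL` to skip Re).
#' @param params A [rheology_params()].
#' @param section_resolution In-plane sampling step for the sections (m).
#' @param v_max_region Arclength interval for the jet search; default valve
#'   plane to mid-ascending section.
#' @return An object of class `"hemodynamic_report"`: `v_max` (m/s),
#'   `dp_max` (mmHg), `sfd` and `nfd` (named per-section vectors), `eoa`
#'   (cm^2), `ieoa` (cm^2/m^2), `ppm_class`, `reynolds`, `patient_id`.
#' @export
analyze_case <- function(field, geometry, patient = NULL, prosthesis = NULL,
                         params = rheology_params(),
                         section_resolution = 5e-4, v_max_region = NULL) {
  sections <- place_standard_sections(geometry,
                                      resolution = section_resolution)
  lm <- geometry$landmarks
  if (is.null(v_max_region))
    v_max_region <- c(lm$s_valve, (lm$s_stj + lm$s_bca) / 2)
  v_max <- max_velocity(field, region = v_max_region, geometry = geometry)
  dp_max <- bernoulli_dp(v_max)
  sfd <- vapply(sections, function(cs) secondary_flow_degree(field, cs),
                numeric(1))
  nfd <- vapply(sections, function(cs)
    normalized_flow_displacement(field, cs), numeric(1))
  eoa <- ieoa <- reynolds <- NA_real_
  ppm <- NA
  if (!is.null(patient)) {
    eoa <- effective_orifice_area(patient$q_peak_ml_s, dp_max)
    if (is.finite(patient$bsa_m2)) {
      ieoa <- indexed_eoa(eoa, patient$bsa_m2)
      ppm <- as.character(classify_ppm(ieoa))
    }
    if (!is.null(prosthesis))
      reynolds <- reynolds_number(patient$q_peak_ml_s * 1e-6,
                                  prosthesis$internal_diameter, params)
  }
  structure(list(patient_id = if (is.null(patient)) NA else
                   patient$patient_id,
                 v_max = v_max, dp_max = dp_max, sfd = sfd, nfd = nfd,
                 eoa = eoa, ieoa = ieoa, ppm_class = ppm,
                 reynolds = reynolds,
                 section_s = vapply(sections, attr, numeric(1), "s")),
            class = "hemodynamic_report")
}

#' @export
print.hemodynamic_report <- function(x, ...) {
  cat("Hemodynamic report", if (!is.na(x$patient_id))
    paste0("(", x$patient_id, ")"), "\n")
  cat(sprintf("  v_max = %.2f m/s, dp_max = %.1f mmHg\n", x$v_max, x$dp_max))
  cat("  SFD:", paste(sprintf("%s=%.3f", names(x$sfd), x$sfd),
                      collapse = ", "), "\n")
  cat("  NFD:", paste(sprintf("%s=%.3f", names(x$nfd), x$nfd),
                      collapse = ", "), "\n")
  if (is.finite(x$eoa))
    cat(sprintf("  EOA = %.2f cm^2, IEOA = %.2f cm^2/m^2 (%s PPM), Re = %.0f\n",
                x$eoa, x$ieoa,
                if (is.na(x$ppm_class)) "?" else x$ppm_class,
                x$reynolds))
  invisible(x)
}
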