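# Prosthesis orifice model: the manufacturer offers nominal sizes 19-29 mm in
# 2 mm steps; the narrowest (leaflet-bounded) cross section is modeled as a
# circle whose diameter is a fixed fraction of the nominal size. The fraction
# is calibrated once by inverting the orifice Reynolds number
# Re = 4 rho Q / (pi mu_inf D) on a reference patient with a size-23
# prosthesis (Q = 354 ml/s, Re = 6,997), giving D = 19.325 mm and
# ratio = 0.84022; the same ratio reproduces the Reynolds numbers of the
# whole packaged cohort (all four sizes) to within rounding.

PROSTHESIS_SIZES_MM <- seq(19, 29, by = 2)

#' Internal orifice ratio of the prosthesis model
#'
#' Dimensionless ratio between the internal (narrowest) orifice diameter and
#' the nominal prosthesis size, calibrated by inverting
#' `Re = 4 rho Q / (pi mu_inf D)` on a reference size-23 case.
#' `default_internal_ratio()` returns the packaged calibration (0.84022);
#' `calibrate_internal_ratio()` re-derives it from a flow rate / Reynolds
#' number pair.
#'
#' @param q_ml_s Peak systolic flow rate through the prosthesis (ml/s).
#' @param reynolds Reynolds number at the narrowest prosthesis cross section.
#' @param nominal_size_mm Nominal prosthesis size (mm).
#' @param params Rheology parameters; see [rheology_params()]. Density and
#'   infinite-shear viscosity are used.
#' @return The dimensionless internal ratio.
#' @export
#' @examples
#' calibrate_internal_ratio(354, 6997, 23)
calibrate_internal_ratio <- function(q_ml_s, reynolds, nominal_size_mm,
                                     params = rheology_params()) {
  check_number(q_ml_s, "q_ml_s", positive = TRUE)
  check_number(reynolds, "reynolds", positive = TRUE)
  if (!nominal_size_mm %in% PROSTHESIS_SIZES_MM)
    stop_af("nominal_size_mm must be one of ",
            paste(PROSTHESIS_SIZES_MM, collapse = ", "),
            class = "aortaflow_validation")
  d <- 4 * params$rho * (q_ml_s * 1e-6) / (pi * params$mu_inf * reynolds)
  d / (nominal_size_mm * 1e-3)
}

#' @rdname calibrate_internal_ratio
#' @export
default_internal_ratio <- function() {
  # frozen value of calibrate_internal_ratio(354, 6997, 23)
  0.8402236961857833
}

#' Prosthesis model and internal orifice diameter
#'
#' `prosthesis_model()` bundles a nominal size with an internal ratio;
#' `prosthesis_internal_diameter()` returns the diameter of the narrowest
#' internal cross section in meters. The prosthesis geometry scales linearly
#' with nominal size, so one calibrated ratio serves all sizes.
#'
#' @param nominal_size_mm Nominal size in mm; one of 19, 21, 23, 25, 27, 29.
#' @param internal_ratio Internal orifice diameter / nominal size; default is
#'   the packaged calibration ([default_internal_ratio()]).
#' @return `prosthesis_model()`: a list of class `"prosthesis_model"` with
#'   `nominal_size_mm`, `internal_ratio` and `internal_diameter` (m).
#'   `prosthesis_internal_diameter()`: the internal diameter (m).
#' @export
#' @examples
#' 1e3 * prosthesis_internal_diameter(23)  # mm
#' prosthesis_model(21)
prosthesis_model <- function(nominal_size_mm,
                             internal_ratio = default_internal_ratio()) {
  d <- prosthesis_internal_diameter(nominal_size_mm, internal_ratio)
  structure(list(nominal_size_mm = nominal_size_mm,
                 internal_ratio = internal_ratio,
                 internal_diameter = d),
            class = "prosthesis_model")
}

#' @rdname prosthesis_model
#' @export
prosthesis_internal_diameter <- function(nominal_size_mm,
                                         internal_ratio =
                                           default_internal_ratio()) {
  if (length(nominal_size_mm) != 1L ||
      !nominal_size_mm %in% PROSTHESIS_SIZES_MM)
    stop_af("nominal_size_mm must be one of ",
            paste(PROSTHESIS_SIZES_MM, collapse = ", "),
            class = "aortaflow_validation")
  if (!is.numeric(internal_ratio) || internal_ratio <= 0 ||
      internal_ratio > 1)
    stop_af("internal_ratio must be in (0, 1]",
            class = "aortaflow_validation")
  internal_ratio * nominal_size_mm * 1e-3
}

#' @export
print.prosthesis_model <- function(x, ...) {
  cat(sprintf("Valve prosthesis: nominal %d mm, internal orifice %.3f mm\n",
              x$nominal_size_mm, 1e3 * x$internal_diameter))
  invisible(x)
}
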