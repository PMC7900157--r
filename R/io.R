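# File formats: VTK XML image data (.vti) for voxel fields, VTK XML polydata
# (.vtp) for streamlines, CSV for tables, JSON for ground truth and reports.
# The VTK writers/readers are minimal ASCII implementations of the XML
# formats (point arrays "velocity" and "mask" on the image grid). Doubles
# are printed with 17 significant digits so a write/read round trip is
# bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write and read voxel velocity fields as VTK image data
#'
#' `write_velocity_field()` stores a [velocity_field()] as an ASCII VTK XML
#' ImageData file (`.vti`) with a 3-component point array `velocity` (m/s)
#' and a scalar point array `mask`; `read_velocity_field()` reads it back.
#' The round trip preserves velocities bit-exactly and the grid metadata
#' exactly.
#'
#' @param field A [velocity_field()].
#' @param path Output/input file path (`.vti`).
#' @return `write_velocity_field()` returns `path` invisibly;
#'   `read_velocity_field()` returns a [velocity_field()].
#' @export
write_velocity_field <- function(field, path) {
  d <- field$dims
  vm <- matrix(field$velocity, ncol = 3L)
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('  <ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="%s" Spacing="%s">',
            d[1] - 1L, d[2] - 1L, d[3] - 1L,
            paste(fmt_num(field$origin), collapse = " "),
            paste(fmt_num(field$spacing), collapse = " ")),
    sprintf('    <Piece Extent="0 %d 0 %d 0 %d">',
            d[1] - 1L, d[2] - 1L, d[3] - 1L),
    '      <PointData Vectors="velocity">',
    paste0('        <DataArray type="Float64" Name="velocity" ',
           'NumberOfComponents="3" format="ascii">'),
    paste(apply(vm, 1, function(r) paste(fmt_num(r), collapse = " ")),
          collapse = "\n"),
    "        </DataArray>",
    '        <DataArray type="UInt8" Name="mask" format="ascii">',
    paste(as.integer(field$mask), collapse = " "),
    "        </DataArray>",
    "      </PointData>",
    "    </Piece>",
    "  </ImageData>",
    "</VTKFile>")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  doc <- xml2::read_xml(path)
  img <- xml2::xml_find_first(doc, ".//ImageData")
  if (inherits(img, "xml_missing"))
    stop_af("not a VTK ImageData file: ", path, class = "aortaflow_io")
  ext <- as.integer(strsplit(xml2::xml_attr(img, "WholeExtent"), " +")[[1]])
  dims <- c(ext[2] - ext[1], ext[4] - ext[3], ext[6] - ext[5]) + 1L
  origin <- as.numeric(strsplit(xml2::xml_attr(img, "Origin"), " +")[[1]])
  spacing <- as.numeric(strsplit(xml2::xml_attr(img, "Spacing"), " +")[[1]])
  arrays <- xml2::xml_find_all(doc, ".//PointData/DataArray")
  nms <- vapply(seq_along(arrays),
                function(i) xml2::xml_attr(arrays[[i]], "Name"), character(1))
  for (need in c("velocity", "mask"))
    if (!need %in% nms)
      stop_af("missing point array '", need, "' in ", path,
              class = "aortaflow_io")
  parse_arr <- function(node)
    as.numeric(strsplit(trimws(xml2::xml_text(node)), "[ \n\t]+")[[1]])
  vel <- matrix(parse_arr(arrays[[which(nms == "velocity")]]), ncol = 3L,
                byrow = TRUE)
  mask <- array(parse_arr(arrays[[which(nms == "mask")]]) != 0, dim = dims)
  velocity_field(origin, spacing, array(vel, dim = c(dims, 3L)), mask)
}

#' Write streamlines as VTK polydata
#'
#' Stores a `streamline_set` as an ASCII VTK XML PolyData file (`.vtp`) with
#' one polyline per streamline and a point array `speed` (m/s).
#'
#' @param streamlines A `streamline_set` from [trace_streamlines()].
#' @param path Output path (`.vtp`).
#' @return `path`, invisibly.
#' @export
write_streamlines_vtp <- function(streamlines, path) {
  pts <- do.call(rbind, lapply(streamlines, `[[`, "points"))
  speeds <- unlist(lapply(streamlines, `[[`, "speeds"))
  n_per <- vapply(streamlines, function(s) nrow(s$points), integer(1))
  offsets <- cumsum(n_per)
  connect <- seq_len(sum(n_per)) - 1L
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    "  <PolyData>",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfLines="%d">',
            nrow(pts), length(streamlines)),
    "      <Points>",
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste(apply(pts, 1, function(r) paste(fmt_num(r), collapse = " ")),
          collapse = "\n"),
    "        </DataArray>",
    "      </Points>",
    "      <PointData>",
    '        <DataArray type="Float64" Name="speed" format="ascii">',
    paste(fmt_num(speeds), collapse = " "),
    "        </DataArray>",
    "      </PointData>",
    "      <Lines>",
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste(connect, collapse = " "),
    "        </DataArray>",
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste(offsets, collapse = " "),
    "        </DataArray>",
    "      </Lines>",
    "    </Piece>",
    "  </PolyData>",
    "</VTKFile>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a patient table
#'
#' Reads the packaged cohort-table dialect: CSV with unit-suffixed columns
#' `patient`, `size_vi_mm`, `size_as_mm`, `q_peak_ml_s`, and optionally
#' `reynolds` and `bsa_m2`.
#'
#' @param path CSV path, e.g. `aortaflow_example("table2.csv")`.
#' @return A data frame.
#' @export
read_patient_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "q_peak_ml_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_af("patient table is missing columns: ",
            paste(miss, collapse = ", "), class = "aortaflow_io")
  df
}

#' Write and read jet ground truth as JSON
#'
#' @param truth A `jet_ground_truth` from [generate_velocity_field()].
#' @param path JSON path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the ground-truth list.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(true_v_max = truth$true_v_max,
                  true_sfd = as.list(truth$true_sfd),
                  true_nfd = as.list(truth$true_nfd),
                  section_s = as.list(truth$section_s),
                  seed = truth$seed,
                  jet = unclass(truth$jet))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite writes Inf as the string "Inf"; coerce numerics back
  x$jet <- lapply(x$jet, function(v) if (is.character(v)) as.numeric(v)
                  else v)
  structure(list(true_v_max = x$true_v_max,
                 true_sfd = unlist(x$true_sfd),
                 true_nfd = unlist(x$true_nfd),
                 section_s = unlist(x$section_s),
                 seed = as.integer(x$seed),
                 jet = do.call(jet_spec, x$jet)),
            class = "jet_ground_truth")
}

#' Convert hemodynamic reports to a one-row-per-case data frame
#'
#' @param reports A list of `hemodynamic_report` objects.
#' @return A data frame with unit-suffixed columns (`v_max_m_s`,
#'   `dp_max_mmhg`, per-section `sfd_*` and `nfd_*`, `eoa_cm2`,
#'   `ieoa_cm2_m2`, `ppm_class`, `reynolds`).
#' @export
reports_to_df <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    row <- data.frame(patient = r$patient_id, v_max_m_s = r$v_max,
                      dp_max_mmhg = r$dp_max)
    for (nm in names(r$sfd)) row[[paste0("sfd_", nm)]] <- r$sfd[[nm]]
    for (nm in names(r$nfd)) row[[paste0("nfd_", nm)]] <- r$nfd[[nm]]
    row$eoa_cm2 <- r$eoa
    row$ieoa_cm2_m2 <- r$ieoa
    row$ppm_class <- if (length(r$ppm_class) == 1 && is.na(r$ppm_class))
      NA_character_ else as.character(r$ppm_class)
    row$reynolds <- r$reynolds
    row
  }))
}

write_report_json <- function(report, path) {
  payload <- unclass(report)
  payload$sfd <- as.list(report$sfd)
  payload$nfd <- as.list(report$nfd)
  payload$section_s <- as.list(report$section_s)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
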