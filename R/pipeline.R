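# Pipeline plumbing: JSON configuration with strict validation, the
# generate / analyze / compare / trace stages as plain functions, and a
# machine-readable manifest for every run. The thin command-line wrapper in
# inst/cli/aortaflow.R dispatches onto these.

config_schema <- function() list(
  n_cases = "integer >= 0",
  seed = "integer",
  grid_spacing = "number (m)",
  geometry = names(formals(aorta_config)),
  jet = names(formals(jet_spec)),
  jet_variation = c("v_peak", "offset_fraction", "offset_angle_deg",
                    "swirl_ratio", "profile_exponent", "jet_radius_fraction"),
  noise = c("target_spacing", "noise_sd"),
  analysis = c("section_resolution", "eoa_constant", "nfd_weighting",
               "v_max_region"),
  rheology = names(formals(rheology_params)),
  patients_csv = "path"
)

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or JSON file) against the documented schema
#' (`inst/extdata/pipeline-config.schema.json`): unknown keys are rejected
#' with the offending path, numeric ranges are delegated to the stage
#' constructors. All defaults are filled in explicitly so a run's manifest
#' records every effective setting.
#'
#' @param config A named list or a path to a JSON file.
#' @return The validated, default-completed configuration list (class
#'   `"pipeline_config"`).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_af("config file not found: ", config, class = "aortaflow_io")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config))
    stop_af("config must be a named list or JSON object",
            class = "aortaflow_validation")
  schema <- config_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad))
    stop_af("unknown config key(s): ", paste(bad, collapse = ", "),
            class = "aortaflow_validation")
  for (sect in c("geometry", "jet", "noise", "analysis", "rheology",
                 "jet_variation")) {
    extra <- setdiff(names(config[[sect]]), schema[[sect]])
    if (length(extra))
      stop_af("unknown config key(s) under ", sect, ": ",
              paste(extra, collapse = ", "), class = "aortaflow_validation")
  }
  if (is.null(config$n_cases)) config$n_cases <- 1L
  if (!is.numeric(config$n_cases) || config$n_cases < 0)
    stop_af("n_cases must be a non-negative integer",
            class = "aortaflow_validation")
  if (is.null(config$seed)) config$seed <- 0L
  if (is.null(config$grid_spacing)) config$grid_spacing <- 1e-3
  config$geometry <- do.call(aorta_config, as.list(config$geometry))
  config$jet <- do.call(jet_spec, as.list(config$jet))
  noise_args <- as.list(config$noise)
  noise_args$seed <- config$seed
  config$noise <- do.call(noise_spec, noise_args)
  an <- config$analysis
  config$analysis <- list(
    section_resolution = an$section_resolution %||% 5e-4,
    eoa_constant = an$eoa_constant %||% 51.6,
    nfd_weighting = an$nfd_weighting %||% "forward",
    v_max_region = an$v_max_region)
  config$rheology <- do.call(rheology_params, as.list(config$rheology))
  structure(config, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample per-case jet parameters: fixed baseline from config$jet, fields in
# config$jet_variation drawn uniformly from [lo, hi] under the case seed.
sample_case_jet <- function(config, case_seed) {
  jet_args <- unclass(config$jet)
  vary <- config$jet_variation
  if (length(vary)) {
    draws <- with_seed(case_seed, lapply(vary, function(rng)
      runif(1, min = rng[[1]], max = rng[[2]])))
    jet_args[names(draws)] <- draws
  }
  do.call(jet_spec, jet_args)
}

write_manifest <- function(out_dir, stage, config, inputs, outputs) {
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(stage = stage,
                   package_version =
                     as.character(utils::packageVersion("aortaflow")),
                   created = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ"),
                   seed = config$seed,
                   config_md5 = hash,
                   config = jsonlite::fromJSON(cfg_json,
                                               simplifyVector = TRUE),
                   inputs = inputs, outputs = outputs)
  path <- file.path(out_dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the generation stage
#'
#' Generates `n_cases` paired velocity fields on the configured geometry:
#' for each case a fine "cfd-like" field and its MRI-like degraded
#' counterpart, plus a ground-truth JSON sidecar. Deterministic for a fixed
#' seed; case `i` uses seed `seed + i`.
#'
#' @param config A configuration list, JSON path, or `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a data frame listing per-case output files
#'   (`case`, `cfd`, `mri`, `truth`).
#' @export
run_generate <- function(config, out_dir, seed = NULL) {
  config <- validate_pipeline_config(config)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$noise$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$n_cases
  if (n == 0) {
    warning("n_cases is 0; nothing to generate")
    write_manifest(out_dir, "generate", config, character(0), character(0))
    return(invisible(data.frame(case = integer(0))))
  }
  geo <- build_idealized_aorta(config$geometry)
  vox <- voxelize_geometry(geo, spacing = config$grid_spacing)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    case_seed <- config$seed + i
    jet <- sample_case_jet(config, case_seed)
    gen <- generate_velocity_field(geo, jet, config$grid_spacing,
                                   seed = case_seed, voxelization = vox)
    noise <- config$noise
    noise$seed <- case_seed
    mri <- degrade_to_mri(gen$field, noise)
    id <- sprintf("case%03d", i)
    f_cfd <- file.path(out_dir, paste0(id, "-cfd.vti"))
    f_mri <- file.path(out_dir, paste0(id, "-mri.vti"))
    f_tr <- file.path(out_dir, paste0(id, "-truth.json"))
    write_velocity_field(gen$field, f_cfd)
    write_velocity_field(mri, f_mri)
    write_ground_truth(gen$truth, f_tr)
    rows[[i]] <- data.frame(case = id, cfd = f_cfd, mri = f_mri,
                            truth = f_tr)
  }
  out <- do.call(rbind, rows)
  write_manifest(out_dir, "generate", config, character(0),
                 unlist(out[, -1], use.names = FALSE))
  invisible(out)
}

#' Run the analysis stage
#'
#' Analyzes a set of velocity-field files against the configured geometry
#' and writes one hemodynamic report JSON per case plus a combined CSV. A
#' case that fails to read or analyze is recorded in the returned data
#' frame and in the manifest; the run continues.
#'
#' @param field_paths Character vector of `.vti` files.
#' @param config Configuration (list, JSON path, or `pipeline_config`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `reports` (the successful
#'   `hemodynamic_report`s, named by case), `table` (data frame), and
#'   `failures` (named character vector of error messages).
#' @export
run_analyze <- function(field_paths, config, out_dir) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geo <- build_idealized_aorta(config$geometry)
  reports <- list(); failures <- character(0)
  for (fp in field_paths) {
    id <- sub("\\.vti$", "", basename(fp))
    res <- tryCatch({
      field <- read_velocity_field(fp)
      rep <- analyze_case(field, geo, params = config$rheology,
                          section_resolution =
                            config$analysis$section_resolution,
                          v_max_region = config$analysis$v_max_region)
      rep$patient_id <- id
      rep
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      message("case ", id, " failed: ", conditionMessage(res))
    } else {
      reports[[id]] <- res
      write_report_json(res, file.path(out_dir, paste0(id, "-report.json")))
    }
  }
  tab <- if (length(reports)) reports_to_df(reports) else data.frame()
  csv <- file.path(out_dir, "reports.csv")
  write.csv(tab, csv, row.names = FALSE)
  write_manifest(out_dir, "analyze", config, field_paths,
                 c(csv, file.path(out_dir, paste0(names(reports),
                                                  "-report.json"))))
  invisible(list(reports = reports, table = tab, failures = failures))
}

#' Run the comparison stage
#'
#' Pairs two report CSVs (as written by [run_analyze()]) by case id after
#' stripping the field-type suffix (`-cfd` / `-mri`), and writes the
#' per-parameter, per-section comparison table (medians, IQRs, R-squared,
#' residual RMSE).
#'
#' @param reports_a_csv,reports_b_csv Paths to `reports.csv` files.
#' @param out_dir Output directory.
#' @return Invisibly, the comparison data frame.
#' @export
run_compare <- function(reports_a_csv, reports_b_csv, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports_from_csv <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df))
      stop_af("empty report table: ", path, class = "aortaflow_validation")
    sfd_cols <- grep("^sfd_", names(df), value = TRUE)
    nfd_cols <- grep("^nfd_", names(df), value = TRUE)
    lapply(seq_len(nrow(df)), function(i) {
      structure(list(
        patient_id = sub("-(cfd|mri)$", "", df$patient[i]),
        v_max = df$v_max_m_s[i], dp_max = df$dp_max_mmhg[i],
        sfd = setNames(as.numeric(df[i, sfd_cols]),
                       sub("^sfd_", "", sfd_cols)),
        nfd = setNames(as.numeric(df[i, nfd_cols]),
                       sub("^nfd_", "", nfd_cols))),
        class = "hemodynamic_report")
    })
  }
  ra <- reports_from_csv(reports_a_csv)
  rb <- reports_from_csv(reports_b_csv)
  tab <- build_comparison_table(ra, rb)
  out <- file.path(out_dir, "comparison.csv")
  write.csv(tab, out, row.names = FALSE)
  invisible(tab)
}

#' Run the streamline-tracing stage
#'
#' Seeds streamlines on a disc just downstream of the valve plane and traces
#' them through a field file, writing VTK polydata and long-format CSV.
#'
#' @param field_path Path to a `.vti` field.
#' @param config Configuration (list, JSON path, or `pipeline_config`).
#' @param out_dir Output directory.
#' @param n_seeds Number of seed points.
#' @param step Integration step (m).
#' @return Invisibly, the `streamline_set`.
#' @export
run_trace <- function(field_path, config, out_dir, n_seeds = 25,
                      step = 5e-4) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geo <- build_idealized_aorta(config$geometry)
  field <- read_velocity_field(field_path)
  s0 <- geo$landmarks$s_valve + 2 * max(field$spacing)
  fr <- frame_at(geo, s0)
  ctr <- centerline_at(geo, s0)
  r0 <- 0.8 * radius_at(geo, s0)
  ang <- with_seed(config$seed, runif(n_seeds, 0, 2 * pi))
  rad <- with_seed(config$seed + 1L, r0 * sqrt(runif(n_seeds)))
  seeds <- t(vapply(seq_len(n_seeds), function(i)
    ctr + rad[i] * (cos(ang[i]) * fr$n1 + sin(ang[i]) * fr$n2),
    numeric(3)))
  sl <- trace_streamlines(field, seeds, step = step,
                          max_length = 1.2 * geo$length)
  id <- sub("\\.vti$", "", basename(field_path))
  write_streamlines_vtp(sl, file.path(out_dir,
                                      paste0(id, "-streamlines.vtp")))
  write.csv(streamlines_to_df(sl),
            file.path(out_dir, paste0(id, "-streamlines.csv")),
            row.names = FALSE)
  write_manifest(out_dir, "trace", config, field_path,
                 file.path(out_dir, paste0(id, c("-streamlines.vtp",
                                                 "-streamlines.csv"))))
  invisible(sl)
}
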