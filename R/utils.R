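# Internal helpers: argument checking, seeded RNG scopes, small vector algebra.

stop_af <- function(..., class = "aortaflow_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_af(name, " must be a single number", class = "aortaflow_validation")
  if (finite && !is.finite(x) && !(is.infinite(x) && x > 0 && !positive && !nonneg))
    if (!is.finite(x)) stop_af(name, " must be finite",
                               class = "aortaflow_validation")
  if (positive && x <= 0)
    stop_af(name, " must be > 0", class = "aortaflow_validation")
  if (nonneg && x < 0)
    stop_af(name, " must be >= 0", class = "aortaflow_validation")
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_af("seed must be a single integer", class = "aortaflow_validation")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop_af("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

#' Locate a packaged example data file
#'
#' The package ships small plain-text reference tables: `table2.csv`
#' (prosthesis sizes, peak systolic inlet flow rates in ml/s, and Reynolds
#' numbers at the prosthesis orifice for a ten-patient surgical AVR cohort)
#' and `table3.csv` (MRI- and CFD-derived indexed effective orifice areas for
#' the same cohort, reference values only).
#'
#' @param file File name, e.g. `"table2.csv"`. With no argument, lists the
#'   available files.
#' @return Full path to the file, or a character vector of file names.
#' @export
#' @examples
#' aortaflow_example()
#' read.csv(aortaflow_example("table2.csv"))
aortaflow_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "aortaflow")))
  path <- system.file("extdata", file, package = "aortaflow")
  if (path == "") stop_af("no packaged file named '", file, "'",
                          class = "aortaflow_io")
  path
}
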