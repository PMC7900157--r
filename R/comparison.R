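# Descriptive comparison statistics for paired MRI/CFD cohorts: ordinary
# least squares with the unadjusted R^2 (squared Pearson correlation) and the
# residual RMSE, median/IQR summaries, prosthesis-size agreement, and the
# per-parameter/per-section comparison table.

#' Simple linear regression with R-squared and residual RMSE
#'
#' Ordinary least squares of `y` on `x` (via [stats::lm()]). `r_squared` is
#' the unadjusted coefficient of determination, equal to the squared Pearson
#' correlation for simple regression. `rmse` is the root mean squared
#' regression residual; the population form (denominator `n`) is the
#' default, with the unbiased `n - 2` form available.
#'
#' @param x,y Numeric vectors of equal length `>= 2`; `x` must not be
#'   constant.
#' @param rmse_denominator `"n"` (default) or `"n-2"`.
#' @return An object of class `"regression_result"` with `slope`,
#'   `intercept`, `r_squared`, `rmse`, `n`.
#' @export
#' @examples
#' linear_regression(c(1, 2, 3), c(2, 2, 5))
linear_regression <- function(x, y, rmse_denominator = c("n", "n-2")) {
  rmse_denominator <- match.arg(rmse_denominator)
  if (length(x) != length(y))
    stop_af("x and y must have equal length", class = "aortaflow_validation")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2)
    stop_af("need at least 2 paired observations",
            class = "aortaflow_validation")
  if (diff(range(x)) == 0)
    stop_af("x is constant; regression is degenerate",
            class = "aortaflow_degenerate")
  fit <- lm(y ~ x)
  res <- fit$residuals
  denom <- if (rmse_denominator == "n") n else {
    if (n <= 2) stop_af("n - 2 denominator needs n > 2",
                        class = "aortaflow_validation")
    n - 2
  }
  r2 <- if (diff(range(y)) == 0) 1 else cor(x, y)^2
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2,
                 rmse = sqrt(sum(res^2) / denom), n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: y = %.4f x + %.4f  (R^2 = %.3f, RMSE = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$rmse, x$n))
  invisible(x)
}

#' Median and interquartile range
#'
#' Median and IQR (`Q3 - Q1`, quartiles by linear interpolation between
#' order statistics, [stats::quantile()] type 7).
#'
#' @param values Nonempty numeric vector.
#' @return A list of class `"summary_stats"` with `median`, `iqr`, `n`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4))
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values))
    stop_af("no finite values", class = "aortaflow_validation")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2], iqr = q[3] - q[1], n = length(values)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("median %.4g (IQR %.4g), n = %d\n", x$median, x$iqr, x$n))
  invisible(x)
}

#' Prosthesis-size agreement between virtual intervention and surgery
#'
#' Mean absolute difference between the prosthesis size chosen during
#' virtual intervention and the size actually implanted, and the number of
#' patients for which the two sizes are identical.
#'
#' @param records Either a data frame with columns `size_vi_mm` and
#'   `size_as_mm` (e.g. from [read_patient_table()]) or a list of
#'   [patient_record()] objects.
#' @return A list with `mae_mm` and `n_identical`.
#' @export
#' @examples
#' size_agreement(read_patient_table(aortaflow_example("table2.csv")))
size_agreement <- function(records) {
  if (is.data.frame(records)) {
    vi <- records$size_vi_mm; as_ <- records$size_as_mm
  } else {
    vi <- vapply(records, `[[`, numeric(1), "size_vi_mm")
    as_ <- vapply(records, `[[`, numeric(1), "size_as_mm")
  }
  if (is.null(vi) || is.null(as_) || !length(vi) || anyNA(vi) || anyNA(as_))
    stop_af("both prosthesis sizes must be present for every record",
            class = "aortaflow_validation")
  list(mae_mm = mean(abs(vi - as_)), n_identical = sum(vi == as_))
}

# Flatten a list of hemodynamic_report objects into a long data frame:
# one row per case x parameter x section (sections "all" for v_max/dp_max).
reports_to_long <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    rbind(data.frame(case = r$patient_id, parameter = c("v_max", "dp_max"),
                     section = "all", value = c(r$v_max, r$dp_max)),
          data.frame(case = r$patient_id, parameter = "sfd",
                     section = names(r$sfd), value = unname(r$sfd)),
          data.frame(case = r$patient_id, parameter = "nfd",
                     section = names(r$nfd), value = unname(r$nfd)))
  }))
}

#' Build a paired comparison table for two report sets
#'
#' For every hemodynamic parameter and cross section, computes the
#' median/IQR of both arms and the ordinary-least-squares agreement
#' (`R^2`, residual RMSE) of arm `b` regressed on arm `a`, pairing cases by
#' patient id. SFD and NFD additionally get an `"all"` row pooling the three
#' sections (each case contributing three paired values).
#'
#' @param reports_a,reports_b Lists of `hemodynamic_report` objects (e.g.
#'   MRI-derived and CFD-derived); must cover the same case ids.
#' @return A data frame with columns `parameter`, `section`, `median_a`,
#'   `iqr_a`, `median_b`, `iqr_b`, `r_squared`, `rmse`, `n`.
#' @export
build_comparison_table <- function(reports_a, reports_b) {
  if (!length(reports_a))
    stop_af("empty report set", class = "aortaflow_validation")
  la <- reports_to_long(reports_a)
  lb <- reports_to_long(reports_b)
  ids_a <- unique(la$case); ids_b <- unique(lb$case)
  unmatched <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(unmatched))
    stop_af("unpaired case ids: ", paste(unmatched, collapse = ", "),
            class = "aortaflow_validation")
  key <- function(d) paste(d$case, d$parameter, d$section)
  lb <- lb[match(key(la), key(lb)), ]
  combos <- unique(la[, c("parameter", "section")])
  pooled <- data.frame(parameter = c("sfd", "nfd"), section = "all")
  combos <- rbind(combos, pooled)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    par <- combos$parameter[i]; sec <- combos$section[i]
    sel <- la$parameter == par &
      (if (sec == "all" && par %in% c("sfd", "nfd")) TRUE
       else la$section == sec)
    a <- la$value[sel]; b <- lb$value[sel]
    # a constant column (e.g. SFD identically zero in swirl-free cases)
    # yields NA agreement statistics rather than aborting the table
    reg <- tryCatch(linear_regression(a, b),
                    aortaflow_degenerate = function(e) NULL)
    ma <- median_iqr(a); mb <- median_iqr(b)
    data.frame(parameter = par, section = sec,
               median_a = ma$median, iqr_a = ma$iqr,
               median_b = mb$median, iqr_b = mb$iqr,
               r_squared = if (is.null(reg)) NA_real_ else reg$r_squared,
               rmse = if (is.null(reg)) NA_real_ else reg$rmse,
               n = length(a))
  })
  out <- do.call(rbind, rows)
  out[order(out$parameter, out$section != "all", out$section), ]
}
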