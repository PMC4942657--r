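#' Linear calibration curve
#'
#' Per-compound linear detector response, area = slope * concentration +
#' intercept, valid over the concentration range it was fitted on.
#'
#' @param compound_id compound the curve belongs to.
#' @param slope response slope, area units per ug/mL (> 0).
#' @param intercept area-axis intercept.
#' @param r Pearson correlation coefficient of the fit.
#' @param range numeric length-2, `c(low, high)` validated concentration
#'   range in ug/mL.
#' @return list of class `calibration_curve`.
#' @export
calibration_curve <- function(compound_id, slope, intercept = 0, r = NA_real_,
                              range = c(NA_real_, NA_real_)) {
  if (!is_scalar_number(slope) || slope <= 0) {
    qams_stop("calibration slope must be > 0", "qams_fit_error")
  }
  if (!is.na(r) && (r < -1 || r > 1)) {
    qams_stop("r must lie in [-1, 1]", "qams_fit_error")
  }
  if (all(is.finite(range)) && range[1] >= range[2]) {
    qams_stop("range must satisfy low < high", "qams_fit_error")
  }
  structure(
    list(compound_id = as.character(compound_id), slope = slope,
         intercept = intercept, r = r, range = as.numeric(range)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: area = %.6g * conc %+.6g (r = %s, range %.4g-%.4g ug/mL)\n",
    x$compound_id, x$slope, x$intercept,
    ifelse(is.na(x$r), "NA", format(x$r, digits = 4)), x$range[1], x$range[2]
  ))
  invisible(x)
}

#' Fit a calibration curve by ordinary least squares
#'
#' Regresses integrated peak area on standard concentration (unweighted OLS)
#' and reports the Pearson correlation. At least three distinct
#' concentrations are required to fit; fewer than six (the customary number
#' of calibration levels) raises a warning.
#'
#' @param concentration known concentrations, ug/mL.
#' @param area measured peak areas.
#' @param compound_id label stored in the returned curve.
#' @return a [calibration_curve()], with `range` set to the observed
#'   concentration span.
#' @examples
#' conc <- 415.2 / c(1, 2, 4, 8, 16, 32)
#' fit_calibration(conc, 14317 * conc - 32209, "loganin")
#' @export
fit_calibration <- function(concentration, area, compound_id = "") {
  if (length(concentration) != length(area)) {
    qams_stop("concentration and area differ in length", "qams_fit_error")
  }
  keep <- is.finite(concentration) & is.finite(area)
  concentration <- concentration[keep]
  area <- area[keep]
  n_distinct <- length(unique(concentration))
  if (length(concentration) < 3L || n_distinct < 3L) {
    qams_stop(
      "calibration needs at least 3 points at 3 distinct concentrations",
      "qams_fit_error"
    )
  }
  if (n_distinct < 6L) {
    warning(sprintf(
      "only %d distinct calibration levels for '%s' (6 or more are customary)",
      n_distinct, compound_id
    ), call. = FALSE)
  }
  fit <- stats::lm(area ~ concentration)
  coefs <- stats::coef(fit)
  if (!is.finite(coefs[2]) || coefs[2] <= 0) {
    qams_stop("fitted calibration slope is not positive", "qams_fit_error")
  }
  calibration_curve(
    compound_id = compound_id,
    slope = unname(coefs[2]),
    intercept = unname(coefs[1]),
    r = stats::cor(concentration, area),
    range = range(concentration)
  )
}

#' Invert a calibration curve
#'
#' Maps a measured area back to a concentration, `(area - intercept) /
#' slope`. Results outside the curve's validated range (including negative
#' concentrations) are returned flagged rather than rejected, so contents of
#' samples sitting near range edges remain computable.
#'
#' @param curve a `calibration_curve`.
#' @param area numeric vector of areas.
#' @return data frame with columns `concentration_ug_ml`, `in_range`, and
#'   `flag` (`"ok"`, `"below_range"`, `"above_range"` or `"negative"`).
#' @export
invert_calibration <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (area - curve$intercept) / curve$slope
  lo <- curve$range[1]
  hi <- curve$range[2]
  in_range <- if (all(is.finite(curve$range))) {
    conc >= lo & conc <= hi
  } else {
    rep(NA, length(conc))
  }
  flag <- rep("ok", length(conc))
  if (all(is.finite(curve$range))) {
    flag[conc < lo] <- "below_range"
    flag[conc > hi] <- "above_range"
  }
  flag[conc < 0] <- "negative"
  data.frame(
    concentration_ug_ml = conc,
    in_range = in_range,
    flag = flag,
    stringsAsFactors = FALSE
  )
}

#' Serialize calibration curves to JSON
#'
#' @param curves list of `calibration_curve`.
#' @param path JSON file path.
#' @return `path` invisibly.
#' @export
write_calibration_curves <- function(curves, path) {
  payload <- lapply(unname(curves), function(cv) {
    list(compound_id = cv$compound_id, slope = cv$slope,
         intercept = cv$intercept, r = cv$r, range = cv$range)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_curves
#' @export
read_calibration_curves <- function(path) {
  if (!file.exists(path)) {
    qams_stop(paste0("no such file: ", path), "qams_io_error")
  }
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  curves <- lapply(payload, function(p) {
    calibration_curve(p$compound_id, p$slope, p$intercept,
                      p$r %||% NA_real_, unlist(p$range))
  })
  names(curves) <- vapply(curves, `[[`, "", "compound_id")
  curves
}
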