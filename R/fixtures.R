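#' Path to a bundled reference data file
#'
#' The package ships the published reference data of the Fructus Corni
#' eleven-component assay as plain-text files: calibration coefficients,
#' stock concentrations, replicate RCF determinations, ruggedness panels
#' (instruments/columns, temperature, flow rate), relative-retention-time
#' panels, spike recoveries, and the 31-sample content comparison.
#'
#' @param file file name inside the package's `extdata` directory; NULL
#'   lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
qams_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "qams")))
  }
  path <- system.file("extdata", file, package = "qams")
  if (!nzchar(path)) {
    qams_stop(paste0("no bundled file named '", file, "'"), "qams_io_error")
  }
  path
}

#' Bundled reference calibration curves
#' @return named list of [calibration_curve()] for the 11 compounds.
#' @export
reference_curves <- function() {
  read_calibration_curves(qams_example("reference_curves.json"))
}

#' Bundled mixed-standard stock concentrations
#' @return named numeric vector, ug/mL per compound.
#' @export
stock_concentrations <- function() {
  tab <- utils::read.csv(qams_example("stock_concentrations.csv"),
                         stringsAsFactors = FALSE)
  stats::setNames(tab$concentration_ug_ml, tab$compound_id)
}

# melt a wide fixture (first id columns, then one column per compound)
melt_fixture <- function(tab, id_cols, value_name) {
  compounds <- setdiff(names(tab), id_cols)
  long <- do.call(rbind, lapply(compounds, function(cid) {
    out <- tab[, id_cols, drop = FALSE]
    out$compound_id <- cid
    out[[value_name]] <- tab[[cid]]
    out
  }))
  rownames(long) <- NULL
  long
}

#' Bundled replicate RCF determinations
#'
#' Six mixed standard solutions, one RCF per solution per non-reference
#' compound.
#'
#' @return long data frame: `solution`, `compound_id`, `f_is`.
#' @export
reference_rcf_replicates <- function() {
  tab <- utils::read.csv(qams_example("rcf_replicates.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  melt_fixture(tab, "solution", "f_is")
}

#' Bundled RCF ruggedness panels
#'
#' Per-condition RCF determinations across instrument/column combinations,
#' column temperatures, and flow rates. Empty cells (peak pair not
#' separated under that condition) are NA.
#'
#' @param which panel to load.
#' @return long data frame: `condition`, the factor column(s),
#'   `compound_id`, `f_is`.
#' @export
reference_ruggedness <- function(which = c("instrument_column",
                                           "temperature", "flow_rate")) {
  which <- match.arg(which)
  file <- paste0("ruggedness_", which, ".csv")
  tab <- utils::read.csv(qams_example(file), stringsAsFactors = FALSE,
                         check.names = FALSE)
  id_cols <- switch(which,
    instrument_column = c("instrument", "column"),
    temperature = "temperature_c",
    flow_rate = "flow_rate_ml_min"
  )
  long <- melt_fixture(tab, id_cols, "f_is")
  long$condition <- do.call(paste, c(lapply(id_cols, function(c) long[[c]]),
                                     sep = "/"))
  long[, c("condition", id_cols, "compound_id", "f_is")]
}

#' Bundled relative-retention-time panel
#'
#' Observed RRT of each target compound against the internal reference,
#' per instrument/column combination.
#'
#' @return long data frame: `condition`, `instrument`, `column`,
#'   `compound_id`, `rrt`.
#' @export
reference_rrt_panel <- function() {
  tab <- utils::read.csv(qams_example("rrt_panel.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  long <- melt_fixture(tab, c("instrument", "column"), "rrt")
  long$condition <- paste(long$instrument, long$column, sep = "/")
  long[, c("condition", "instrument", "column", "compound_id", "rrt")]
}

#' Default RRT reference for the Fructus Corni assay
#'
#' The per-compound mean RRTs shipped with the package, as an
#' [rrt_reference()] with a 5% default tolerance.
#'
#' @param tolerance_percent matching tolerance (default 5).
#' @return an `rrt_reference` for the 10 non-reference compounds.
#' @export
default_rrt_reference <- function(tolerance_percent = 5) {
  tab <- utils::read.csv(qams_example("rrt_reference.csv"),
                         stringsAsFactors = FALSE)
  rrt_reference(tab$compound_id, tab$expected_rrt, tolerance_percent)
}

#' Bundled spike-recovery results
#' @return data frame: `compound_id`, `original_mg`, `added_mg`,
#'   `detected_mg`, `recovery_percent`, `rsd_percent` (published values;
#'   n = 6 replicates per compound).
#' @export
reference_recovery <- function() {
  utils::read.csv(qams_example("spike_recovery.csv"),
                  stringsAsFactors = FALSE)
}

#' Bundled 31-sample content comparison
#'
#' Contents (mg per g of herb) of 21 crude and 10 processed Fructus Corni
#' samples by the external standard method and by QAMS. "ND" cells (component
#' absent, e.g. processing markers in crude samples) are NA; the internal
#' reference has no QAMS value, being the calibrated compound itself.
#'
#' @return long data frame: `sample_id`, `type`, `compound_id`,
#'   `esm_mg_g`, `qams_mg_g`.
#' @export
reference_sample_contents <- function() {
  tab <- utils::read.csv(qams_example("sample_contents.csv"),
                         stringsAsFactors = FALSE, na.strings = "ND",
                         check.names = FALSE)
  cols <- setdiff(names(tab), c("sample_id", "type"))
  ids <- unique(sub("_(esm|qams)$", "", cols))
  long <- do.call(rbind, lapply(ids, function(cid) {
    data.frame(
      sample_id = tab$sample_id,
      type = tab$type,
      compound_id = cid,
      esm_mg_g = tab[[paste0(cid, "_esm")]],
      qams_mg_g = if (paste0(cid, "_qams") %in% names(tab)) {
        tab[[paste0(cid, "_qams")]]
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  }))
  rownames(long) <- NULL
  long
}

#' Content comparison fixture as paired method records
#'
#' Reshapes [reference_sample_contents()] into the two record tables
#' [compare_methods()] consumes.
#'
#' @return list with elements `esm` and `qams`.
#' @export
reference_content_records <- function() {
  long <- reference_sample_contents()
  records <- function(col, method) {
    data.frame(
      sample_id = long$sample_id,
      compound_id = long$compound_id,
      method = method,
      content_mg_g = long[[col]],
      not_detected = is.na(long[[col]]),
      stringsAsFactors = FALSE
    )
  }
  list(esm = records("esm_mg_g", "ESM"), qams = records("qams_mg_g", "QAMS"))
}
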