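#' Chromatographic run condition
#'
#' Metadata describing the instrument configuration a run was acquired under.
#' Arbitrary positive temperatures and flow rates are accepted; the bundled
#' ruggedness panels use 25/30/35 degrees C and 0.9/1.0/1.1 mL/min.
#'
#' @param instrument instrument label.
#' @param column column label.
#' @param temperature_c column temperature in degrees Celsius.
#' @param flow_rate_ml_min mobile-phase flow rate in mL per minute.
#' @return a list of class `run_condition`.
#' @export
run_condition <- function(instrument = "default", column = "default",
                          temperature_c = 30, flow_rate_ml_min = 1.0) {
  if (!is_scalar_number(temperature_c) || temperature_c <= 0) {
    qams_stop("temperature_c must be a positive number", "qams_config_error")
  }
  if (!is_scalar_number(flow_rate_ml_min) || flow_rate_ml_min <= 0) {
    qams_stop("flow_rate_ml_min must be a positive number", "qams_config_error")
  }
  structure(
    list(
      instrument = as.character(instrument), column = as.character(column),
      temperature_c = temperature_c, flow_rate_ml_min = flow_rate_ml_min
    ),
    class = "run_condition"
  )
}

#' Sample preparation record
#'
#' Bookkeeping needed to convert a solution concentration back to a content
#' per gram of herb: powder mass, extraction volume and any further dilution.
#' The Fructus Corni preparation is 2 g of powder extracted into 50 mL of
#' methanol and injected without further dilution.
#'
#' @param mass_g weighed powder mass in grams.
#' @param extraction_volume_ml extraction volume in mL.
#' @param dilution_factor dimensionless dilution applied after extraction
#'   (>= 1; 1 means injected as extracted).
#' @return a list of class `sample_prep`.
#' @export
sample_prep <- function(mass_g = 2, extraction_volume_ml = 50,
                        dilution_factor = 1) {
  if (!is_scalar_number(mass_g) || mass_g <= 0) {
    qams_stop("mass_g must be > 0", "qams_config_error")
  }
  if (!is_scalar_number(extraction_volume_ml) || extraction_volume_ml <= 0) {
    qams_stop("extraction_volume_ml must be > 0", "qams_config_error")
  }
  if (!is_scalar_number(dilution_factor) || dilution_factor < 1) {
    qams_stop("dilution_factor must be >= 1", "qams_config_error")
  }
  structure(
    list(
      mass_g = mass_g, extraction_volume_ml = extraction_volume_ml,
      dilution_factor = dilution_factor
    ),
    class = "sample_prep"
  )
}

#' Standard mixture level
#'
#' One dilution level of a mixed standard solution: a named vector of known
#' concentrations (ug/mL) per compound.
#'
#' @param level_id identifier of the level.
#' @param concentrations named numeric vector, ug/mL per compound id.
#' @param registry optional `compound_registry`; when given, the internal
#'   reference must be present among the concentrations.
#' @return a list of class `standard_level`.
#' @export
standard_level <- function(level_id, concentrations, registry = NULL) {
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
    qams_stop("concentrations must be a named vector", "qams_config_error")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    qams_stop("all standard concentrations must be > 0", "qams_config_error")
  }
  if (!is.null(registry)) {
    ref <- internal_reference(registry)
    if (!ref %in% names(concentrations)) {
      qams_stop(
        sprintf("internal reference '%s' missing from standard level", ref),
        "qams_config_error"
      )
    }
  }
  structure(
    list(level_id = as.character(level_id), concentrations = concentrations),
    class = "standard_level"
  )
}

#' Injection run
#'
#' One chromatographic injection: a peak table (retention time in minutes,
#' integrated area in arbitrary absorbance units, optional compound
#' assignment) plus acquisition metadata. Peaks are stored sorted by
#' retention time; duplicate retention times within one run are rejected.
#'
#' @param run_id run identifier.
#' @param peaks data frame with columns `rt_min`, `area` and optionally
#'   `compound_id` (NA until peaks are located).
#' @param condition a `run_condition`.
#' @param source what was injected: a standard level id or a sample id.
#' @param window_max_min upper end of the analysis window in minutes; all
#'   retention times must fall in (0, window_max_min].
#' @return a list of class `injection_run`.
#' @export
injection_run <- function(run_id, peaks, condition = run_condition(),
                          source = NA_character_, window_max_min = 50) {
  if (!is.data.frame(peaks) || !all(c("rt_min", "area") %in% names(peaks))) {
    qams_stop("peaks must have columns rt_min and area", "qams_parse_error")
  }
  if (is.null(peaks$compound_id)) peaks$compound_id <- NA_character_
  peaks <- peaks[, c("rt_min", "area", "compound_id")]
  if (any(!is.finite(peaks$rt_min)) || any(peaks$rt_min <= 0) ||
      any(peaks$rt_min > window_max_min)) {
    qams_stop(
      sprintf("retention times must lie in (0, %g] minutes", window_max_min),
      "qams_parse_error"
    )
  }
  if (any(!is.finite(peaks$area)) || any(peaks$area < 0)) {
    qams_stop("areas must be finite and >= 0", "qams_parse_error")
  }
  peaks <- peaks[order(peaks$rt_min), , drop = FALSE]
  rownames(peaks) <- NULL
  if (anyDuplicated(peaks$rt_min)) {
    qams_stop("two peaks share an identical retention time", "qams_parse_error")
  }
  structure(
    list(
      run_id = as.character(run_id), condition = condition, peaks = peaks,
      source = as.character(source), window_max_min = window_max_min
    ),
    class = "injection_run"
  )
}

#' @export
print.injection_run <- function(x, ...) {
  cat(sprintf(
    "<injection_run> %s (%d peaks, source: %s)\n",
    x$run_id, nrow(x$peaks), x$source
  ))
  print.data.frame(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Read a peak-table CSV into injection runs
#'
#' The expected dialect is comma-separated UTF-8 with a mandatory header row
#' and decimal points. One row per detected peak; rows are grouped into runs
#' by run id (in order of first appearance) and peaks sorted by retention
#' time. Malformed numeric cells are reported with their data row numbers
#' (first data row below the header is row 1).
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical column names
#'   `run_id`, `rt_min`, `area` (and optionally `compound_id`, `source`) to
#'   the file's column names.
#' @param condition `run_condition` attached to every run, or a function of
#'   the run id returning one.
#' @param window_max_min analysis window passed to [injection_run()].
#' @return list of `injection_run`, named by run id.
#' @export
read_peak_table <- function(path,
                            schema = c(run_id = "run_id", rt_min = "rt_min",
                                       area = "area",
                                       compound_id = "compound_id",
                                       source = "source"),
                            condition = run_condition(),
                            window_max_min = 50) {
  if (!file.exists(path)) {
    qams_stop(paste0("no such file: ", path), "qams_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  required <- c("run_id", "rt_min", "area")
  for (col in required) {
    if (is.na(schema[col]) || !schema[col] %in% names(raw)) {
      qams_stop(
        sprintf("missing required column '%s' in %s", schema[col] %||% col, path),
        "qams_schema_error"
      )
    }
  }
  num <- function(field) {
    x <- suppressWarnings(as.numeric(raw[[schema[field]]]))
    bad <- which(is.na(x) & !(raw[[schema[field]]] %in% c("", "NA")))
    if (length(bad)) {
      qams_stop(
        sprintf("non-numeric %s in row %s", field,
                paste(bad, collapse = ", ")),
        "qams_parse_error"
      )
    }
    x
  }
  rt <- num("rt_min")
  area <- num("area")
  cid <- if (!is.na(schema["compound_id"]) &&
             schema["compound_id"] %in% names(raw)) {
    ifelse(raw[[schema["compound_id"]]] %in% c("", "NA"), NA_character_,
           raw[[schema["compound_id"]]])
  } else {
    NA_character_
  }
  src <- if (!is.na(schema["source"]) && schema["source"] %in% names(raw)) {
    raw[[schema["source"]]]
  } else {
    NA_character_
  }
  run_ids <- raw[[schema["run_id"]]]
  runs <- lapply(unique(run_ids), function(rid) {
    idx <- which(run_ids == rid)
    cond <- if (is.function(condition)) condition(rid) else condition
    injection_run(
      run_id = rid,
      peaks = data.frame(rt_min = rt[idx], area = area[idx],
                         compound_id = if (length(cid) > 1L) cid[idx] else cid,
                         stringsAsFactors = FALSE),
      condition = cond,
      source = if (length(src) > 1L) src[idx][1L] else src,
      window_max_min = window_max_min
    )
  })
  names(runs) <- unique(run_ids)
  runs
}

#' Write injection runs to a peak-table CSV
#'
#' Inverse of [read_peak_table()]: numeric fields round-trip exactly at
#' 15 significant digits.
#'
#' @param runs list of `injection_run`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_peak_table <- function(runs, path) {
  if (inherits(runs, "injection_run")) runs <- list(runs)
  tab <- do.call(rbind, lapply(runs, function(r) {
    data.frame(
      run_id = r$run_id,
      rt_min = r$peaks$rt_min,
      area = r$peaks$area,
      compound_id = r$peaks$compound_id,
      source = r$source,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(format(tab, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a standard concentration table
#'
#' CSV with a `level_id` column plus one column per compound id holding the
#' known concentration (ug/mL) of that compound at each level.
#'
#' @param path CSV path.
#' @param registry optional registry forwarded to [standard_level()].
#' @return list of `standard_level`, named by level id.
#' @export
read_concentration_table <- function(path, registry = NULL) {
  if (!file.exists(path)) {
    qams_stop(paste0("no such file: ", path), "qams_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"level_id" %in% names(raw)) {
    qams_stop("missing required column 'level_id'", "qams_schema_error")
  }
  compounds <- setdiff(names(raw), "level_id")
  levels <- lapply(seq_len(nrow(raw)), function(i) {
    conc <- as.numeric(raw[i, compounds])
    names(conc) <- compounds
    conc <- conc[!is.na(conc)]
    standard_level(raw$level_id[i], conc, registry = registry)
  })
  names(levels) <- as.character(raw$level_id)
  levels
}

#' @rdname read_concentration_table
#' @param levels list of `standard_level` to write.
#' @export
write_concentration_table <- function(levels, path) {
  compounds <- unique(unlist(lapply(levels, function(l) names(l$concentrations))))
  rows <- lapply(levels, function(l) {
    v <- l$concentrations[compounds]
    names(v) <- compounds
    c(level_id = l$level_id, format(v, digits = 15, scientific = FALSE,
                                    trim = TRUE))
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read run/sample metadata from JSON or YAML
#'
#' Accepts a file with keys `instrument`, `column`, `temperature_c`,
#' `flow_rate_ml_min` and an optional `sample` block with `mass_g`,
#' `volume_ml`, `dilution`.
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return list with elements `condition` (a `run_condition`) and `prep`
#'   (a `sample_prep`, or NULL when no sample block is present).
#' @export
read_run_metadata <- function(path) {
  if (!file.exists(path)) {
    qams_stop(paste0("no such file: ", path), "qams_io_error")
  }
  meta <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cond <- run_condition(
    instrument = meta$instrument %||% "default",
    column = meta$column %||% "default",
    temperature_c = meta$temperature_c %||% 30,
    flow_rate_ml_min = meta$flow_rate_ml_min %||% 1.0
  )
  prep <- if (!is.null(meta$sample)) {
    sample_prep(
      mass_g = meta$sample$mass_g,
      extraction_volume_ml = meta$sample$volume_ml,
      dilution_factor = meta$sample$dilution %||% 1
    )
  }
  list(condition = cond, prep = prep)
}
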