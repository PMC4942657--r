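run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    qams_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              "qams_pipeline_error")
  })
}

#' Run the full single-marker quantification workflow
#'
#' Composes the package end to end on in-memory objects:
#' locate standard peaks -> fit calibration curves -> estimate RCFs from the
#' dilution series -> (optionally) summarize a ruggedness panel -> locate and
#' quantify every sample by both the external standard method and QAMS ->
#' compare the two methods. Any stage error is re-raised with the stage name
#' prefixed.
#'
#' @param standard a `standard_series` (or list with `levels` and `runs`).
#' @param samples a `sample_batch` (or list with `runs` and `preps`; `preps`
#'   is one [sample_prep()] or a list named by run id).
#' @param registry a `compound_registry`.
#' @param reference an [rrt_reference()].
#' @param anchor_rt expected internal-reference retention time, minutes.
#' @param window_percent anchor search window (default 5).
#' @param panel optional `condition_panel` for a ruggedness check.
#' @param rcf_threshold_percent ruggedness RSD threshold (default 5).
#' @param test,alpha forwarded to [compare_methods()].
#' @return list of class `qams_pipeline_result` with elements `curves`,
#'   `rcf`, `ruggedness` (or NULL), `esm`, `qams` (content record tables),
#'   `comparison`, and `ok` — TRUE when the methods agree and, if a panel
#'   was given, every compound passes the ruggedness threshold.
#' @export
qams_pipeline <- function(standard, samples,
                          registry = fructus_corni_registry(),
                          reference = default_rrt_reference(),
                          anchor_rt, window_percent = 5,
                          panel = NULL, rcf_threshold_percent = 5,
                          test = "t", alpha = 0.05) {
  validate_registry(registry)
  ref_id <- internal_reference(registry)

  located_std <- run_stage("peak_location", lapply(
    standard$runs, assign_peaks, registry = registry, reference = reference,
    expected_rt = anchor_rt, window_percent = window_percent
  ))

  curves <- run_stage("calibration", {
    pts <- do.call(rbind, lapply(located_std, function(run) {
      lev <- standard$levels[[run$source]]
      pk <- run$peaks[!is.na(run$peaks$compound_id), , drop = FALSE]
      data.frame(
        compound_id = pk$compound_id,
        concentration = unname(lev$concentrations[pk$compound_id]),
        area = pk$area, stringsAsFactors = FALSE
      )
    }))
    out <- lapply(split(pts, pts$compound_id), function(d) {
      fit_calibration(d$concentration, d$area, d$compound_id[1])
    })
    out[registry$id[registry$id %in% names(out)]]
  })

  rcf <- run_stage("rcf", {
    rcf_from_dilution_series(located_std, standard$levels, registry)
  })

  ruggedness <- if (!is.null(panel)) {
    run_stage("ruggedness", {
      located_groups <- lapply(panel$groups, function(runs) {
        lapply(runs, assign_peaks, registry = registry,
               reference = reference, expected_rt = anchor_rt,
               window_percent = window_percent)
      })
      ruggedness_panel(located_groups, panel$levels, registry,
                       rcf_threshold_percent)
    })
  }

  preps <- samples$preps
  quant <- run_stage("quantification", {
    esm <- list()
    qams <- list()
    for (run in samples$runs) {
      located <- run_stage("peak_location", assign_peaks(
        run, registry = registry, reference = reference,
        expected_rt = anchor_rt, window_percent = window_percent
      ))
      prep <- if (inherits(preps, "sample_prep")) preps
        else preps[[run$run_id]]
      esm[[run$run_id]] <- content_records(
        run$run_id, esm_concentration(located, curves, registry), "ESM", prep
      )
      qams[[run$run_id]] <- content_records(
        run$run_id, qams_concentration(located, rcf, curves[[ref_id]],
                                       registry), "QAMS", prep
      )
    }
    list(esm = do.call(rbind, esm), qams = do.call(rbind, qams))
  })
  rownames(quant$esm) <- rownames(quant$qams) <- NULL

  comparison <- run_stage("comparison", {
    compare_methods(quant$esm, quant$qams, test = test, alpha = alpha)
  })

  structure(
    list(
      curves = curves, rcf = rcf, ruggedness = ruggedness,
      esm = quant$esm, qams = quant$qams, comparison = comparison,
      ok = comparison$agreement &&
        (is.null(ruggedness) || all(ruggedness$summary$pass))
    ),
    class = "qams_pipeline_result"
  )
}

#' @export
print.qams_pipeline_result <- function(x, ...) {
  cat("<qams_pipeline_result>\n")
  cat(sprintf("  curves: %d, RCF compounds: %d\n", length(x$curves),
              nrow(x$rcf)))
  if (!is.null(x$ruggedness)) {
    cat(sprintf("  ruggedness: %d/%d compounds pass\n",
                sum(x$ruggedness$summary$pass), nrow(x$ruggedness$summary)))
  }
  cat(sprintf("  samples quantified: %d\n",
              length(unique(x$esm$sample_id))))
  cat(sprintf("  method agreement: %s\n", x$comparison$agreement))
  cat(sprintf("  ok: %s\n", x$ok))
  invisible(x)
}

#' Simulate a complete study to disk
#'
#' Generates a calibration/RCF standard series, a 31-sample-style batch and
#' an instrument/column ruggedness panel from one seed, and writes them as
#' the plain-text formats the readers consume, plus the generating truth as
#' JSON. Identical seeds reproduce identical bytes.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; mandatory, so no simulation has hidden entropy.
#' @param n_crude,n_processed sample counts.
#' @param config optional [generator_config()]; defaults to
#'   `generator_config(seed = seed)`.
#' @param dilutions calibration dilution factors.
#' @param instruments,columns panel factor levels.
#' @return invisibly, a named list of the written file paths.
#' @export
simulate_study <- function(dir, seed, n_crude = 21, n_processed = 10,
                           config = NULL,
                           dilutions = c(1, 2, 4, 8, 16, 32),
                           instruments = c("Instrument A", "Instrument B"),
                           columns = c("Column A", "Column B")) {
  if (missing(seed)) {
    qams_stop("an explicit seed is required", "qams_config_error")
  }
  config <- config %||% generator_config(seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  series <- generate_standard_series(config, dilutions, seed = seed + 1L)
  batch <- generate_sample_batch(config, n_crude, n_processed,
                                 seed = seed + 2L)
  panel <- generate_condition_panel(config, instruments = instruments,
                                    columns = columns, seed = seed + 3L)

  paths <- list(
    standard_peaks = file.path(dir, "standard_peaks.csv"),
    standard_levels = file.path(dir, "standard_levels.csv"),
    sample_peaks = file.path(dir, "sample_peaks.csv"),
    sample_info = file.path(dir, "sample_info.csv"),
    panel_peaks = file.path(dir, "panel_peaks.csv"),
    panel_runs = file.path(dir, "panel_runs.csv"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "manifest.json")
  )
  write_peak_table(series$runs, paths$standard_peaks)
  write_concentration_table(series$levels, paths$standard_levels)
  write_peak_table(batch$runs, paths$sample_peaks)

  prep <- config$prep
  utils::write.csv(
    cbind(batch$sample_info,
          mass_g = prep$mass_g, volume_ml = prep$extraction_volume_ml,
          dilution = prep$dilution_factor),
    paths$sample_info, row.names = FALSE, quote = FALSE
  )

  panel_runs <- do.call(rbind, lapply(names(panel$groups), function(lbl) {
    data.frame(condition = lbl,
               run_id = vapply(panel$groups[[lbl]], `[[`, "", "run_id"),
               stringsAsFactors = FALSE)
  }))
  write_peak_table(do.call(c, unname(panel$groups)), paths$panel_peaks)
  utils::write.csv(panel_runs, paths$panel_runs, row.names = FALSE,
                   quote = FALSE)

  jsonlite::write_json(
    list(
      seed = seed, anchor_rt = config$anchor_rt,
      f_true = as.list(config$f_true),
      true_slope = as.list(config$true_slope),
      contents = batch$truth$contents,
      area_cv = config$area_cv
    ),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(
    list(package = "qams", version = as.character(utils::packageVersion("qams")),
         seed = seed, files = lapply(paths, basename)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
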