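#' Configuration for the synthetic chromatographic-run generator
#'
#' Describes one simulated HPLC system for the eleven-component assay. The
#' generator is phenomenological: each compound responds linearly
#' (area = slope * concentration + intercept), areas carry multiplicative
#' lognormal noise, retention times sit at fixed positions (the bundled mean
#' relative retention times anchored at the internal reference's retention
#' time) and drift mostly *together* within a run.
#'
#' Two deliberate modeling choices:
#' \itemize{
#'   \item The realized detector response of the simulated system differs
#'     from the bundled reference slopes by a fixed per-compound gain drawn
#'     once per configuration (`rcf_perturbation`, uniform within +/- 5% by
#'     default, internal reference fixed at 1). The system's true RCFs are
#'     therefore reference slope ratios perturbed by up to that amount —
#'     which is exactly why correction factors carried over from another
#'     system disagree with same-system calibration.
#'   \item Retention drift decomposes into a run-level component shared by
#'     all peaks (`rt_run_cv`, cancels in relative retention) and a much
#'     smaller independent per-peak jitter (`rt_peak_cv`). Uncorrelated
#'     per-peak drift of 1% would scramble the elution order of peak pairs
#'     only 1% apart in RRT, which real gradients do not do.
#' }
#'
#' @param registry a `compound_registry`.
#' @param curves named list of `calibration_curve` supplying the reference
#'   response slopes (defaults to the bundled curves).
#' @param stock named stock concentrations, ug/mL (bundled values).
#' @param rrt an [rrt_reference()] giving target RRTs (bundled mean row).
#' @param anchor_rt retention time of the internal reference, minutes.
#'   Configurable because absolute retention times are system specific.
#' @param area_cv fractional area noise (default 0.02, the low-percent
#'   repeatability of a well-behaved system).
#' @param rt_run_cv run-level retention drift CV (default 0.01).
#' @param rt_peak_cv independent per-peak retention jitter CV (default
#'   0.0005 — about a second at mid-run, the adjacent-peak reproducibility a
#'   stable gradient actually delivers; anything much larger would scramble
#'   the epimer pairs sitting 0.01 RRT apart, which real systems resolve).
#' @param rcf_perturbation half-width of the per-compound response gain
#'   (default 0.05).
#' @param condition_response_cv per-condition response perturbation CV for
#'   ruggedness panels (default 0.02 — sized so cross-condition RCF RSDs
#'   stay below the 5% acceptance threshold, as observed on real systems).
#' @param condition_rt_cv CV of the per-condition selectivity stretch of
#'   retention relative to the anchor (default 0.005). The stretch is a
#'   monotone warp: neighboring peaks shift together across conditions, as
#'   on real columns, so elution order is preserved while relative
#'   retention of early eluters spreads by a few percent.
#' @param intercepts named true intercepts for area generation. Default all
#'   zero: detector response is proportional at the origin, and the small
#'   negative fitted intercepts of real calibration lines must not be
#'   extrapolated to concentrations far below the calibrated range.
#' @param content_ranges data frame `compound_id`, `lo`, `hi` (mg/g) for
#'   sample-batch truth (defaults span the published 31-sample contents).
#' @param prep a [sample_prep()] (default 2 g / 50 mL / no dilution).
#' @param window_max_min analysis window for generated runs (default 55:
#'   the 50-minute gradient plus a short hold so late peaks survive drift).
#' @param seed integer seed; fixes the configuration's response gains and is
#'   the default seed of every `generate_*` call.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(registry = fructus_corni_registry(),
                             curves = reference_curves(),
                             stock = stock_concentrations(),
                             rrt = default_rrt_reference(),
                             anchor_rt = 31.0,
                             area_cv = 0.02,
                             rt_run_cv = 0.01,
                             rt_peak_cv = 0.0005,
                             rcf_perturbation = 0.05,
                             condition_response_cv = 0.02,
                             condition_rt_cv = 0.005,
                             intercepts = NULL,
                             content_ranges = default_content_ranges(),
                             prep = sample_prep(),
                             window_max_min = 55,
                             seed = 1L) {
  validate_registry(registry)
  stopifnot(area_cv >= 0, rt_run_cv >= 0, rt_peak_cv >= 0,
            rcf_perturbation >= 0, condition_response_cv >= 0,
            condition_rt_cv >= 0)
  ids <- registry$id
  ref <- internal_reference(registry)
  slope <- vapply(ids, function(id) curves[[id]]$slope, numeric(1))
  if (any(slope <= 0)) {
    qams_stop("reference slopes must be > 0", "qams_config_error")
  }
  beta <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(intercepts)) beta[names(intercepts)] <- intercepts

  base_rt <- stats::setNames(rep(NA_real_, length(ids)), ids)
  base_rt[ref] <- anchor_rt
  base_rt[rrt$compound_id] <- anchor_rt * rrt$expected_rrt
  if (any(is.na(base_rt))) {
    qams_stop("rrt reference does not cover the registry", "qams_config_error")
  }
  if (any(diff(base_rt) <= 0)) {
    qams_stop("base retention times must increase in elution order",
              "qams_config_error")
  }
  if (max(base_rt) >= window_max_min) {
    qams_stop("latest peak does not fit the analysis window",
              "qams_config_error")
  }

  gain <- with_seed(seed, {
    g <- stats::runif(length(ids), 1 - rcf_perturbation, 1 + rcf_perturbation)
    g[ids == ref] <- 1
    stats::setNames(g, ids)
  })
  true_slope <- slope * gain

  structure(
    list(
      registry = registry, stock = stock[ids],
      slope = stats::setNames(slope, ids), gain = gain,
      true_slope = true_slope, intercept = beta,
      f_true = stats::setNames(true_slope[ref] / true_slope, ids),
      base_rt = base_rt, anchor_rt = anchor_rt,
      area_cv = area_cv, rt_run_cv = rt_run_cv, rt_peak_cv = rt_peak_cv,
      rcf_perturbation = rcf_perturbation,
      condition_response_cv = condition_response_cv,
      condition_rt_cv = condition_rt_cv,
      content_ranges = content_ranges, prep = prep,
      crude_absent = intersect(
        c("hmf", "ethylmorroniside_7a", "ethylmorroniside_7b"), ids
      ),
      window_max_min = window_max_min, seed = seed
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d compounds, anchor %s at %.4g min, area CV %.3g, seed %d\n",
    nrow(x$registry), internal_reference(x$registry), x$anchor_rt,
    x$area_cv, x$seed
  ))
  invisible(x)
}

#' Default per-compound content ranges for sample simulation
#'
#' Uniform sampling ranges (mg per g of herb) spanning the contents observed
#' across the 31 bundled crude and processed samples.
#'
#' @return data frame `compound_id`, `lo`, `hi`.
#' @export
default_content_ranges <- function() {
  data.frame(
    compound_id = c("gallic_acid", "hmf", "morroniside", "cornin",
                    "sweroside", "loganin", "methylmorroniside_7a",
                    "methylmorroniside_7b", "ethylmorroniside_7a",
                    "ethylmorroniside_7b", "cornuside"),
    lo = c(0.39, 1.42, 3.50, 0.18, 0.66, 6.2, 0.01, 0.04, 0.14, 0.23, 0.81),
    hi = c(2.40, 2.43, 14.02, 0.34, 1.10, 8.7, 0.03, 0.09, 0.35, 0.38, 1.75),
    stringsAsFactors = FALSE
  )
}

# one simulated injection; assumes the caller set the RNG state.
# rt_stretch is a per-condition monotone warp of retention relative to the
# anchor (selectivity drifts smoothly along the gradient, so neighboring
# peaks move together and never reorder across conditions).
generate_run <- function(config, conc, run_id, source,
                         condition = run_condition(),
                         resp_gain = NULL, rt_stretch = 1,
                         merge_unresolved = FALSE) {
  ids <- names(conc)
  resp <- if (is.null(resp_gain)) rep(1, length(ids)) else resp_gain[ids]
  area <- (config$true_slope[ids] * conc + config$intercept[ids]) * resp *
    ln_noise(length(ids), config$area_cv)
  t_s <- config$base_rt[[internal_reference(config$registry)]]
  rt_base <- t_s + (config$base_rt[ids] - t_s) * rt_stretch
  drift <- ln_noise(1L, config$rt_run_cv)
  rt <- rt_base * drift * ln_noise(length(ids), config$rt_peak_cv)
  pk <- data.frame(rt_min = unname(rt), area = unname(pmax(area, 0)),
                   compound_id = NA_character_, stringsAsFactors = FALSE)
  labels <- data.frame(compound_id = ids, rt_min = unname(rt),
                       stringsAsFactors = FALSE)
  if (merge_unresolved && all(c("cornin", "sweroside") %in% ids)) {
    i <- match(c("cornin", "sweroside"), ids)
    merged_rt <- stats::weighted.mean(rt[i], pk$area[i])
    merged_area <- sum(pk$area[i])
    pk <- pk[-i, , drop = FALSE]
    pk <- rbind(pk, data.frame(rt_min = merged_rt, area = merged_area,
                               compound_id = NA_character_,
                               stringsAsFactors = FALSE))
    labels <- labels[-match(c("cornin", "sweroside"), labels$compound_id), ,
                     drop = FALSE]
  }
  run <- injection_run(run_id, pk, condition = condition, source = source,
                       window_max_min = config$window_max_min)
  attr(run, "true_labels") <- labels
  run
}

#' Generate a standard dilution series
#'
#' Simulates injections of the mixed standard solution at the given dilution
#' factors: concentrations scale exactly by `1/factor`; areas follow the
#' configured response perturbed by lognormal noise; retention times drift
#' as configured.
#'
#' @param config a [generator_config()].
#' @param dilutions dilution factors (>= 1). The default six two-fold steps
#'   reproduce the span of the bundled calibration ranges (stock down to
#'   stock/32).
#' @param replicates injections per level.
#' @param seed RNG seed (defaults to the configuration seed).
#' @return list of class `standard_series`: `levels` (named
#'   [standard_level()] list), `runs` (named `injection_run` list, with true
#'   peak labels attached as attributes), `truth` (generating parameters).
#' @export
generate_standard_series <- function(config, dilutions = c(1, 2, 4, 8, 16, 32),
                                     replicates = 1, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (any(dilutions < 1)) {
    qams_stop("dilution factors must be >= 1", "qams_config_error")
  }
  ids <- config$registry$id
  levels <- lapply(dilutions, function(d) {
    standard_level(sprintf("L%g", d), config$stock[ids] / d,
                   registry = config$registry)
  })
  names(levels) <- vapply(levels, `[[`, "", "level_id")
  runs <- with_seed(seed, {
    out <- list()
    for (lev in levels) {
      for (r in seq_len(replicates)) {
        rid <- sprintf("std_%s_r%d", lev$level_id, r)
        out[[rid]] <- generate_run(config, lev$concentrations, rid,
                                   source = lev$level_id)
      }
    }
    out
  })
  structure(
    list(
      levels = levels, runs = runs,
      truth = list(
        true_slope = config$true_slope, intercept = config$intercept,
        f_true = config$f_true, base_rt = config$base_rt,
        area_cv = config$area_cv, dilutions = dilutions, seed = seed
      )
    ),
    class = "standard_series"
  )
}

#' Generate a ground-truthed sample batch
#'
#' Draws per-sample true contents uniformly within the configured ranges,
#' converts them to solution concentrations through the sample preparation,
#' and simulates one injection per sample. Crude samples lack the processing
#' markers (5-hydroxymethyl-2-furfural and both O-ethylmorronisides), which
#' appear only in processed samples.
#'
#' @param config a [generator_config()].
#' @param n_crude,n_processed sample counts (>= 0).
#' @param seed RNG seed (defaults to the configuration seed).
#' @return list of class `sample_batch`: `runs`, `preps` (named by run id),
#'   `sample_info` (id/type table) and `truth` (`contents` long data frame
#'   of true mg/g plus the generating parameters).
#' @export
generate_sample_batch <- function(config, n_crude = 21, n_processed = 10,
                                  seed = config$seed) {
  stopifnot(inherits(config, "generator_config"),
            n_crude >= 0, n_processed >= 0)
  n <- n_crude + n_processed
  info <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    type = rep(c("crude", "processed"), c(n_crude, n_processed)),
    stringsAsFactors = FALSE
  )
  ranges <- config$content_ranges
  prep <- config$prep
  to_conc <- prep$mass_g * 1000 /
    (prep$extraction_volume_ml * prep$dilution_factor)
  out <- with_seed(seed, {
    runs <- list()
    contents <- list()
    for (i in seq_len(n)) {
      present <- config$registry$id
      if (info$type[i] == "crude") {
        present <- setdiff(present, config$crude_absent)
      }
      rr <- ranges[match(present, ranges$compound_id), ]
      content <- stats::setNames(stats::runif(nrow(rr), rr$lo, rr$hi),
                                 present)
      conc <- content * to_conc
      runs[[info$sample_id[i]]] <- generate_run(
        config, conc, info$sample_id[i], source = info$sample_id[i]
      )
      contents[[i]] <- data.frame(
        sample_id = info$sample_id[i], compound_id = present,
        content_mg_g = unname(content), stringsAsFactors = FALSE
      )
    }
    list(runs = runs, contents = if (n) do.call(rbind, contents)
         else data.frame())
  })
  preps <- stats::setNames(rep(list(prep), n), info$sample_id)
  structure(
    list(
      runs = out$runs, preps = preps, sample_info = info,
      truth = list(
        contents = out$contents, f_true = config$f_true,
        true_slope = config$true_slope, area_cv = config$area_cv,
        seed = seed
      )
    ),
    class = "sample_batch"
  )
}

#' Generate a ruggedness condition panel
#'
#' Simulates the standard dilution series under every combination of the
#' given instruments, columns, temperatures and flow rates. The first
#' combination is the nominal condition (no perturbation); every other
#' condition receives fixed per-compound response and retention
#' perturbations (CVs from the configuration). At 35 degrees C the cornin
#' and sweroside peaks co-elute and are emitted as one merged peak (summed
#' area at the area-weighted retention time), reproducing the known
#' separation failure of the assay at elevated column temperature.
#'
#' @param config a [generator_config()].
#' @param instruments,columns,temperatures,flow_rates factor levels (at
#'   least one each).
#' @param dilutions dilution factors injected under every condition
#'   (default 2, 4, 8).
#' @param seed RNG seed (defaults to the configuration seed).
#' @return list of class `condition_panel`: `groups` (named list: condition
#'   label -> list of runs), `levels`, and `truth` (per-condition
#'   perturbations).
#' @export
generate_condition_panel <- function(config,
                                     instruments = "Instrument A",
                                     columns = "Column A",
                                     temperatures = 30,
                                     flow_rates = 1.0,
                                     dilutions = c(2, 4, 8),
                                     seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!length(instruments) || !length(columns) || !length(temperatures) ||
      !length(flow_rates)) {
    qams_stop("each factor needs at least one level", "qams_config_error")
  }
  grid <- expand.grid(
    instrument = instruments, column = columns,
    temperature_c = temperatures, flow_rate_ml_min = flow_rates,
    stringsAsFactors = FALSE
  )
  ids <- config$registry$id
  levels <- lapply(dilutions, function(d) {
    standard_level(sprintf("L%g", d), config$stock[ids] / d,
                   registry = config$registry)
  })
  names(levels) <- vapply(levels, `[[`, "", "level_id")

  out <- with_seed(seed, {
    groups <- list()
    gains <- list()
    for (g in seq_len(nrow(grid))) {
      cond <- run_condition(grid$instrument[g], grid$column[g],
                            grid$temperature_c[g], grid$flow_rate_ml_min[g])
      label <- sprintf("%s/%s/%gC/%gmL", cond$instrument, cond$column,
                       cond$temperature_c, cond$flow_rate_ml_min)
      nominal <- g == 1L
      resp_gain <- if (nominal) stats::setNames(rep(1, length(ids)), ids)
        else stats::setNames(ln_noise(length(ids),
                                      config$condition_response_cv), ids)
      rt_stretch <- if (nominal) 1 else ln_noise(1L, config$condition_rt_cv)
      merge <- cond$temperature_c >= 35
      runs <- list()
      for (lev in levels) {
        rid <- sprintf("%s_%s", gsub("[^A-Za-z0-9]+", "_", label),
                       lev$level_id)
        runs[[rid]] <- generate_run(config, lev$concentrations, rid,
                                    source = lev$level_id, condition = cond,
                                    resp_gain = resp_gain,
                                    rt_stretch = rt_stretch,
                                    merge_unresolved = merge)
      }
      groups[[label]] <- runs
      gains[[label]] <- list(resp_gain = resp_gain, rt_stretch = rt_stretch,
                             merged = merge)
    }
    list(groups = groups, gains = gains)
  })
  structure(
    list(groups = out$groups, levels = levels,
         truth = list(condition_gains = out$gains, f_true = config$f_true,
                      seed = seed)),
    class = "condition_panel"
  )
}
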