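#' Relative correction factor
#'
#' The RCF of compound *i* against the internal reference *s* is the ratio of
#' their response factors (concentration per unit area):
#' `f_is = (C_i * A_s) / (C_s * A_i)`. It is dimensionless, invariant under
#' any common rescaling of the two areas (detector gain), and exactly 1 for
#' the reference against itself.
#'
#' @param c_i concentration of compound i (ug/mL).
#' @param a_i peak area of compound i.
#' @param c_s concentration of the internal reference.
#' @param a_s peak area of the internal reference.
#' @return numeric RCF (vectorized over its arguments).
#' @examples
#' compute_rcf(124.44, 784605, 415.2, 5912209)
#' @export
compute_rcf <- function(c_i, a_i, c_s, a_s) {
  vals <- c(c_i, a_i, c_s, a_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    qams_stop("all RCF inputs must be finite and > 0", "qams_domain_error")
  }
  (c_i * a_s) / (c_s * a_i)
}

#' Aggregate RCF observations into an RCF table
#'
#' One observation is one injection run's RCF for one compound; observations
#' are never averaged before aggregation. The table reports, per compound,
#' the mean, sample standard deviation (n-1 denominator) and relative
#' standard deviation of its observations.
#'
#' @param observations data frame with columns `compound_id`, `f_is` and
#'   optionally `source` (run/condition identifier).
#' @return data frame of class `rcf_table` with columns `compound_id`, `n`,
#'   `mean`, `sd`, `rsd_percent`; the raw observations are kept in
#'   `attr(, "observations")`.
#' @export
rcf_table <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("compound_id", "f_is") %in% names(observations)))
  obs <- observations[is.finite(observations$f_is), , drop = FALSE]
  if (nrow(obs) == 0L) {
    qams_stop("no finite RCF observations", "qams_domain_error")
  }
  if (any(obs$f_is <= 0)) {
    qams_stop("RCF observations must be > 0", "qams_domain_error")
  }
  ids <- unique(obs$compound_id)
  tab <- do.call(rbind, lapply(ids, function(id) {
    v <- obs$f_is[obs$compound_id == id]
    data.frame(
      compound_id = id,
      n = length(v),
      mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      rsd_percent = if (length(v) > 1L) 100 * stats::sd(v) / mean(v) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  attr(tab, "observations") <- obs
  class(tab) <- c("rcf_table", "data.frame")
  tab
}

#' @export
print.rcf_table <- function(x, ...) {
  cat(sprintf("<rcf_table> %d compounds\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean RCFs of an RCF table as a named vector
#' @param x an `rcf_table`.
#' @return named numeric vector of per-compound mean RCFs.
#' @export
rcf_means <- function(x) {
  stats::setNames(x$mean, x$compound_id)
}

#' RCFs from a dilution series of mixed standards
#'
#' Computes one RCF observation per (compound, injection run) from located
#' standard injections, pairing each run with its standard level via the
#' run's `source`, then aggregates with [rcf_table()]. Runs whose internal
#' reference peak was not located are excluded with a warning, since no RCF
#' can be anchored in them.
#'
#' @param runs list of located `injection_run` (peaks carry `compound_id`).
#' @param levels list of `standard_level`, named by level id, or unnamed (in
#'   which case the level ids are used).
#' @param registry a `compound_registry`.
#' @return an [rcf_table()] over the non-reference compounds.
#' @export
rcf_from_dilution_series <- function(runs, levels, registry) {
  validate_registry(registry)
  ref <- internal_reference(registry)
  if (is.null(names(levels))) {
    names(levels) <- vapply(levels, `[[`, "", "level_id")
  }
  obs <- list()
  for (run in runs) {
    lev <- levels[[run$source]]
    if (is.null(lev)) {
      qams_stop(
        sprintf("run '%s' references unknown standard level '%s'",
                run$run_id, run$source),
        "qams_config_error"
      )
    }
    pk <- run$peaks
    s_row <- which(pk$compound_id %in% ref)
    if (length(s_row) != 1L) {
      warning(sprintf(
        "run '%s' excluded: internal reference peak not located", run$run_id
      ), call. = FALSE)
      next
    }
    a_s <- pk$area[s_row]
    c_s <- lev$concentrations[[ref]]
    targets <- which(!is.na(pk$compound_id) & pk$compound_id != ref &
                       pk$compound_id %in% names(lev$concentrations))
    if (!length(targets)) next
    obs[[length(obs) + 1L]] <- data.frame(
      compound_id = pk$compound_id[targets],
      f_is = vapply(targets, function(i) {
        compute_rcf(lev$concentrations[[pk$compound_id[i]]], pk$area[i],
                    c_s, a_s)
      }, numeric(1)),
      source = run$run_id,
      stringsAsFactors = FALSE
    )
  }
  if (!length(obs)) {
    qams_stop("no usable runs in dilution series", "qams_domain_error")
  }
  rcf_table(do.call(rbind, obs))
}

#' Summarize per-condition RCF values into a ruggedness report
#'
#' Takes one RCF value per (condition, compound) — e.g. per-condition means
#' from replicate injections — and reports the overall mean, sample SD, RSD
#' and a pass flag against an RSD threshold. Missing cells (conditions where
#' a compound's peak was not separated/detected) are excluded from the mean
#' and SD, never imputed.
#'
#' @param values data frame with columns `condition`, `compound_id`, `f_is`
#'   (NA marks a not-detected cell).
#' @param threshold_percent RSD acceptance threshold (default 5).
#' @return data frame of class `ruggedness_summary` with per-compound
#'   `n_conditions`, `mean`, `sd`, `rsd_percent`, `pass`.
#' @export
ruggedness_summary <- function(values, threshold_percent = 5) {
  stopifnot(is.data.frame(values),
            all(c("condition", "compound_id", "f_is") %in% names(values)))
  if (length(unique(values$condition)) < 2L) {
    qams_stop("ruggedness needs at least 2 condition groups",
              "qams_config_error")
  }
  ids <- unique(values$compound_id)
  tab <- do.call(rbind, lapply(ids, function(id) {
    v <- values$f_is[values$compound_id == id]
    v <- v[is.finite(v)]
    rsd_pc <- if (length(v) > 1L) 100 * stats::sd(v) / mean(v) else NA_real_
    data.frame(
      compound_id = id,
      n_conditions = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      rsd_percent = rsd_pc,
      pass = !is.na(rsd_pc) & rsd_pc <= threshold_percent,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  attr(tab, "threshold_percent") <- threshold_percent
  attr(tab, "values") <- values
  class(tab) <- c("ruggedness_summary", "data.frame")
  tab
}

#' @export
print.ruggedness_summary <- function(x, ...) {
  cat(sprintf(
    "<ruggedness_summary> RSD threshold %.3g%%, %d/%d compounds pass\n",
    attr(x, "threshold_percent"), sum(x$pass), nrow(x)
  ))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Ruggedness panel across chromatographic conditions
#'
#' Recomputes RCFs per condition group from located standard injections,
#' takes the per-condition mean per compound, and summarizes across
#' conditions with [ruggedness_summary()]. Conditions where a compound was
#' not located (e.g. an unseparated peak pair) contribute a not-detected cell
#' that is excluded from the overall mean.
#'
#' @param groups named list: condition label -> list of located
#'   `injection_run`.
#' @param levels list of `standard_level` shared by all groups.
#' @param registry a `compound_registry`.
#' @param threshold_percent RSD acceptance threshold (default 5).
#' @return list of class `ruggedness_panel` with elements
#'   `condition_means` (long data frame) and `summary` (a
#'   `ruggedness_summary`).
#' @export
ruggedness_panel <- function(groups, levels, registry, threshold_percent = 5) {
  validate_registry(registry)
  if (length(groups) < 2L) {
    qams_stop("ruggedness needs at least 2 condition groups",
              "qams_config_error")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    qams_stop("groups must be a named list of conditions", "qams_config_error")
  }
  empty <- names(groups)[vapply(groups, length, 0L) == 0L]
  if (length(empty)) {
    qams_stop(paste0("empty condition group(s): ",
                     paste(empty, collapse = ", ")),
              "qams_config_error")
  }
  targets <- setdiff(registry$id, internal_reference(registry))
  rows <- list()
  for (cond in names(groups)) {
    tab <- rcf_from_dilution_series(groups[[cond]], levels, registry)
    m <- rcf_means(tab)
    rows[[cond]] <- data.frame(
      condition = cond,
      compound_id = targets,
      f_is = unname(m[targets]),
      stringsAsFactors = FALSE
    )
  }
  condition_means <- do.call(rbind, rows)
  rownames(condition_means) <- NULL
  structure(
    list(
      condition_means = condition_means,
      summary = ruggedness_summary(condition_means, threshold_percent)
    ),
    class = "ruggedness_panel"
  )
}

#' @export
print.ruggedness_panel <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Write an RCF table to CSV
#'
#' Layout mirrors the usual published presentation: one row per observation
#' source (solution), one column per compound, plus trailing `Mean` and
#' `RSD%` rows.
#'
#' @param x an `rcf_table`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_rcf_table <- function(x, path) {
  obs <- attr(x, "observations")
  ids <- x$compound_id
  srcs <- unique(obs$source %||% seq_len(nrow(obs)))
  wide <- do.call(rbind, lapply(srcs, function(s) {
    row <- vapply(ids, function(id) {
      v <- obs$f_is[obs$source == s & obs$compound_id == id]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    data.frame(solution = s, t(row), check.names = FALSE)
  }))
  wide <- rbind(
    wide,
    data.frame(solution = "Mean", t(stats::setNames(x$mean, ids)),
               check.names = FALSE),
    data.frame(solution = "RSD%", t(stats::setNames(x$rsd_percent, ids)),
               check.names = FALSE)
  )
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  invisible(path)
}
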