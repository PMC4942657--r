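#' Relative standard deviation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation — the
#' convention under which published RCF dispersion rows reproduce. Scale
#' invariant: `rsd(k * v) == rsd(v)` for `k > 0`.
#'
#' @param values numeric vector, at least 2 values with positive mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    qams_stop("rsd needs at least 2 values", "qams_domain_error")
  }
  m <- mean(values)
  if (m <= 0) {
    qams_stop("rsd needs a positive mean", "qams_domain_error")
  }
  100 * stats::sd(values) / m
}

#' Spike recovery
#'
#' `100 * (detected - original) / added`: the percentage of a known added
#' analyte amount that is found again on re-analysis. Invariant under a
#' common rescaling of the three masses.
#'
#' @param original analyte amount in the unspiked sample (mg).
#' @param added spiked amount (mg, > 0).
#' @param detected total amount found after spiking (mg, >= 0).
#' @return recovery in percent (vectorized).
#' @examples
#' recovery(0.12, 0.114, 0.239) # ~104.4%
#' @export
recovery <- function(original, added, detected) {
  if (any(!is.finite(c(original, added, detected)))) {
    qams_stop("recovery inputs must be finite", "qams_domain_error")
  }
  if (any(added <= 0)) {
    qams_stop("added amount must be > 0", "qams_domain_error")
  }
  if (any(detected < 0) || any(original < 0)) {
    qams_stop("amounts must be >= 0", "qams_domain_error")
  }
  100 * (detected - original) / added
}

#' Method-validation RSD report
#'
#' Per-compound RSD with a pass/fail flag, for the three classical
#' repeated-measurement designs: precision (consecutive injections of one
#' solution), repeatability (independently prepared samples) and stability
#' (one solution re-analyzed over a time grid). The input may be peak areas
#' or computed contents; `value_type` records which.
#'
#' @param groups named list: compound id -> numeric vector of repeated
#'   measurements.
#' @param kind `"precision"`, `"repeatability"` or `"stability"`.
#' @param threshold_percent RSD acceptance threshold (default 5).
#' @param time_grid for stability reports, the analysis times (hours).
#' @param value_type `"area"` or `"content"`.
#' @return data frame of class `validation_report` with `compound_id`, `n`,
#'   `mean`, `sd`, `rsd_percent`, `pass`; compounds with fewer than 2 values
#'   are skipped with a warning.
#' @export
validation_report <- function(groups,
                              kind = c("precision", "repeatability",
                                       "stability"),
                              threshold_percent = 5, time_grid = NULL,
                              value_type = c("area", "content")) {
  kind <- match.arg(kind)
  value_type <- match.arg(value_type)
  if (!length(groups) || is.null(names(groups))) {
    qams_stop("groups must be a non-empty named list", "qams_config_error")
  }
  if (kind == "stability" && !is.null(time_grid)) {
    lens <- vapply(groups, length, 0L)
    if (any(lens > 1L & lens != length(time_grid))) {
      qams_stop("stability measurements do not match the time grid",
                "qams_config_error")
    }
  }
  rows <- list()
  for (id in names(groups)) {
    v <- groups[[id]][is.finite(groups[[id]])]
    if (length(v) < 2L) {
      warning(sprintf("compound '%s' skipped: fewer than 2 values", id),
              call. = FALSE)
      next
    }
    r <- rsd(v)
    rows[[id]] <- data.frame(
      compound_id = id, n = length(v), mean = mean(v), sd = stats::sd(v),
      rsd_percent = r, pass = r <= threshold_percent,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    qams_stop("no compound had 2 or more values", "qams_domain_error")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  attr(out, "threshold_percent") <- threshold_percent
  attr(out, "value_type") <- value_type
  if (kind == "stability") attr(out, "time_grid") <- time_grid
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %s (%s values), RSD threshold %.3g%%: %d/%d pass\n",
    attr(x, "kind"), attr(x, "value_type"), attr(x, "threshold_percent"),
    sum(x$pass), nrow(x)
  ))
  if (!is.null(attr(x, "time_grid"))) {
    cat("time grid (h):", paste(attr(x, "time_grid"), collapse = ", "), "\n")
  }
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
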