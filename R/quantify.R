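#' External-standard concentrations of a located run
#'
#' Inverts each located compound's own calibration curve. The classical
#' multi-standard route: every analyte needs its own curve.
#'
#' @param run a located `injection_run` (peaks labeled with compound ids).
#' @param curves named list of `calibration_curve` per compound.
#' @param registry optional `compound_registry`; when given, compounds with
#'   no located peak are reported as not-detected rows.
#' @return data frame with columns `compound_id`, `area`,
#'   `concentration_ug_ml`, `in_range`, `flag`, `not_detected`.
#' @export
esm_concentration <- function(run, curves, registry = NULL) {
  stopifnot(inherits(run, "injection_run"))
  pk <- run$peaks
  located <- pk[!is.na(pk$compound_id), , drop = FALSE]
  missing_curve <- setdiff(located$compound_id, names(curves))
  if (length(missing_curve)) {
    qams_stop(
      paste0("no calibration curve for located compound(s): ",
             paste(missing_curve, collapse = ", ")),
      "qams_config_error"
    )
  }
  rows <- lapply(seq_len(nrow(located)), function(i) {
    inv <- invert_calibration(curves[[located$compound_id[i]]],
                              located$area[i])
    data.frame(
      compound_id = located$compound_id[i], area = located$area[i],
      concentration_ug_ml = inv$concentration_ug_ml,
      in_range = inv$in_range, flag = inv$flag, not_detected = FALSE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(registry)) {
    absent <- setdiff(registry$id, out$compound_id)
    if (length(absent)) {
      out <- rbind(out, data.frame(
        compound_id = absent, area = NA_real_,
        concentration_ug_ml = NA_real_, in_range = NA, flag = "not_detected",
        not_detected = TRUE, stringsAsFactors = FALSE
      ))
    }
    out <- out[match(registry$id, out$compound_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Single-marker (QAMS) concentrations of a located run
#'
#' Only the internal reference is calibrated. Its concentration `C_s` comes
#' from its own curve; every other analyte is quantified through its mean
#' relative correction factor:
#' `C_i = f_is * A_i * C_s / A_s`.
#'
#' @param run a located `injection_run`.
#' @param rcf an `rcf_table` (its per-compound means are used — the method's
#'   premise is that the RCF is a constant of proportionality) or a named
#'   numeric vector of RCFs.
#' @param reference_curve `calibration_curve` of the internal reference.
#' @param registry optional registry, as in [esm_concentration()].
#' @return data frame with the same columns as [esm_concentration()].
#' @export
qams_concentration <- function(run, rcf, reference_curve, registry = NULL) {
  stopifnot(inherits(run, "injection_run"),
            inherits(reference_curve, "calibration_curve"))
  f_mean <- if (inherits(rcf, "rcf_table")) rcf_means(rcf) else rcf
  ref <- reference_curve$compound_id
  pk <- run$peaks
  s_row <- which(pk$compound_id %in% ref)
  if (length(s_row) != 1L) {
    qams_stop(
      sprintf("internal reference peak missing in run '%s': QAMS impossible",
              run$run_id),
      "qams_anchor_error"
    )
  }
  a_s <- pk$area[s_row]
  inv_s <- invert_calibration(reference_curve, a_s)
  c_s <- inv_s$concentration_ug_ml

  located <- pk[!is.na(pk$compound_id) & pk$compound_id != ref, , drop = FALSE]
  no_f <- setdiff(located$compound_id, names(f_mean))
  if (length(no_f)) {
    qams_stop(
      paste0("no RCF for located compound(s): ", paste(no_f, collapse = ", ")),
      "qams_config_error"
    )
  }
  out <- data.frame(
    compound_id = c(ref, located$compound_id),
    area = c(a_s, located$area),
    concentration_ug_ml = c(
      c_s,
      unname(f_mean[located$compound_id]) * located$area * c_s / a_s
    ),
    stringsAsFactors = FALSE
  )
  out$in_range <- c(inv_s$in_range, rep(NA, nrow(located)))
  out$flag <- c(inv_s$flag, rep("ok", nrow(located)))
  out$flag[out$concentration_ug_ml < 0] <- "negative"
  out$not_detected <- FALSE
  if (!is.null(registry)) {
    absent <- setdiff(registry$id, out$compound_id)
    if (length(absent)) {
      out <- rbind(out, data.frame(
        compound_id = absent, area = NA_real_,
        concentration_ug_ml = NA_real_, in_range = NA, flag = "not_detected",
        not_detected = TRUE, stringsAsFactors = FALSE
      ))
    }
    out <- out[match(registry$id, out$compound_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Convert a solution concentration to herb content
#'
#' `content (mg/g) = c (ug/mL) * V (mL) * dilution / (m (g) * 1000)`.
#' Linear in concentration, volume and dilution; inverse-linear in mass.
#'
#' @param concentration_ug_ml solution concentration(s), ug/mL.
#' @param prep a [sample_prep()].
#' @return content in mg per g of herb (vectorized).
#' @examples
#' content_from_concentration(292.8, sample_prep(2, 50, 1)) # 7.32 mg/g
#' @export
content_from_concentration <- function(concentration_ug_ml, prep) {
  stopifnot(inherits(prep, "sample_prep"))
  concentration_ug_ml * prep$extraction_volume_ml * prep$dilution_factor /
    (prep$mass_g * 1000)
}

#' Build content records for one sample
#'
#' @param sample_id sample identifier.
#' @param concentrations output of [esm_concentration()] or
#'   [qams_concentration()].
#' @param method `"ESM"` or `"QAMS"`.
#' @param prep the sample's [sample_prep()].
#' @return data frame with columns `sample_id`, `compound_id`, `method`,
#'   `content_mg_g`, `flag`, `not_detected`.
#' @export
content_records <- function(sample_id, concentrations, method, prep) {
  method <- match.arg(method, c("ESM", "QAMS"))
  data.frame(
    sample_id = sample_id,
    compound_id = concentrations$compound_id,
    method = method,
    content_mg_g = content_from_concentration(
      concentrations$concentration_ug_ml, prep
    ),
    flag = concentrations$flag,
    not_detected = concentrations$not_detected,
    stringsAsFactors = FALSE
  )
}

#' Compare single-marker against external-standard contents
#'
#' Pairs records on (sample, compound), drops pairs where either method
#' reports not-detected, and summarizes per compound: mean and maximum
#' relative difference `(QAMS - ESM) / ESM` and a paired two-sided test
#' (t-test by default, Wilcoxon signed-rank as an option). The overall
#' "no significant difference" flag requires every per-compound p-value to
#' exceed `alpha`. Compounds with fewer than two pairs are skipped with a
#' warning.
#'
#' @param esm,qams data frames with columns `sample_id`, `compound_id`,
#'   `content_mg_g` and optionally `not_detected` (NA content also counts as
#'   not detected), e.g. from [content_records()].
#' @param test `"t"` or `"wilcoxon"`.
#' @param alpha significance level for the overall flag (default 0.05).
#' @return list of class `qams_comparison`: `by_compound` (per-compound
#'   summary data frame), `agreement` (logical overall flag), `n_samples`
#'   (number of distinct paired samples), `test`, `alpha`.
#' @export
compare_methods <- function(esm, qams, test = c("t", "wilcoxon"),
                            alpha = 0.05) {
  test <- match.arg(test)
  clean <- function(d) {
    nd <- if (!is.null(d$not_detected)) d$not_detected else FALSE
    d <- d[!nd & !is.na(d$content_mg_g), c("sample_id", "compound_id",
                                           "content_mg_g")]
    d
  }
  pairs <- merge(clean(esm), clean(qams),
                 by = c("sample_id", "compound_id"),
                 suffixes = c("_esm", "_qams"))
  if (!nrow(pairs)) {
    qams_stop("no pairable (sample, compound) records", "qams_domain_error")
  }
  by_compound <- list()
  for (id in unique(pairs$compound_id)) {
    p <- pairs[pairs$compound_id == id, , drop = FALSE]
    if (nrow(p) < 2L) {
      warning(sprintf("compound '%s' skipped: fewer than 2 pairs", id),
              call. = FALSE)
      next
    }
    rel <- (p$content_mg_g_qams - p$content_mg_g_esm) / p$content_mg_g_esm
    diffs <- p$content_mg_g_qams - p$content_mg_g_esm
    # differences at floating-point noise are differences in representation,
    # not in measurement
    negligible <- abs(diffs) <=
      1e-9 * pmax(abs(p$content_mg_g_esm), .Machine$double.xmin)
    ht <- if (all(negligible)) {
      # degenerate: identical paired values carry no evidence of difference
      list(statistic = 0, p.value = 1)
    } else if (stats::sd(diffs) == 0) {
      # a constant nonzero shift is a systematic difference by definition
      list(statistic = sign(diffs[1]) * Inf, p.value = 0)
    } else if (test == "t") {
      stats::t.test(p$content_mg_g_qams, p$content_mg_g_esm, paired = TRUE)
    } else {
      suppressWarnings(
        stats::wilcox.test(p$content_mg_g_qams, p$content_mg_g_esm,
                           paired = TRUE, exact = FALSE)
      )
    }
    by_compound[[id]] <- data.frame(
      compound_id = id,
      n_pairs = nrow(p),
      mean_rel_diff = mean(rel),
      max_abs_rel_diff = max(abs(rel)),
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      stringsAsFactors = FALSE
    )
  }
  if (!length(by_compound)) {
    qams_stop("no compound had 2 or more pairs", "qams_domain_error")
  }
  by_compound <- do.call(rbind, by_compound)
  rownames(by_compound) <- NULL
  structure(
    list(
      by_compound = by_compound,
      agreement = all(by_compound$p_value > alpha),
      n_samples = length(unique(pairs$sample_id)),
      test = test,
      alpha = alpha
    ),
    class = "qams_comparison"
  )
}

#' @export
print.qams_comparison <- function(x, ...) {
  cat(sprintf(
    "<qams_comparison> %d samples, paired %s-test, alpha = %g\n",
    x$n_samples, x$test, x$alpha
  ))
  print.data.frame(x$by_compound, row.names = FALSE, digits = 3)
  cat(if (x$agreement) "No significant difference between methods.\n"
      else "Significant difference detected for at least one compound.\n")
  invisible(x)
}
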