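#' Relative retention time
#'
#' Retention time of a compound divided by that of the internal reference,
#' `rrt = t_i / t_s`. A dimensionless peak identifier that survives uniform
#' retention drift, so peaks can be located without a standard for every
#' analyte.
#'
#' @param t_i retention time of the analyte, minutes.
#' @param t_s retention time of the internal reference, minutes.
#' @return numeric relative retention time (vectorized).
#' @export
relative_retention <- function(t_i, t_s) {
  if (any(!is.finite(c(t_i, t_s))) || any(c(t_i, t_s) <= 0)) {
    qams_stop("retention times must be finite and > 0", "qams_domain_error")
  }
  t_i / t_s
}

#' Relative retention time reference
#'
#' Expected RRT per compound with a matching tolerance (percent relative
#' deviation). Per-compound tolerances are allowed since observed RRT
#' dispersions differ between early and late eluters.
#'
#' @param compound_id compound ids (excluding the internal reference, whose
#'   RRT is 1 by definition and which is located separately as the anchor).
#' @param expected_rrt expected relative retention times (> 0).
#' @param tolerance_percent matching tolerance, recycled to all compounds
#'   (default 5).
#' @return data frame of class `rrt_reference`.
#' @export
rrt_reference <- function(compound_id, expected_rrt, tolerance_percent = 5) {
  if (any(!is.finite(expected_rrt)) || any(expected_rrt <= 0)) {
    qams_stop("expected_rrt must be finite and > 0", "qams_domain_error")
  }
  ref <- data.frame(
    compound_id = as.character(compound_id),
    expected_rrt = as.numeric(expected_rrt),
    tolerance_percent = rep_len(tolerance_percent, length(compound_id)),
    stringsAsFactors = FALSE
  )
  ref <- ref[order(ref$expected_rrt), , drop = FALSE]
  rownames(ref) <- NULL
  class(ref) <- c("rrt_reference", "data.frame")
  ref
}

#' Locate the internal reference (anchor) peak
#'
#' Returns the largest-area peak whose retention time lies within
#' `window_percent` of the expected anchor retention time. Area, not
#' proximity, breaks ties inside the window: the internal reference is
#' chosen to be abundant, so the dominant peak of its region is the anchor.
#'
#' @param run an `injection_run`.
#' @param expected_rt expected anchor retention time, minutes (instrument
#'   configuration, not a published constant — absolute retention times are
#'   system specific).
#' @param window_percent half-width of the search window as a percentage of
#'   `expected_rt` (default 5).
#' @return one-row data frame (`rt_min`, `area`, `peak`) where `peak` is the
#'   row index in `run$peaks`.
#' @export
locate_internal_reference <- function(run, expected_rt, window_percent = 5) {
  stopifnot(inherits(run, "injection_run"))
  if (nrow(run$peaks) == 0L) {
    qams_stop("run has no peaks", "qams_anchor_error")
  }
  if (!is_scalar_number(expected_rt) || expected_rt <= 0) {
    qams_stop("expected_rt must be > 0", "qams_domain_error")
  }
  dev <- abs(run$peaks$rt_min - expected_rt) / expected_rt
  in_win <- which(dev <= window_percent / 100)
  if (!length(in_win)) {
    qams_stop(
      sprintf(
        "internal reference anchor not found within %.3g%% of %.4g min in run '%s'",
        window_percent, expected_rt, run$run_id
      ),
      "qams_anchor_error"
    )
  }
  best <- in_win[which.max(run$peaks$area[in_win])]
  data.frame(rt_min = run$peaks$rt_min[best], area = run$peaks$area[best],
             peak = best)
}

#' Assign peaks to compounds by relative retention time
#'
#' For every compound in the reference, candidate peaks are those whose
#' observed RRT against the anchor deviates from the expected RRT by at most
#' the compound's tolerance. Candidate (compound, peak) pairs are then
#' assigned greedily in order of ascending relative deviation with per-peak
#' exclusivity, so a peak claimed by a closer match is unavailable to a worse
#' one; compounds left without a peak are reported not-detected. Two
#' compounds claiming the same peak at exactly equal deviation is an
#' ambiguity error — silent misassignment is worse than a failure.
#'
#' @param run an `injection_run`.
#' @param anchor anchor peak from [locate_internal_reference()].
#' @param reference an [rrt_reference()].
#' @return data frame of class `peak_assignment`: one row per reference
#'   compound with `compound_id`, `rt_min`, `area`, `rrt`, `rel_dev`,
#'   `not_detected`; the anchor is stored as `attr(, "anchor")`.
#' @export
locate_peaks <- function(run, anchor, reference) {
  stopifnot(inherits(run, "injection_run"), inherits(reference, "rrt_reference"))
  if (!anchor$peak %in% seq_len(nrow(run$peaks)) ||
      run$peaks$rt_min[anchor$peak] != anchor$rt_min) {
    qams_stop("anchor does not belong to this run", "qams_domain_error")
  }
  pk <- run$peaks
  cand_peaks <- setdiff(seq_len(nrow(pk)), anchor$peak)
  rrt_obs <- pk$rt_min / anchor$rt_min

  pairs <- do.call(rbind, lapply(seq_len(nrow(reference)), function(i) {
    dev <- abs(rrt_obs[cand_peaks] - reference$expected_rrt[i]) /
      reference$expected_rrt[i]
    ok <- dev <= reference$tolerance_percent[i] / 100
    if (!any(ok)) return(NULL)
    data.frame(ci = i, peak = cand_peaks[ok], rel_dev = dev[ok])
  }))

  assigned_peak <- rep(NA_integer_, nrow(reference))
  if (!is.null(pairs) && nrow(pairs)) {
    # ascending deviation; expected-rrt order only as a deterministic
    # iteration order among distinct deviations
    pairs <- pairs[order(pairs$rel_dev, reference$expected_rrt[pairs$ci]), ,
                   drop = FALSE]
    peak_taken <- rep(FALSE, nrow(pk))
    for (k in seq_len(nrow(pairs))) {
      ci <- pairs$ci[k]
      p <- pairs$peak[k]
      if (!is.na(assigned_peak[ci]) || peak_taken[p]) next
      rivals <- pairs$ci[pairs$peak == p & is.na(assigned_peak[pairs$ci]) &
                           abs(pairs$rel_dev - pairs$rel_dev[k]) < 1e-12]
      rivals <- setdiff(unique(rivals), ci)
      if (length(rivals)) {
        qams_stop(
          sprintf(
            "ambiguous assignment: compounds %s claim the peak at %.4g min with equal deviation",
            paste(sQuote(reference$compound_id[c(ci, rivals)]), collapse = ", "),
            pk$rt_min[p]
          ),
          "qams_ambiguity_error"
        )
      }
      assigned_peak[ci] <- p
      peak_taken[p] <- TRUE
    }
  }

  out <- data.frame(
    compound_id = reference$compound_id,
    rt_min = ifelse(is.na(assigned_peak), NA_real_, pk$rt_min[assigned_peak]),
    area = ifelse(is.na(assigned_peak), NA_real_, pk$area[assigned_peak]),
    rrt = ifelse(is.na(assigned_peak), NA_real_, rrt_obs[assigned_peak]),
    rel_dev = ifelse(
      is.na(assigned_peak), NA_real_,
      abs(rrt_obs[assigned_peak] - reference$expected_rrt) /
        reference$expected_rrt
    ),
    not_detected = is.na(assigned_peak),
    stringsAsFactors = FALSE
  )
  attr(out, "anchor") <- anchor
  class(out) <- c("peak_assignment", "data.frame")
  out
}

#' Locate anchor and targets, returning a labeled run
#'
#' Convenience wrapper: finds the internal reference anchor, assigns the
#' remaining peaks by RRT, and returns the run with `compound_id` filled in
#' on the matched peaks (others stay NA).
#'
#' @inheritParams locate_internal_reference
#' @param reference an [rrt_reference()] for the non-reference compounds.
#' @param registry a `compound_registry` (supplies the internal reference id).
#' @return the `injection_run` with labeled peaks; the assignment table is
#'   attached as `attr(, "assignment")`.
#' @export
assign_peaks <- function(run, registry, reference, expected_rt,
                         window_percent = 5) {
  validate_registry(registry)
  anchor <- locate_internal_reference(run, expected_rt, window_percent)
  assignment <- locate_peaks(run, anchor, reference)
  run$peaks$compound_id <- NA_character_
  run$peaks$compound_id[anchor$peak] <- internal_reference(registry)
  hit <- !assignment$not_detected
  idx <- match(assignment$rt_min[hit], run$peaks$rt_min)
  run$peaks$compound_id[idx] <- assignment$compound_id[hit]
  attr(run, "assignment") <- assignment
  run
}
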