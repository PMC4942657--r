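test_that("relative retention is a positive ratio with reciprocal symmetry", {
  expect_equal(relative_retention(31, 31), 1)
  expect_equal(relative_retention(49.6, 31.0), 1.6, tolerance = 1e-3)
  set.seed(9)
  for (i in 1:20) {
    a <- stats::runif(1, 0.1, 50); b <- stats::runif(1, 0.1, 50)
    expect_equal(relative_retention(a, b) * relative_retention(b, a), 1,
                 tolerance = 1e-12)
  }
  expect_error(relative_retention(-1, 2), class = "qams_domain_error")
  expect_error(relative_retention(1, 0), class = "qams_domain_error")
})

test_that("the anchor is the largest peak inside the search window", {
  run <- make_run(31, 100)
  expect_equal(locate_internal_reference(run, 31)$rt_min, 31)

  two <- make_run(c(30.5, 31.2), c(10, 1000))
  expect_equal(locate_internal_reference(two, 31)$area, 1000)

  off <- make_run(c(10, 20), c(1, 1))
  expect_error(locate_internal_reference(off, 31),
               class = "qams_anchor_error")

  # drifted anchor: +2% retention drift on a synthetic run is still found
  cfg <- generator_config(seed = 3, rt_run_cv = 0, rt_peak_cv = 0)
  run3 <- quiet_series(cfg, dilutions = 1, seed = 3)$runs[[1]]
  run3$peaks$rt_min <- run3$peaks$rt_min * 1.02
  anchor <- locate_internal_reference(run3, 31)
  expect_equal(anchor$rt_min, 31 * 1.02, tolerance = 1e-9)
})

test_that("peaks at the reference RRTs are all assigned and absences reported", {
  ref <- default_rrt_reference()
  t_s <- 31
  run <- make_run(c(ref$expected_rrt, 1) * t_s,
                  c(seq(1000, 10000, length.out = 10), 50000))
  anchor <- locate_internal_reference(run, t_s)
  got <- locate_peaks(run, anchor, ref)
  expect_false(any(got$not_detected))
  expect_equal(got$rrt, ref$expected_rrt, tolerance = 1e-12)

  # crude-style run: no peak near the 5-HMF position
  no_hmf <- ref$expected_rrt[ref$compound_id != "hmf"]
  run2 <- make_run(c(no_hmf, 1) * t_s, c(rep(1000, 9), 50000))
  got2 <- locate_peaks(run2, locate_internal_reference(run2, t_s), ref)
  expect_true(got2$not_detected[got2$compound_id == "hmf"])
  expect_equal(sum(got2$not_detected), 1L)
})

test_that("assignment is invariant under uniform rescaling of the time axis", {
  ref <- default_rrt_reference()
  rts <- c(ref$expected_rrt * 1.003, 1) * 31
  run <- make_run(rts, seq_along(rts) * 100)
  base <- locate_peaks(run, locate_internal_reference(run, 31), ref)
  for (k in c(0.5, 1.3)) {
    scaled <- make_run(rts * k, seq_along(rts) * 100, window = 80)
    got <- locate_peaks(scaled, locate_internal_reference(scaled, 31 * k),
                        ref)
    expect_identical(got$not_detected, base$not_detected)
    expect_equal(got$rrt, base$rrt, tolerance = 1e-12)
  }
})

test_that("a merged co-eluting pair is assigned to exactly one compound", {
  ref <- default_rrt_reference()
  keep <- !(ref$compound_id %in% c("cornin", "sweroside"))
  # single unresolved peak between the cornin and sweroside positions
  rts <- c(ref$expected_rrt[keep], 0.97, 1) * 31
  run <- make_run(rts, c(rep(1000, length(rts) - 1), 50000))
  got <- locate_peaks(run, locate_internal_reference(run, 31), ref)
  pair <- got[got$compound_id %in% c("cornin", "sweroside"), ]
  expect_equal(sum(pair$not_detected), 1L)
  # nearest by relative deviation wins: 0.97 is relatively closer to 0.98
  expect_false(pair$not_detected[pair$compound_id == "sweroside"])
})

test_that("an exact deviation tie raises an ambiguity error naming both compounds", {
  ref <- rrt_reference(c("early", "late"), c(0.9, 1.1),
                       tolerance_percent = 15)
  # harmonic mean of the two expectations: equal relative deviation
  tie <- 2 * 0.9 * 1.1 / (0.9 + 1.1)
  run <- make_run(c(tie, 1) * 30, c(100, 1000))
  err <- expect_error(
    locate_peaks(run, locate_internal_reference(run, 30), ref),
    class = "qams_ambiguity_error"
  )
  expect_match(conditionMessage(err), "early")
  expect_match(conditionMessage(err), "late")
})

test_that("generator labels are recovered when jitter is below half the RRT gap", {
  cfg <- generator_config(seed = 13)
  batch <- generate_sample_batch(cfg, 10, 10, seed = 13)
  reg <- fructus_corni_registry()
  ref <- default_rrt_reference()
  for (run in batch$runs) {
    located <- assign_peaks(run, reg, ref, expected_rt = 31)
    truth <- attr(run, "true_labels")
    pk <- located$peaks[!is.na(located$peaks$compound_id), ]
    expect_identical(
      pk$compound_id,
      truth$compound_id[match(pk$rt_min, truth$rt_min)]
    )
    expect_equal(nrow(pk), nrow(truth))
  }
})
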