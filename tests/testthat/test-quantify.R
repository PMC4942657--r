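test_that("external-standard inversion is algebraic and propagates absences", {
  curves <- reference_curves()
  run <- make_run(c(31), c(14317 * 292.8 - 32209), ids = "loganin")
  reg <- fructus_corni_registry()
  got <- esm_concentration(run, curves, reg)
  expect_equal(
    got$concentration_ug_ml[got$compound_id == "loganin"], 292.8,
    tolerance = 1e-9
  )
  expect_true(got$not_detected[got$compound_id == "hmf"])
  expect_identical(got$flag[got$compound_id == "hmf"], "not_detected")

  expect_error(esm_concentration(run, curves["gallic_acid"]),
               class = "qams_config_error")
})

test_that("the single-marker formula reduces to the anchor when f = 1 and areas match", {
  curve <- calibration_curve("loganin", 14317, -32209, range = c(12.97, 415.2))
  a <- 14317 * 300 - 32209
  run <- make_run(c(20, 31), c(a, a), ids = c("x", "loganin"))
  got <- qams_concentration(run, c(x = 1), curve)
  c_s <- got$concentration_ug_ml[got$compound_id == "loganin"]
  c_x <- got$concentration_ug_ml[got$compound_id == "x"]
  expect_equal(c_x, c_s, tolerance = 1e-12)
  expect_equal(c_s, 300, tolerance = 1e-9)

  no_anchor <- make_run(20, a, ids = "x")
  expect_error(qams_concentration(no_anchor, c(x = 1), curve),
               class = "qams_anchor_error")
  expect_error(qams_concentration(run, c(y = 1), curve),
               class = "qams_config_error")
})

test_that("QAMS and ESM coincide exactly for slope-ratio RCFs and zero intercepts", {
  set.seed(99)
  for (i in 1:10) {
    k_s <- stats::runif(1, 1e3, 2e4)
    k_x <- stats::runif(1, 1e3, 2e4)
    a_x <- stats::runif(1, 1e3, 1e6)
    a_s <- stats::runif(1, 1e3, 1e6)
    run <- make_run(c(20, 31), c(a_x, a_s), ids = c("x", "loganin"))
    curves <- list(
      x = calibration_curve("x", k_x, 0),
      loganin = calibration_curve("loganin", k_s, 0)
    )
    esm <- esm_concentration(run, curves)
    qam <- qams_concentration(run, c(x = k_s / k_x), curves$loganin)
    expect_equal(
      qam$concentration_ug_ml[qam$compound_id == "x"],
      esm$concentration_ug_ml[esm$compound_id == "x"],
      tolerance = 1e-12
    )
  }
})

test_that("content conversion is linear in its prep factors", {
  expect_equal(content_from_concentration(292.8, sample_prep(2, 50, 1)),
               7.32, tolerance = 1e-12)
  expect_equal(content_from_concentration(0, sample_prep(2, 50, 1)), 0)
  base <- content_from_concentration(100, sample_prep(2, 50, 1))
  expect_equal(content_from_concentration(100, sample_prep(2, 50, 2)),
               2 * base)
  expect_equal(content_from_concentration(100, sample_prep(4, 50, 1)),
               base / 2)
  expect_equal(content_from_concentration(200, sample_prep(2, 50, 1)),
               2 * base)
})

test_that("identical content tables compare as perfectly agreeing", {
  recs <- data.frame(
    sample_id = rep(sprintf("S%02d", 1:5), each = 2),
    compound_id = rep(c("a", "b"), 5),
    content_mg_g = stats::runif(10, 1, 10),
    not_detected = FALSE
  )
  cmp <- compare_methods(recs, recs)
  expect_true(cmp$agreement)
  expect_equal(cmp$n_samples, 5L)
  expect_true(all(cmp$by_compound$mean_rel_diff == 0))
  expect_true(all(cmp$by_compound$max_abs_rel_diff == 0))
})

test_that("compounds with fewer than two pairs are skipped with a warning", {
  esm <- data.frame(sample_id = c("S1", "S2", "S1"),
                    compound_id = c("a", "a", "b"),
                    content_mg_g = c(1, 2, 3), not_detected = FALSE)
  qams <- esm
  qams$content_mg_g <- c(1.1, 2.1, 3.1)
  expect_warning(cmp <- compare_methods(esm, qams), "fewer than 2")
  expect_identical(cmp$by_compound$compound_id, "a")
  cmpw <- suppressWarnings(compare_methods(esm, qams, test = "wilcoxon"))
  expect_s3_class(cmpw, "qams_comparison")
})

test_that("on a synthetic batch QAMS tracks ESM wherever ESM is itself in range", {
  cfg <- generator_config(seed = 9)
  series <- quiet_series(cfg, seed = 10)
  batch <- generate_sample_batch(cfg, 16, 15, seed = 9)
  res <- suppressWarnings(qams_pipeline(series, batch, anchor_rt = 31))
  m <- merge(res$esm, res$qams, by = c("sample_id", "compound_id"),
             suffixes = c("_e", "_q"))
  m <- m[!m$not_detected_e & m$flag_e == "ok", ]
  rel <- (m$content_mg_g_q - m$content_mg_g_e) / m$content_mg_g_e
  per_compound <- tapply(rel, m$compound_id, mean)
  expect_true(all(abs(per_compound) < 0.05))
  # presence pattern: crude samples carry no processing markers
  crude_ids <- batch$sample_info$sample_id[batch$sample_info$type == "crude"]
  nd <- res$esm[res$esm$sample_id %in% crude_ids &
                  res$esm$compound_id == "hmf", "not_detected"]
  expect_true(all(nd))
})
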