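noise_free_config <- function(seed = 4) {
  generator_config(seed = seed, area_cv = 0, rt_run_cv = 0, rt_peak_cv = 0,
                   rcf_perturbation = 0, condition_response_cv = 0,
                   condition_rt_cv = 0)
}

test_that("identical seeds reproduce identical outputs", {
  cfg <- generator_config(seed = 8)
  s1 <- quiet_series(cfg, seed = 8)
  s2 <- quiet_series(cfg, seed = 8)
  expect_identical(s1, s2)
  b1 <- generate_sample_batch(cfg, 5, 5, seed = 8)
  b2 <- generate_sample_batch(cfg, 5, 5, seed = 8)
  expect_identical(b1, b2)
  b3 <- generate_sample_batch(cfg, 5, 5, seed = 9)
  expect_false(identical(b1$truth$contents, b3$truth$contents))
})

test_that("dilution levels scale concentrations exactly", {
  cfg <- generator_config(seed = 2)
  series <- quiet_series(cfg, dilutions = c(1, 2, 4, 8))
  stock <- cfg$stock
  for (d in c(1, 2, 4, 8)) {
    lev <- series$levels[[sprintf("L%g", d)]]
    expect_equal(lev$concentrations, stock / d, tolerance = 1e-12)
  }
})

test_that("noise-free generation is exactly on the response lines and invertible", {
  cfg <- noise_free_config()
  series <- quiet_series(cfg, dilutions = 1)
  run <- series$runs[[1]]
  truth <- attr(run, "true_labels")
  ids <- truth$compound_id[match(run$peaks$rt_min, truth$rt_min)]
  expect_equal(run$peaks$area,
               unname(cfg$true_slope[ids] * cfg$stock[ids]),
               tolerance = 1e-12)
  expect_equal(run$peaks$rt_min, unname(cfg$base_rt[ids]),
               tolerance = 1e-12)
})

test_that("the full pipeline returns truth exactly in the noise-free limit", {
  cfg <- noise_free_config()
  series <- quiet_series(cfg)
  batch <- generate_sample_batch(cfg, 3, 3, seed = 4)
  res <- suppressWarnings(qams_pipeline(series, batch, anchor_rt = 31))
  truth <- batch$truth$contents
  for (tab in list(res$esm, res$qams)) {
    got <- tab[!tab$not_detected, ]
    m <- merge(got, truth, by = c("sample_id", "compound_id"),
               suffixes = c("_est", "_true"))
    expect_equal(nrow(m), nrow(truth))
    expect_equal(m$content_mg_g_est, m$content_mg_g_true, tolerance = 1e-9)
  }
  expect_true(res$comparison$agreement)
  expect_true(res$ok)
})

test_that("batch composition follows the crude/processed presence pattern", {
  cfg <- generator_config(seed = 6)
  batch <- generate_sample_batch(cfg, 21, 10, seed = 6)
  expect_length(batch$runs, 31L)
  n_peaks <- vapply(batch$runs, function(r) nrow(r$peaks), 0L)
  expect_equal(sum(n_peaks == 8L), 21L)  # crude: 3 markers absent
  expect_equal(sum(n_peaks == 11L), 10L)
  empty <- generate_sample_batch(cfg, 0, 0, seed = 6)
  expect_length(empty$runs, 0L)
})

test_that("generated relative retention times match the reference row within 1%", {
  cfg <- generator_config(seed = 12)
  series <- quiet_series(cfg, dilutions = c(1, 2), replicates = 10,
                         seed = 12)
  ref <- default_rrt_reference()
  obs <- do.call(rbind, lapply(series$runs, function(run) {
    truth <- attr(run, "true_labels")
    t_s <- truth$rt_min[truth$compound_id == "loganin"]
    data.frame(compound_id = truth$compound_id, rrt = truth$rt_min / t_s)
  }))
  mean_rrt <- tapply(obs$rrt, obs$compound_id, mean)
  for (i in seq_len(nrow(ref))) {
    expect_lt(
      abs(mean_rrt[[ref$compound_id[i]]] - ref$expected_rrt[i]) /
        ref$expected_rrt[i],
      0.01
    )
  }
})

test_that("a single-condition panel reduces to the standard series", {
  cfg <- generator_config(seed = 14)
  panel <- generate_condition_panel(cfg, seed = 14)
  series <- quiet_series(cfg, dilutions = c(2, 4, 8), seed = 14)
  expect_length(panel$groups, 1L)
  for (i in 1:3) {
    expect_equal(panel$groups[[1]][[i]]$peaks[, c("rt_min", "area")],
                 series$runs[[i]]$peaks[, c("rt_min", "area")])
  }
})

test_that("at 35 degrees the unresolved pair merges and cornin is reported absent", {
  cfg <- generator_config(seed = 19)
  panel <- generate_condition_panel(cfg, temperatures = c(30, 35), seed = 19)
  reg <- fructus_corni_registry()
  ref <- default_rrt_reference()
  hot <- panel$groups[[grep("35C", names(panel$groups))]]
  for (run in hot) {
    expect_equal(nrow(run$peaks), 10L)  # 11 compounds, one merged pair
    located <- assign_peaks(run, reg, ref, expected_rt = 31)
    assignment <- attr(located, "assignment")
    expect_true(assignment$not_detected[assignment$compound_id == "cornin"])
    expect_false(
      assignment$not_detected[assignment$compound_id == "sweroside"]
    )
  }
})

test_that("an instrument/column grid keeps every RCF inside the 5% ruggedness band", {
  cfg <- generator_config(seed = 21)
  panel <- generate_condition_panel(
    cfg, instruments = paste("Instrument", c("A", "B", "C")),
    columns = paste("Column", c("A", "B", "C")), seed = 21
  )
  reg <- fructus_corni_registry()
  located <- lapply(panel$groups, function(runs) {
    lapply(runs, assign_peaks, registry = reg,
           reference = default_rrt_reference(), expected_rt = 31)
  })
  rp <- ruggedness_panel(located, panel$levels, reg)
  expect_true(all(rp$summary$pass))
  expect_true(all(rp$summary$rsd_percent < 5))
})
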