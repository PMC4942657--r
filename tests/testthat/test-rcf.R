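test_that("the correction factor obeys its algebraic identities", {
  expect_equal(compute_rcf(10, 500, 10, 500), 1)
  # detector-gain invariance: rescaling both areas leaves f unchanged
  set.seed(3)
  for (i in 1:20) {
    c_i <- stats::runif(1, 1, 500); a_i <- stats::runif(1, 1e3, 1e6)
    c_s <- stats::runif(1, 1, 500); a_s <- stats::runif(1, 1e3, 1e6)
    k <- stats::runif(1, 0.1, 10)
    expect_equal(compute_rcf(c_i, k * a_i, c_s, k * a_s),
                 compute_rcf(c_i, a_i, c_s, a_s), tolerance = 1e-12)
  }
  expect_error(compute_rcf(-1, 2, 3, 4), class = "qams_domain_error")
  expect_error(compute_rcf(1, 0, 3, 4), class = "qams_domain_error")
})

test_that("gallic acid RCF synthesized from the bundled response lines sits in the published band", {
  curves <- reference_curves()
  a_i <- curves$gallic_acid$slope * 124.44 + curves$gallic_acid$intercept
  a_s <- curves$loganin$slope * 415.20 + curves$loganin$intercept
  f <- compute_rcf(124.44, a_i, 415.20, a_s)
  expect_gt(f, 2.1)
  expect_lt(f, 2.5)
})

test_that("aggregation reproduces the bundled replicate table and degenerate cases", {
  obs <- reference_rcf_replicates()
  tab <- rcf_table(obs[, c("compound_id", "f_is")])
  gallic <- tab[tab$compound_id == "gallic_acid", ]
  expect_equal(gallic$mean, 2.319, tolerance = 1e-3)
  expect_equal(gallic$n, 6L)

  same <- data.frame(compound_id = "x", f_is = rep(1.234, 6))
  expect_equal(rcf_table(same)$rsd_percent, 0)
})

test_that("a noisy synthetic dilution series recovers the generator's true RCFs", {
  cfg <- generator_config(seed = 11)
  series <- quiet_series(cfg, dilutions = c(2, 4, 8), replicates = 2,
                         seed = 11)
  reg <- fructus_corni_registry()
  located <- lapply(series$runs, assign_peaks, registry = reg,
                    reference = default_rrt_reference(), expected_rt = 31)
  tab <- rcf_from_dilution_series(located, series$levels, reg)
  for (i in seq_len(nrow(tab))) {
    id <- tab$compound_id[i]
    se <- tab$sd[i] / sqrt(tab$n[i])
    expect_lt(abs(tab$mean[i] - cfg$f_true[[id]]), 3 * se)
  }
})

test_that("runs without a located internal reference are excluded with a warning", {
  cfg <- generator_config(seed = 11, area_cv = 0, rt_run_cv = 0,
                          rt_peak_cv = 0)
  series <- quiet_series(cfg, dilutions = c(2, 4))
  reg <- fructus_corni_registry()
  located <- lapply(series$runs, assign_peaks, registry = reg,
                    reference = default_rrt_reference(), expected_rt = 31)
  # blank out the anchor label in one run
  located[[1]]$peaks$compound_id[located[[1]]$peaks$compound_id == "loganin"] <-
    NA_character_
  expect_warning(
    tab <- rcf_from_dilution_series(located, series$levels, reg),
    "excluded"
  )
  expect_true(all(tab$n == 1L))
})

test_that("ruggedness summaries exclude missing cells and flag against the threshold", {
  temp <- reference_ruggedness("temperature")
  cornin <- temp[temp$compound_id == "cornin", ]
  expect_equal(sum(is.na(cornin$f_is)), 1L)
  summ <- ruggedness_summary(temp)
  got <- summ[summ$compound_id == "cornin", ]
  expect_equal(got$n_conditions, 2L)
  expect_equal(got$mean, 1.29, tolerance = 5e-3)

  identical_groups <- data.frame(
    condition = rep(c("c1", "c2", "c3"), each = 2),
    compound_id = rep(c("a", "b"), 3),
    f_is = rep(c(2, 1.5), 3)
  )
  summ0 <- ruggedness_summary(identical_groups)
  expect_true(all(summ0$rsd_percent == 0))
  expect_true(all(summ0$pass))

  expect_error(
    ruggedness_summary(data.frame(condition = "only", compound_id = "a",
                                  f_is = 1)),
    class = "qams_config_error"
  )
})

test_that("ruggedness panels reject empty or single groups", {
  reg <- fructus_corni_registry()
  cfg <- generator_config(seed = 5)
  panel <- generate_condition_panel(cfg, instruments = c("I1", "I2"),
                                    seed = 5)
  located <- lapply(panel$groups, function(runs) {
    lapply(runs, assign_peaks, registry = reg,
           reference = default_rrt_reference(), expected_rt = 31)
  })
  expect_error(ruggedness_panel(located[1], panel$levels, reg),
               class = "qams_config_error")
  broken <- located
  broken[[1]] <- list()
  expect_error(ruggedness_panel(broken, panel$levels, reg),
               "empty", class = "qams_config_error")
  rp <- ruggedness_panel(located, panel$levels, reg)
  expect_s3_class(rp$summary, "ruggedness_summary")
  expect_equal(sort(unique(rp$condition_means$condition)),
               sort(names(located)))
})
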