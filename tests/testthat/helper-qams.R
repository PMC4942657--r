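# small builders shared across test files

make_run <- function(rt, area, ids = NULL, run_id = "r1", source = NA,
                     window = 55) {
  injection_run(
    run_id,
    data.frame(rt_min = rt, area = area,
               compound_id = if (is.null(ids)) NA_character_ else ids,
               stringsAsFactors = FALSE),
    source = source, window_max_min = window
  )
}

tiny_registry <- function() {
  compound_registry(c("a", "s", "b"), internal_reference = "s")
}

# closed-form simple linear regression (independent of stats::lm)
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

# two-pass sample standard deviation (independent of stats::sd)
sd_oracle <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

quiet_series <- function(...) suppressWarnings(generate_standard_series(...))
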