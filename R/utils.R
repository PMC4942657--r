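`%||%` <- function(a, b) if (is.null(a)) b else a

qams_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "qams_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate code with a temporary RNG seed
#'
#' Seeds the random number generator, evaluates `code`, and restores the
#' caller's RNG state afterwards so package functions never leak seed state
#' into the user's session.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    qams_stop("`seed` must be a single integer", "qams_config_error")
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# multiplicative lognormal noise with unit mean and coefficient of variation cv
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
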