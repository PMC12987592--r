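## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not perturb the
#' caller's RNG stream.
#' @noRd
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
isBinaryMatrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1))
}

#' @noRd
checkSymmetric <- function(x, tol = 1e-9) {
  max(abs(x - t(x))) <= tol
}

## Stop with a classed condition so callers/tests can distinguish failure
## modes (format, value, id, shape, ...).
#' @noRd
stopType <- function(type, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(paste0("circDrugGSL_", type), "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

## Smoothed (trailing-window mean) version of a loss trace, used by the
## plateau-based early-stopping rule and by descent diagnostics.
#' @noRd
smoothTrace <- function(x, window = 10L) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - window + 1L)
    mean(x[lo:i])
  }, numeric(1))
}
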