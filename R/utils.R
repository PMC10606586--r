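# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so library code never perturbs user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# clamp values into [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# stop() with a classed condition so callers/tests can distinguish error kinds
dgclStop <- function(msg, class) {
  stop(structure(
    class = c(class, "dgclError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

configError    <- function(msg) dgclStop(msg, "dgclConfigError")
validationError <- function(msg) dgclStop(msg, "dgclValidationError")
ioError        <- function(msg) dgclStop(msg, "dgclIOError")
stateError     <- function(msg) dgclStop(msg, "dgclStateError")
degenerateError <- function(msg) dgclStop(msg, "dgclDegenerateError")

assertFinite <- function(x, what) {
  if (!all(is.finite(x))) {
    validationError(sprintf("%s contains non-finite values", what))
  }
  invisible(TRUE)
}

# L2-normalise matrix rows; zero rows raise a validation error
l2NormalizeRows <- function(x, what = "features") {
  nrm <- sqrt(rowSums(x * x))
  if (any(nrm == 0)) {
    validationError(sprintf("%s has zero-norm rows; cannot L2-normalize", what))
  }
  x / nrm
}
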