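# Internal helpers shared across modules.

# Half-vectorization (column-major lower triangle including the diagonal).
# This ordering is the package-wide convention for the sampling covariance V;
# every consumer of V asserts it through these helpers.
vech <- function(m) m[lower.tri(m, diag = TRUE)]

# Inverse of vech() for a t x t symmetric matrix.
unvech <- function(v, t) {
  m <- matrix(0, t, t)
  m[lower.tri(m, diag = TRUE)] <- v
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  m
}

# Labels "a:b" for vech elements, in vech order.
vechLabels <- function(labels) {
  t <- length(labels)
  idx <- which(lower.tri(matrix(0, t, t), diag = TRUE), arr.ind = TRUE)
  paste(labels[idx[, 2L]], labels[idx[, 1L]], sep = ":")
}

# Row/col indices of vech elements, in vech order (row >= col).
vechIndices <- function(t) {
  which(lower.tri(matrix(0, t, t), diag = TRUE), arr.ind = TRUE)
}

# Evaluate code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Deterministic child seed for a named pipeline stage.
childSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562) + 1L
}

# Classed conditions so callers can distinguish configuration, input, model
# and numerical failures.
fgStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "fg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
configError <- function(fmt, ...) fgStop("fg_config_error", fmt, ...)
inputError  <- function(fmt, ...) fgStop("fg_input_error", fmt, ...)
modelError  <- function(fmt, ...) fgStop("fg_model_error", fmt, ...)
numericError <- function(fmt, ...) fgStop("fg_numeric_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided normal p-value from a Z statistic, kept strictly in (0, 1].
zToP <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
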