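#' @keywords internal
"_PACKAGE"

## Seed fan-out: one master seed is hashed into independent substreams so that
## e.g. the train/test split, tuning and permutation draws never share a stream.
## Kept below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  h <- (as.double(master) * 69069 + stream * 1234567 + 987653) %% 2147483629
  as.integer(h)
}

## Evaluate f under a local RNG state; the caller's RNG is untouched.
with_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  f()
}

#' Root mean square error
#'
#' @param truth Numeric vector of observed values.
#' @param pred Numeric vector of predictions, same length.
#' @return The root mean square error, a non-negative scalar in the units of
#'   `truth`.
#' @export
rmse <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  sqrt(mean((truth - pred)^2))
}

## Pearson r with a p-value; returns r = 0 with a warning for zero-variance
## input (the convention used by the selection filter and report matrices).
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance column: correlation set to 0")
    return(0)
  }
  stats::cor(x, y)
}
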