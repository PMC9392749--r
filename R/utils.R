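# Small shared helpers: rounding, percentages, seeded evaluation.

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; cohort percentage columns use the
#' conventional half-up rule so that printed percentages are reproducible.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to \code{digits} decimals.
#' @examples
#' roundHalfUp(0.05, 1)  # 0.1, where round(0.05, 1) gives 0
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a sample count as a percentage
#'
#' Converts a count out of a cohort size into a percentage rounded half-up to
#' one decimal, the format used in the per-gene recurrence table (e.g. 186 of
#' 286 tumors -> 65.0).
#'
#' @param n integer count of samples.
#' @param total cohort size (must be > 0).
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @examples
#' formatPct(186, 286)  # 65.0
#' formatPct(11, 286)   # 3.8
#' @export
formatPct <- function(n, total, digits = 1) {
  stopifnot(is.numeric(n), is.numeric(total), all(total > 0))
  roundHalfUp(100 * n / total, digits)
}

# Evaluate expr under a fixed RNG seed, restoring caller RNG state after.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic zero-padded ids: "TE000001", ...
.padId <- function(prefix, i, width = 6) sprintf("%s%0*d", prefix, width, i)
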