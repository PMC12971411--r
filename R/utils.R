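# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random number stream.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Percent shares in summary tables are rounded half-up to match the
#' conventional presentation (R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal digits.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Draw one element uniformly from a vector (safe for length-1 vectors,
# unlike sample()).
pick1 <- function(v) v[sample.int(length(v), 1L)]

# Canonical unordered pair key, used to match anchor pairs across tables.
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}
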