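# shared validation + small numeric helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bbm <- function(...) stop(sprintf(...), call. = FALSE)

assert_binary_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask)) stop_bbm("%s must be a matrix", what)
  if (is.logical(mask)) return(invisible(mask))
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1)))
    stop_bbm("%s is not binary: values other than 0/1 present", what)
  invisible(mask)
}

as_logical_mask <- function(mask) {
  assert_binary_mask(mask)
  if (!is.logical(mask)) mask <- mask > 0
  mask
}

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed report tables use
#' conventional half-up rounding at 2 decimals instead.
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library functions stay composable
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# derive a child seed from a base seed and a stage tag, kept below 2^31
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
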