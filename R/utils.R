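#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom stats predict
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive a reproducible child seed from a base seed, kept inside the 32-bit
# integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% .Machine$integer.max)
}
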