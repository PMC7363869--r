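#' Derive a child seed from a master seed and labels
#'
#' Deterministic splitting rule used throughout the pipeline so every
#' stochastic stage (pseudo-absence set, cross-validation run, species,
#' stage) gets its own reproducible stream: the labels are concatenated
#' with `:` and folded into the master seed by the polynomial hash
#' `h <- (h * 31 + code) mod (2^31 - 1)` over the character codes.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the stage.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @examples
#' childSeed(42, "speciesA", "global", "pa", 2)
#' @export
childSeed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  lab <- paste(vapply(list(...), as.character, character(1)),
               collapse = ":")
  for (code in utf8ToInt(lab)) h <- (h * 31 + code) %% m
  as.integer(max(1, h))
}
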