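#' Derive a child seed from a master seed and a stage label
#'
#' Deterministic 31-bit hash so every random decision in a pipeline consumes
#' its own reproducible stream derived from one master seed.
#'
#' @param master Integer master seed.
#' @param label Character stage label.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, label) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% m
  as.integer(((as.numeric(master) %% m) * 48271 + h) %% (m - 1) + 1)
}
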