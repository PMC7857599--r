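#' Derive a child seed deterministically from a root seed
#'
#' Counter-based seed derivation: mixes the root seed with any number of
#' integer or character components through a Lehmer-style modular hash, so
#' every replicate of an experiment gets an independently reproducible seed
#' below 2^31.  The arithmetic stays exact in double precision.
#'
#' @param root Integer root seed.
#' @param ... Integer or character components (experiment name, grid index,
#'   replicate index, stage).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(root) %% m
  for (x in list(...)) {
    if (is.character(x)) x <- utf8ToInt(x)
    for (v in as.numeric(x)) {
      h <- (h * 48271 + v + 1) %% m
    }
  }
  as.integer(h %% (m - 1) + 1)
}
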