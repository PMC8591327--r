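# Deterministic seed streams.
#
# Every stochastic operation in the package takes an explicit integer seed.
# Pipelines hold a single root seed and derive one sub-seed per (replicate,
# generation, operation) triple, so any single step of a long simulation can
# be replayed in isolation.

#' Derive a deterministic sub-seed from a root seed and a stream label
#'
#' A small multiplicative hash maps `(root, key)` to an integer in
#' `[1, 2^31 - 2]`.  The same root and key always yield the same sub-seed;
#' distinct keys yield (for practical purposes) independent streams.
#'
#' @param root Integer root seed of the run.
#' @param ... Stream labels (characters or integers); concatenated in order.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "rep", 3, "meiosis")
derive_seed <- function(root, ...) {
  m <- 2147483647
  key <- paste(c(...), collapse = "/")
  s <- as.double(root %% m)
  for (v in utf8ToInt(key)) {
    s <- (s * 69069 + v) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
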