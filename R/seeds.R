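#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in a meta-simulation flows from one root seed. Each stage
#' (ground-truth sampling, practitioner draws, structure-learner synthetic
#' samples, classifier fits) derives its own seed deterministically from the
#' root seed and a sequence of tags, so any single repetition can be re-run
#' in isolation and two runs with the same root seed are identical.
#'
#' The scheme folds the tags (integers or strings) into a 31-bit integer by
#' iterated multiply-add modulo the Mersenne prime 2^31 - 1.
#'
#' @param root integer root seed.
#' @param ... tags identifying the stream: stage name, practitioner index,
#'   repetition index, method id, ...
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, "truth", 1)
#' derive_seed(42, "sl", "hc", 3, 17)
#' @export
derive_seed <- function(root, ...) {
  m <- 2147483647
  h <- as.double(root %% m)
  for (tag in list(...)) {
    codes <- if (is.character(tag)) utf8ToInt(tag) else as.integer(tag)
    for (v in codes) {
      h <- (h * 31 + (as.double(v) %% m) + 7) %% m
    }
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
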