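# RNG plumbing shared by every stochastic operation in the package.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded package operations never disturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic seed-splitting rule used throughout the simulation pipeline:
#' the master seed and an index path (e.g. subject, hemisphere, observer) are
#' folded into a single integer by a multiplicative hash modulo the Mersenne
#' prime 2^31 - 1, so every stage of a study draws from its own reproducible
#' stream and all derived seeds stay within R's integer range.
#'
#' @param master Integer master seed.
#' @param ... Integer indices identifying the stream (subject index,
#'   hemisphere index, observer index, replicate number, ...).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(17, 3, 1, 2)
child_seed <- function(master, ...) {
  idx <- as.numeric(c(...))
  m <- 2147483647 # 2^31 - 1
  h <- (abs(as.numeric(master)) %% m) + 1
  for (x in idx) {
    # 48271 is the MINSTD multiplier; products stay below 2^53 so doubles
    # carry them exactly
    h <- (h * 48271 + abs(x) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
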