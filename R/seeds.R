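#' Derive a stage-specific child seed from a global seed
#'
#' All stochastic stages of the workflow draw their seed deterministically
#' from one global integer seed plus a stage name, so that a single seed
#' reproduces an entire run while stages stay statistically decoupled.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name (e.g. `"drift"`, `"genotypes"`).
#' @return An integer in `[0, 2^31 - 2]` suitable for `set.seed()`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps everything in 32-bit integer range
  h <- as.double(seed) %% m
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% m
  as.integer(h)
}

# Run `expr` under a local RNG state seeded by `seed`; restores the caller's
# RNG afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
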