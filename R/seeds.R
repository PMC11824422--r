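#' Derive a reproducible sub-stream seed from a master seed
#'
#' All stochastic generators in the package draw their seed from a single
#' master seed plus a stream name, so that adding a new generator to a
#' pipeline never perturbs the random streams of existing ones.  The name is
#' hashed with a 32-bit FNV-1a and combined with the master seed modulo
#' 2^31 - 1 (R seeds are 32-bit integers).
#'
#' @param master integer master seed.
#' @param stream character scalar naming the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "sfs") != substream_seed(1, "pileup")
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- 2166136261
  for (b in utf8ToInt(stream)) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((abs(master) * 48271 + h) %% 2147483646)
}

# Evaluate `expr` under a local RNG state seeded by `seed`; restores the
# caller's RNG so generators behave as pure functions of (parameters, seed).
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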