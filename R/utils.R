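# Internal numeric and RNG helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# make augmented pixel values depend on tie parity; detection pipelines in
# this space round .5 upward in magnitude.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clip255 <- function(x) {
  pmin(pmax(x, 0), 255)
}

#' Derive a reproducible sub-seed from a base seed and string tokens
#'
#' Mixes a base seed with arbitrary tokens (image ids, copy indices) using a
#' polynomial rolling hash modulo 2^31 - 1, so per-image noise streams are
#' independent of processing order and stable across platforms.
#'
#' @param seed Integer base seed.
#' @param ... Tokens (coerced to character) to mix in.
#' @return An integer in [0, 2^31 - 2] suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(17, "img_0003", 1)
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  h <- as.numeric(seed) %% m
  for (tok in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(tok)))) {
      h <- (h * 31 + ch) %% m
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
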