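#' @keywords internal
"_PACKAGE"

#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages draw their seed from one master seed keyed by a stage
#' name, so stages can be re-run independently yet reproducibly. The derived
#' value always fits a 32-bit signed integer.
#'
#' @param seed master integer seed.
#' @param stage character stage key (e.g. `"simulate"`).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69069 + h * 2654435769) %% 2147483629L + 1)
}

# run expr with a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# 0-based window index of 1-based positions for windows tiled from position 1
window_index <- function(pos, window) (pos - 1L) %/% as.integer(window)

# per-(chrom, window) aggregation key, stable ordering
window_key <- function(chrom, pos, window) {
  w <- window_index(pos, window)
  list(key = paste(chrom, w, sep = "\r"), chrom = chrom, win = w)
}

# harmonic numbers a_n = sum_{k=1}^{n} 1/k
harmonic <- function(n) if (n <= 0) 0 else sum(1 / seq_len(n))

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
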