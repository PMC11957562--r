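#' @keywords internal
"_PACKAGE"

## Modular-coordinate helpers. All public coordinates in this package are
## 0-based, half-open, reduced modulo the genome length; intervals that span
## the origin are carried canonically as (start, width) with 0 <= start < L.

#' Reduce positions modulo a genome length
#'
#' @param pos integer vector of (possibly out-of-range) 0-based positions.
#' @param len genome length in bases.
#' @return positions reduced into `[0, len)`.
#' @keywords internal
mod_pos <- function(pos, len) {
  ((pos %% len) + len) %% len
}

## 1-based R indices for the circular window starting at 0-based `start`,
## of width `width` (width may exceed len only never; wraps are allowed).
circ_index <- function(start, width, len) {
  stopifnot(width >= 0)
  if (width == 0L) return(integer(0))
  mod_pos(seq.int(start, length.out = width), len) + 1L
}

## Shortest distance between two positions on the circle.
circ_dist <- function(a, b, len) {
  d <- abs(mod_pos(a, len) - mod_pos(b, len))
  pmin(d, len - d)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that simulation functions are
#' deterministic given their own seed without disturbing the caller's
#' random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Circular moving average with an odd window; used for track smoothing.
circ_smooth <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(as.numeric(x))
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  half <- (window - 1L) %/% 2L
  xx <- c(x[(n - half + 1L):n], x, x[1L:half])
  as.numeric(stats::filter(xx, rep(1 / window, window), sides = 2))[
    (half + 1L):(half + n)]
}

## Rotate a vector so that old position r (0-based) becomes position 0.
rotate_vec <- function(x, r) {
  n <- length(x)
  r <- mod_pos(r, n)
  if (r == 0L) return(x)
  c(x[(r + 1L):n], x[1L:r])
}

reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
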