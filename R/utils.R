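# Internal helpers: seeding, interpolation, numeric checks.

#' Evaluate code under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Deterministic per-stage substream seed derived from a global seed
#'
#' Maps (seed, stage name) to an integer below 2^31 so that pipeline stages
#' can be rerun independently and reproducibly.
#' @noRd
seed_substream <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  ((as.double(seed) %% 2147483647) * 31 + h) %% 2147483647
}

#' Bilinear interpolation of a pixel grid at fractional 0-based coordinates
#'
#' Pixel centers sit at integer (row, col) coordinates, row 0 is the apical
#' (top) edge. Coordinates must stay inside [0, nrow-1] x [0, ncol-1].
#' @noRd
bilinear_sample <- function(pixels, r, c) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (any(r < 0 | r > nr - 1 | c < 0 | c > nc - 1)) {
    stop("sample coordinates outside image bounds", call. = FALSE)
  }
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- pixels[cbind(r0 + 1, c0 + 1)]
  i01 <- pixels[cbind(r0 + 1, c0 + 2)]
  i10 <- pixels[cbind(r0 + 2, c0 + 1)]
  i11 <- pixels[cbind(r0 + 2, c0 + 2)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

#' Composite trapezoid rule over an (x, y) polyline
#' @noRd
trapz_xy <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Linear interpolation of a curve at new abscissae (no extrapolation)
#' @noRd
lin_interp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", ties = "ordered")$y
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
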