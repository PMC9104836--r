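# Unitary 2-D Fourier transforms and centred-spectrum helpers.
# All grids in the package have even side lengths, so fftshift is its own
# inverse and a single shift function suffices.

#' Unitary 2-D Fourier transforms
#'
#' `ft2()`/`ift2()` are the unitary forward/inverse 2-D DFT (scaled by
#' `1/sqrt(N)` so that Parseval's identity holds exactly). `fftShift()`
#' swaps quadrants so the DC bin moves between position `[1, 1]` and the
#' grid centre `[n/2 + 1, n/2 + 1]`; for the even-sided grids used here it
#' is an involution. `ftc()`/`iftc()` map a spatial field to/from its
#' centred spectrum.
#'
#' @param x numeric or complex matrix with even side lengths.
#' @return complex matrix of the same dimensions.
#' @examples
#' u <- matrix(rnorm(16), 4, 4)
#' max(Mod(iftc(ftc(u)) - u)) < 1e-12
#' abs(sum(Mod(ftc(u))^2) - sum(u^2)) < 1e-9  # Parseval
#' @export
ft2 <- function(x) stats::fft(x) / sqrt(length(x))

#' @rdname ft2
#' @export
ift2 <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' @rdname ft2
#' @export
fftShift <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  stopifnot(n1 %% 2 == 0, n2 %% 2 == 0)
  x[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2)), drop = FALSE]
}

#' @rdname ft2
#' @export
ftc <- function(x) fftShift(ft2(x))

#' @rdname ft2
#' @export
iftc <- function(x) ift2(fftShift(x))

# Run code under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched. seed = NULL runs code as-is.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Wrap radians to (-pi, pi].
wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
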