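# Shared fixtures: miniature optical configurations and an independent
# brute-force DFT oracle for the forward model.

# 3 x 3 LEDs, 16 -> 32 pixels: aperture radius ~4.1 px, max window shift 2.
tinyConfig <- function(...)
  opticalConfig(ledRows = 3, ledCols = 3, lrSide = 16, hrSide = 32, ...)

# 5 x 5 LEDs, 32 -> 96 pixels: enough aperture overlap for end-to-end
# recovery within seconds.
smallConfig <- function(...)
  opticalConfig(ledRows = 5, ledCols = 5, lrSide = 32, hrSide = 96, ...)

# Loop-based direct DFT evaluation of the forward model on tiny grids:
# I = | (1/sqrt(m^2)) sum_f p(f) S(f0 + f) exp(2 pi i f.x / m) |^2 with
# S the unitary DFT of u computed by explicit summation. Independent of
# the package's fft/shift helpers.
directDFTIntensity <- function(u, pupilValues, shiftX, shiftY) {
  n <- nrow(u); m <- nrow(pupilValues)
  # centred HR spectrum by brute force: frequency index -n/2 .. n/2-1
  S <- matrix(0 + 0i, n, n)
  for (a in 1:n) for (b in 1:n) {
    fy <- a - (n / 2 + 1); fx <- b - (n / 2 + 1)
    ph <- outer(exp(-2i * pi * fy * (0:(n - 1)) / n),
                exp(-2i * pi * fx * (0:(n - 1)) / n))
    S[a, b] <- sum(u * ph) / n
  }
  # crop the window centred at the shifted bin
  rows <- (n / 2 + 1 + shiftY - m / 2):(n / 2 + 1 + shiftY + m / 2 - 1)
  cols <- (n / 2 + 1 + shiftX - m / 2):(n / 2 + 1 + shiftX + m / 2 - 1)
  Sw <- S[rows, cols] * pupilValues
  # inverse unitary DFT on the LR grid by brute force
  I <- matrix(0, m, m)
  fidx <- (1:m) - (m / 2 + 1)
  for (y in 1:m) for (x in 1:m) {
    ph <- outer(exp(2i * pi * fidx * (y - 1) / m),
                exp(2i * pi * fidx * (x - 1) / m))
    I[y, x] <- Mod(sum(Sw * ph) / m)^2
  }
  I
}

# Random ADMM-like state on arbitrary (manual) windows, for subproblem
# oracle tests. Grids are small; windows need not come from any LED
# geometry.
randomAdmmState <- function(n = 8, m = 4, nWin = 3, seed = 1) {
  set.seed(seed)
  rc <- function(k) matrix(complex(real = rnorm(k * k),
                                   imaginary = rnorm(k * k)), k, k)
  starts <- cbind(sample(0:(n - m), nWin, replace = TRUE),
                  sample(0:(n - m), nWin, replace = TRUE))
  windows <- lapply(seq_len(nWin), function(j)
    structure(list(rows = (starts[j, 1] + 1):(starts[j, 1] + m),
                   cols = (starts[j, 2] + 1):(starts[j, 2] + m)),
              class = "SpectrumWindow"))
  mask <- matrix(TRUE, m, m); mask[1, 1] <- FALSE   # one dead pupil pixel
  p <- rc(m); p[!mask] <- 0
  q <- array(0 + 0i, c(m, m, nWin)); w <- q
  A <- array(0, c(m, m, nWin))
  for (j in seq_len(nWin)) {
    q[, , j] <- rc(m); w[, , j] <- 0.3 * rc(m)
    A[, , j] <- Mod(rc(m))
  }
  delta <- ftc(matrix(1 + 0i, n, n))
  list(s = rc(n), p = p, q = q, w = w, delta = delta, A = A,
       windows = windows, mask = mask, order = seq_len(nWin), k = 1L)
}
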