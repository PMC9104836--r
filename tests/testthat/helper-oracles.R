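# Independent numeric oracles for the ADMM subproblems, shared by the
# unit and acceptance tests. Each solves the subproblem by a route that
# does not reuse the closed forms under test.

# derivative-free per-pixel minimizer of the q-subproblem in the spatial
# domain: (1/2)(|e| - A)^2 + (alpha/2)|e - et|^2 (unitary transforms make
# the Fourier-domain objective separable over spatial pixels)
oracleQ <- function(state, params, j) {
  qt <- state$p * cropSpectrum(state$s, state$windows[[j]]) - state$w[, , j]
  et <- iftc(qt)
  A <- state$A[, , j]
  m <- nrow(et)
  eOpt <- matrix(0 + 0i, m, m)
  for (i in seq_len(m * m)) {
    f <- function(z) 0.5 * (sqrt(z[1]^2 + z[2]^2) - A[i])^2 +
      params$alpha / 2 * ((z[1] - Re(et[i]))^2 + (z[2] - Im(et[i]))^2)
    res <- stats::optim(c(Re(et[i]), Im(et[i])), f, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    eOpt[i] <- complex(real = res$par[1], imaginary = res$par[2])
  }
  ftc(eOpt)
}

# dense normal-equations solve of the s-subproblem, operator built column
# by column from basis vectors
oracleS <- function(state, params) {
  n <- nrow(state$s)
  ridge <- params$gamma / params$alpha
  applyOp <- function(v) {
    S <- matrix(v, n, n)
    out <- ridge * S
    for (j in seq_along(state$windows)) {
      win <- state$windows[[j]]
      out[win$rows, win$cols] <- out[win$rows, win$cols] +
        Mod(state$p)^2 * S[win$rows, win$cols]
    }
    as.vector(out)
  }
  M <- matrix(0 + 0i, n * n, n * n)
  for (i in seq_len(n * n)) {
    e <- rep(0 + 0i, n * n); e[i] <- 1
    M[, i] <- applyOp(e)
  }
  rhs <- ridge * state$delta
  for (j in seq_along(state$windows)) {
    win <- state$windows[[j]]
    rhs[win$rows, win$cols] <- rhs[win$rows, win$cols] +
      Conj(state$p) * (state$q[, , j] + state$w[, , j])
  }
  matrix(solve(M, as.vector(rhs)), n, n)
}

# per-pixel scalar least squares for the pupil via a stacked real QR
# solve (use betaScale = "raw" so `beta` is the ridge actually applied)
oracleP <- function(state, params) {
  m <- nrow(state$p)
  ridge <- params$beta
  out <- matrix(0 + 0i, m, m)
  crops <- lapply(state$windows, function(w) cropSpectrum(state$s, w))
  for (i in seq_len(m * m)) {
    if (!state$mask[i]) next
    X <- NULL; y <- NULL
    for (j in seq_along(crops)) {
      cj <- crops[[j]][i]
      rj <- state$q[, , j][i] + state$w[, , j][i]
      X <- rbind(X, c(Re(cj), -Im(cj)), c(Im(cj), Re(cj)))
      y <- c(y, Re(rj), Im(rj))
    }
    X <- rbind(X, sqrt(ridge) * diag(2))
    y <- c(y, 0, 0)
    coef <- qr.solve(X, y)
    out[i] <- complex(real = coef[1], imaginary = coef[2])
  }
  out
}
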