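# Independent oracles used across the test files.

# Fixed-step explicit Euler integration of the model using the R-level RHS,
# with the same clamp-small-negatives rule as the adaptive integrator.
euler_integrate <- function(state, params, dt = 1e-4, t_end = 300) {
  nsteps <- ceiling(t_end / dt)
  for (k in seq_len(nsteps)) {
    d <- cdi_rhs(state, params)
    u <- state$u + dt * d$du
    v <- state$v + dt * d$dv
    u[u < 0] <- 0
    v[v < 0] <- 0
    state <- cdi_state(u, v, time = state$time + dt)
  }
  state
}

# 1D state constructor that skips nonnegativity validation, so finite
# differences may probe slightly negative concentrations
raw_state_1d <- function(u, v)
  structure(list(u = u, v = v, time = 0, dim = 1L), class = "cdi_state")

# Central finite-difference Jacobian of the 1D RHS, ordered (u, v).
fd_jacobian_1d <- function(state, params, h = 1e-7) {
  N <- length(state$u)
  y0 <- c(state$u, state$v)
  J <- matrix(0, 2 * N, 2 * N)
  for (j in seq_len(2 * N)) {
    yp <- y0; ym <- y0
    yp[j] <- yp[j] + h; ym[j] <- ym[j] - h
    fp <- cdi_rhs(raw_state_1d(yp[1:N], yp[(N + 1):(2 * N)]), params)
    fm <- cdi_rhs(raw_state_1d(ym[1:N], ym[(N + 1):(2 * N)]), params)
    J[, j] <- (c(fp$du, fp$dv) - c(fm$du, fm$dv)) / (2 * h)
  }
  J
}

# quick parameter fixture used by many tests
p_pattern <- function(c1 = 2, D = 1e-3, ratio = 3.5, N = 32)
  cdi_params(alpha = ratio, beta = 1, c1 = c1, D = D, n_grid = N)
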