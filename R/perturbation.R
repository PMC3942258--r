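#' Two-domain trial coexistence state (D = 0)
#'
#' Builds the simplest spatially inhomogeneous steady state of the 1D model
#' without diffusion: one contiguous domain of each species at its carrying
#' capacity, joined by two single-site transition layers carrying an
#' intermediate CDI- concentration \eqn{u^* = \alpha - c_1 \beta} (and no
#' CDI+). At a transition layer the inhibition received from the single
#' adjacent CDI+ site, \eqn{c_1 \beta}, exactly balances the growth surplus,
#' so the state zeroes the D = 0 right-hand side at every site.
#'
#' With the default layer positions \code{c(N/2, N)} the CDI+ domain
#' occupies sites N/2+1 .. N-1 and the CDI- domain sites 1 .. N/2-1. Any
#' cyclic relocation of the layers gives the same state up to rotation.
#'
#' @param params A \code{\link{cdi_params}} with \eqn{\alpha > c_1 \beta}
#'   (positive layer concentration).
#' @param N Ring length (defaults to \code{params$n_grid}).
#' @param layers Integer positions of the two transition-layer sites.
#' @return A \code{\link{cdi_state}} of class
#'   \code{c("cdi_trial_state", "cdi_state")} with attribute
#'   \code{"layers"}.
#' @examples
#' p <- cdi_params(alpha = 3.5, beta = 1, c1 = 2, D = 0)
#' ts <- trial_state(p)
#' ts$u[16]  # transition layer: 3.5 - 2*1 = 1.5
#' @export
trial_state <- function(params, N = params$n_grid,
                        layers = c(N %/% 2, N)) {
  stopifnot(inherits(params, "cdi_params"), N >= 4)
  if (params$c1 <= 0) stop("c1 must be positive for a transition layer")
  ustar <- params$alpha - params$c1 * params$beta
  if (ustar <= 0)
    stop("no positive transition-layer concentration: need alpha > c1 * beta")
  layers <- sort(as.integer(layers))
  if (length(layers) != 2L || any(layers < 1L | layers > N) ||
      layers[1] == layers[2])
    stop("layers must be two distinct sites in 1..N")
  if (diff(layers) < 2L || diff(layers) > N - 2L)
    stop("each domain must contain at least one site between the layers")
  u <- rep(params$alpha, N); v <- rep(0, N)
  vsites <- (layers[1] + 1):(layers[2] - 1)
  u[vsites] <- 0; v[vsites] <- params$beta
  u[layers] <- ustar
  st <- cdi_state(u, v)
  attr(st, "layers") <- layers
  class(st) <- c("cdi_trial_state", class(st))
  st
}

#' Analytic Jacobian of the 1D model
#'
#' The 2N x 2N Jacobian of the 1D right-hand side (including diffusion)
#' at a state, ordered (u_1..u_N, v_1..v_N). Used for linear stability of
#' inhomogeneous steady states.
#'
#' @param state A 1D \code{\link{cdi_state}}.
#' @param params A \code{\link{cdi_params}}.
#' @return A 2N x 2N numeric matrix.
#' @export
cdi_jacobian_1d <- function(state, params) {
  stopifnot(inherits(state, "cdi_state"), state$dim == 1L)
  u <- state$u; v <- state$v; N <- length(u)
  a <- params$alpha; b <- params$beta
  c1 <- params$c1; Dd2 <- params$D / params$delta^2
  ip <- c(2:N, 1); im <- c(N, 1:(N - 1))
  onsite <- params$onsite_only
  vker <- if (onsite) params$c * v else c1 * (v[ip] + v + v[im])
  J <- matrix(0, 2 * N, 2 * N)
  for (i in seq_len(N)) {
    # u-equation
    J[i, i] <- a - 2 * u[i] - v[i] - vker[i] - 2 * Dd2
    J[i, ip[i]] <- J[i, ip[i]] + Dd2
    J[i, im[i]] <- J[i, im[i]] + Dd2
    if (onsite) {
      J[i, N + i] <- -u[i] * (1 + params$c)
    } else {
      J[i, N + i] <- -u[i] * (1 + c1)
      J[i, N + ip[i]] <- -u[i] * c1
      J[i, N + im[i]] <- -u[i] * c1
    }
    # v-equation
    J[N + i, N + i] <- b - u[i] - 2 * v[i] - 2 * Dd2
    J[N + i, N + ip[i]] <- J[N + i, N + ip[i]] + Dd2
    J[N + i, N + im[i]] <- J[N + i, N + im[i]] + Dd2
    J[N + i, i] <- -v[i]
  }
  J
}

#' Linear stability of the trial state at D = 0
#'
#' Evaluates the full 2N x 2N Jacobian of the 1D model (with D as stored in
#' \code{params}, normally 0) at the trial state and reports its spectrum.
#' The state is declared stable when the maximal eigenvalue real part is
#' below a strict-negativity tolerance.
#'
#' @param trial A \code{\link{trial_state}} (or any 1D steady state).
#' @param params A \code{\link{cdi_params}}.
#' @param tol Negativity tolerance on the maximal real part.
#' @return A list with \code{max_re} (maximal eigenvalue real part),
#'   \code{stable} (logical), and \code{eigenvalues}.
#' @examples
#' p <- cdi_params(alpha = 3.5, beta = 1, c1 = 2, D = 0)
#' stability_D0(trial_state(p), p)$stable  # TRUE: 3 < 3.5 < 5
#' @export
stability_D0 <- function(trial, params, tol = 1e-10) {
  ev <- eigen(cdi_jacobian_1d(trial, params), only.values = TRUE)$values
  mx <- max(Re(ev))
  list(max_re = mx, stable = mx < -tol, eigenvalues = ev)
}

#' Analytic necessary condition for patterned coexistence
#'
#' For slow diffusion the perturbed two-domain steady state can only remain
#' positive and bounded by the carrying capacities if the growth advantage
#' lies in the open interval \deqn{1 + c_1 < \alpha/\beta < 1 + 2 c_1,}
#' which bounds the coexistence (beak) region of the phase diagram as
#' \eqn{D \to 0}.
#'
#' @param c1 One-dimensional per-site inhibition (positive; vectorized).
#' @return A data frame with columns \code{c1}, \code{lower}
#'   (\eqn{1 + c_1}), \code{upper} (\eqn{1 + 2 c_1}).
#' @examples
#' coexistence_condition(2)  # (3, 5)
#' @export
coexistence_condition <- function(c1) {
  if (any(c1 <= 0)) stop("c1 must be positive")
  data.frame(c1 = c1, lower = 1 + c1, upper = 1 + 2 * c1)
}
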