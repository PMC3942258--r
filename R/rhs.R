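#' Time derivative of the CDI competition model
#'
#' Evaluates the right-hand side of the model at a given state, dispatching
#' on the state's geometry.
#'
#' Well-mixed (0D): \deqn{du/dt = u(\alpha - u - v(1+c)), \quad
#'   dv/dt = v(\beta - u - v).}
#' One dimension, periodic ring of N sites: \deqn{du_i/dt = u_i(\alpha - u_i
#'   - v_i - c_1(v_{i+1} + v_i + v_{i-1})) + (D/\delta^2)(u_{i+1} - 2u_i +
#'   u_{i-1}),} \deqn{dv_i/dt = v_i(\beta - u_i - v_i) +
#'   (D/\delta^2)(v_{i+1} - 2v_i + v_{i-1}),} with \eqn{c_1 = c/3}. Two
#' dimensions: the inhibition sum runs over the site and its four von-Neumann
#' neighbours with weight \eqn{c_2 = c/5}, and diffusion uses the 5-point
#' Laplacian; both axes are periodic.
#'
#' For any spatially uniform state these reduce exactly to the well-mixed
#' form, since \eqn{3c_1 = 5c_2 = c} and the Laplacian of a constant field
#' vanishes.
#'
#' @param state A \code{\link{cdi_state}}.
#' @param params A \code{\link{cdi_params}}; for 1D states
#'   \code{length(state$u)} must equal \code{params$n_grid}.
#' @return A list with fields \code{du} and \code{dv}, the same shape as the
#'   state fields.
#' @examples
#' p <- cdi_params(alpha = 2, beta = 1, c = 2)
#' cdi_rhs(cdi_state(1, 1), p)  # du = -2, dv = -1
#' @export
cdi_rhs <- function(state, params) {
  stopifnot(inherits(state, "cdi_state"), inherits(params, "cdi_params"))
  u <- state$u; v <- state$v
  a <- params$alpha; b <- params$beta; cc <- params$c
  Dd2 <- params$D / params$delta^2
  if (state$dim == 0L) {
    return(list(du = u * (a - u - v * (1 + cc)),
                dv = v * (b - u - v)))
  }
  if (state$dim == 1L) {
    if (length(u) != params$n_grid)
      stop("state length does not match params$n_grid")
    up <- shift1(u, -1); um <- shift1(u, 1)
    vp <- shift1(v, -1); vm <- shift1(v, 1)
    inhib <- if (params$onsite_only) cc * v else params$c1 * (vp + v + vm)
    return(list(du = u * (a - u - v - inhib) + Dd2 * (up - 2 * u + um),
                dv = v * (b - u - v) + Dd2 * (vp - 2 * v + vm)))
  }
  nbr_sum <- function(m) {
    shift2(m, 1, 0) + shift2(m, -1, 0) + shift2(m, 0, 1) + shift2(m, 0, -1)
  }
  inhib <- if (params$onsite_only) cc * v else params$c2 * (v + nbr_sum(v))
  list(du = u * (a - u - v - inhib) + Dd2 * (nbr_sum(u) - 4 * u),
       dv = v * (b - u - v) + Dd2 * (nbr_sum(v) - 4 * v))
}

# cyclic shift of a vector by k positions (k > 0 moves entries forward)
shift1 <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[seq_len(n - k)])
}

# cyclic shift of a matrix by (i, j)
shift2 <- function(m, i, j) {
  r <- shift1(seq_len(nrow(m)), -i)
  s <- shift1(seq_len(ncol(m)), -j)
  m[r, s, drop = FALSE]
}
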