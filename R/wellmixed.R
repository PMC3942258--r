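#' Homogeneous steady states of the well-mixed model
#'
#' The well-mixed competition system has four steady states: total
#' extinction \eqn{(0, 0)}, the two single-species states \eqn{(\alpha, 0)}
#' and \eqn{(0, \beta)}, and the interior coexistence state
#' \eqn{(\beta - (\alpha - \beta)/c,\; (\alpha - \beta)/c)}, which exists in
#' the positive quadrant only for suitable parameters and degenerates when
#' \eqn{c = 0}.
#'
#' @param params A \code{\link{cdi_params}}.
#' @return A data frame with columns \code{name}, \code{u}, \code{v},
#'   \code{feasible} (both coordinates nonnegative). When \code{c == 0} the
#'   interior row is dropped (with a message) because it is undefined.
#' @examples
#' steady_states(cdi_params(alpha = 2, beta = 1, c = 2))  # interior (0.5, 0.5)
#' @export
steady_states <- function(params) {
  stopifnot(inherits(params, "cdi_params"))
  a <- params$alpha; b <- params$beta; cc <- params$c
  out <- data.frame(
    name = c("extinction_both", "u_only", "v_only"),
    u = c(0, a, 0), v = c(0, 0, b), feasible = TRUE,
    stringsAsFactors = FALSE)
  if (cc == 0) {
    message("c = 0: interior steady state undefined; returning 3 states")
    return(out)
  }
  vi <- (a - b) / cc
  ui <- b - vi
  rbind(out, data.frame(name = "interior", u = ui, v = vi,
                        feasible = ui >= 0 && vi >= 0,
                        stringsAsFactors = FALSE))
}

#' Region of the well-mixed phase diagram
#'
#' Partition of the (growth advantage, inhibition) quarter-plane by the
#' linear stability of the two extinction states: the CDI- species alone
#' wins for \eqn{\alpha/\beta > 1 + c}, the CDI+ species alone wins for
#' \eqn{\alpha/\beta < 1}, and for \eqn{1 < \alpha/\beta < 1 + c} both
#' extinction states are stable and the outcome depends on the initial
#' condition. Points exactly on a boundary are labelled \code{"boundary"}.
#'
#' @param ratio Growth advantage \eqn{\alpha/\beta} (vectorized).
#' @param c Total inhibition strength (vectorized, recycled).
#' @return Character vector of labels: \code{"u_always_wins"},
#'   \code{"v_always_wins"}, \code{"bistable"}, or \code{"boundary"}.
#' @export
wellmixed_region <- function(ratio, c) {
  n <- max(length(ratio), length(c))
  ratio <- rep_len(ratio, n); c <- rep_len(c, n)
  out <- rep("boundary", n)
  out[ratio > 1 + c] <- "u_always_wins"
  out[ratio < 1] <- "v_always_wins"
  out[ratio > 1 & ratio < 1 + c] <- "bistable"
  out
}

#' Jacobian of the well-mixed model at a point
#'
#' @param u,v Coordinates at which to evaluate.
#' @param params A \code{\link{cdi_params}}.
#' @return The 2x2 Jacobian matrix.
#' @export
wellmixed_jacobian <- function(u, v, params) {
  a <- params$alpha; b <- params$beta; cc <- params$c
  matrix(c(a - 2 * u - (1 + cc) * v, -u * (1 + cc),
           -v, b - u - 2 * v),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("du", "dv"), c("u", "v")))
}

#' Linear stability classification of the well-mixed steady states
#'
#' Evaluates the 2x2 Jacobian at each homogeneous steady state and
#' classifies it by the real parts of its eigenvalues: \code{"stable"} (all
#' negative), \code{"unstable"} (some positive), \code{"saddle"} (mixed
#' signs), or \code{"marginal"} (an eigenvalue within tolerance of zero).
#'
#' @param params A \code{\link{cdi_params}}.
#' @param tol Tolerance for treating an eigenvalue real part as zero.
#' @return An object of class \code{"cdi_stability"}: a list with
#'   \code{states} (the \code{\link{steady_states}} table augmented with
#'   \code{lambda1}, \code{lambda2}, \code{stability}) and \code{region}
#'   (the \code{\link{wellmixed_region}} label for the parameters).
#' @examples
#' classify_stability(cdi_params(alpha = 2, beta = 1, c = 2))
#' @export
classify_stability <- function(params, tol = 1e-12) {
  ss <- steady_states(params)
  ev <- t(vapply(seq_len(nrow(ss)), function(i) {
    J <- wellmixed_jacobian(ss$u[i], ss$v[i], params)
    sort(Re(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
  }, numeric(2)))
  ss$lambda1 <- ev[, 1]; ss$lambda2 <- ev[, 2]
  ss$stability <- ifelse(
    abs(ev[, 1]) < tol | abs(ev[, 2]) < tol, "marginal",
    ifelse(ev[, 1] < 0, "stable",
           ifelse(ev[, 2] > 0, "unstable", "saddle")))
  structure(list(states = ss,
                 region = wellmixed_region(params$alpha / params$beta,
                                           params$c)),
            class = "cdi_stability")
}

#' @export
print.cdi_stability <- function(x, ...) {
  cat(sprintf("Well-mixed regime: %s\n", x$region))
  print(x$states, digits = 4)
  invisible(x)
}

#' Lyapunov function of the well-mixed model
#'
#' A scalar potential that is non-increasing along every trajectory of the
#' well-mixed system in the nonnegative quadrant:
#' \deqn{V(u, v) = -\alpha u + u^2/2 + (1+c)\left(uv - \beta v +
#'   v^2/2\right),} for which \eqn{dV/dt = -u\,F^2 - (1+c)\,v\,G^2 \le 0}
#' with \eqn{F, G} the per-capita growth rates of u and v. Its restriction
#' to the quadrant has local minima at the two single-species states and, in
#' the bistable regime, a saddle at the interior steady state; the
#' flow-weighted gradient \eqn{(u\,\partial V/\partial u,\; v\,\partial
#' V/\partial v)} vanishes at every steady state.
#'
#' @param params A \code{\link{cdi_params}}.
#' @param u,v Numeric vectors of coordinates; the surface is evaluated on
#'   their outer grid.
#' @return A \code{length(u) x length(v)} matrix of V values.
#' @examples
#' p <- cdi_params(alpha = 2, beta = 1, c = 2)
#' V <- lyapunov_surface(p, seq(0, 2.5, 0.1), seq(0, 1.5, 0.1))
#' @export
lyapunov_surface <- function(params, u, v) {
  stopifnot(inherits(params, "cdi_params"))
  a <- params$alpha; b <- params$beta; cc <- params$c
  outer(u, v, function(u, v)
    -a * u + u^2 / 2 + (1 + cc) * (u * v - b * v + v^2 / 2))
}

#' Lyapunov value at points (vectorized helper)
#'
#' @inheritParams lyapunov_surface
#' @return Numeric vector of V evaluated elementwise.
#' @export
lyapunov_value <- function(params, u, v) {
  a <- params$alpha; b <- params$beta; cc <- params$c
  -a * u + u^2 / 2 + (1 + cc) * (u * v - b * v + v^2 / 2)
}

#' Ensemble of well-mixed competition outcomes
#'
#' Integrates \code{n} random positive initial conditions (u drawn uniformly
#' on \eqn{(0, \alpha)}, v on \eqn{(0, \beta)}) to convergence and records
#' the winner of each competition.
#'
#' @param params A \code{\link{cdi_params}}.
#' @param n Number of trajectories.
#' @param seed Master seed for the initial-condition draws.
#' @param settings \code{\link{integration_settings}}.
#' @return A data frame with one row per trajectory: \code{u0}, \code{v0},
#'   final \code{u}, \code{v}, and \code{winner} (\code{"u"}, \code{"v"}, or
#'   \code{"coexistence"} if neither fell below threshold).
#' @export
wellmixed_ensemble <- function(params, n = 100, seed = 1,
                               settings = integration_settings()) {
  thr <- 1e-4 * max(params$alpha, params$beta)
  seeds <- spawn_seeds(seed, n)
  rows <- lapply(seq_len(n), function(i) {
    ic <- random_ic(params, shape = "wellmixed", seed = seeds[i])
    run <- integrate_cdi(ic, params, settings)
    winner <- if (run$state$v < thr && run$state$u >= thr) "u"
      else if (run$state$u < thr && run$state$v >= thr) "v"
      else "coexistence"
    data.frame(u0 = ic$u, v0 = ic$v, u = run$state$u, v = run$state$v,
               winner = winner, converged = run$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
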