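#' Integration settings
#'
#' Controls for the adaptive Runge-Kutta 4(5) integrator and its convergence
#' rule.
#'
#' A run is declared converged when the maximal per-step state change
#' (max over all sites and both species of \eqn{|\Delta u|, |\Delta v|}),
#' averaged over the \code{convergence_window} most recent accepted steps,
#' falls below \code{convergence_tol_factor} times the largest carrying
#' capacity \eqn{\max(\alpha, \beta)}. Proposed steps that would take any
#' concentration below \code{-max_error_per_step} are rejected and retried
#' with a smaller step; residual negatives within that threshold of zero are
#' set to exactly zero before the next step.
#'
#' @param max_error_per_step Absolute per-step error cap (max-norm over all
#'   state components). Default \code{1e-6}.
#' @param max_step Largest allowed step size. Default \code{0.1}.
#' @param convergence_tol_factor Convergence threshold as a multiple of
#'   \eqn{\max(\alpha, \beta)}. Default \code{1e-8}.
#' @param convergence_window Number of consecutive accepted steps averaged by
#'   the convergence rule. Default \code{1000}.
#' @param max_time Hard cap on integrated dimensionless time; runs that reach
#'   it are flagged unconverged. Default \code{1e6}.
#' @return An object of class \code{"cdi_settings"}.
#' @export
integration_settings <- function(max_error_per_step = 1e-6,
                                 max_step = 1e-1,
                                 convergence_tol_factor = 1e-8,
                                 convergence_window = 1000L,
                                 max_time = 1e6) {
  stopifnot(max_error_per_step > 0, max_step > 0,
            convergence_tol_factor > 0, convergence_window >= 1,
            max_time > 0)
  structure(list(max_error_per_step = max_error_per_step,
                 max_step = max_step,
                 convergence_tol_factor = convergence_tol_factor,
                 convergence_window = as.integer(convergence_window),
                 max_time = max_time),
            class = "cdi_settings")
}

#' Integrate the CDI model to convergence
#'
#' Advances a state under the model dynamics with an embedded Cash-Karp
#' Runge-Kutta 4(5) scheme with proportional step-size control, a hard step
#' cap, negativity clamping, and the windowed convergence rule described in
#' \code{\link{integration_settings}}. The geometry (well-mixed, 1D ring,
#' 2D torus) is taken from the state.
#'
#' @param state Initial \code{\link{cdi_state}}.
#' @param params A \code{\link{cdi_params}}.
#' @param settings An \code{\link{integration_settings}} object.
#' @param save_interval If positive, record state snapshots every
#'   \code{save_interval} time units (for space-time plots); \code{NULL}
#'   (default) records nothing.
#' @return An object of class \code{"cdi_run"}: a list with \code{state}
#'   (final \code{cdi_state}), \code{converged}, \code{n_accepted},
#'   \code{n_rejected}, \code{params}, \code{settings}, and (when snapshots
#'   were requested) \code{trajectory}, a matrix whose first column is time
#'   followed by the flattened u then v fields.
#' @examples
#' p <- cdi_params(alpha = 2, beta = 1, c = 0.5)
#' run <- integrate_cdi(cdi_state(0.1, 0.9), p)
#' run$state$u  # -> 2 (CDI- wins)
#' @export
integrate_cdi <- function(state, params, settings = integration_settings(),
                          save_interval = NULL) {
  stopifnot(inherits(state, "cdi_state"), inherits(params, "cdi_params"),
            inherits(settings, "cdi_settings"))
  if (state$dim == 1L && length(state$u) != params$n_grid)
    stop("state length does not match params$n_grid")
  side <- if (state$dim == 2L) nrow(state$u) else 0L
  res <- integrate_cpp(
    u0 = as.vector(state$u), v0 = as.vector(state$v),
    dim = state$dim, side = side,
    alpha = params$alpha, beta = params$beta, c = params$c,
    D = params$D, delta = params$delta,
    tol = settings$max_error_per_step, hmax = settings$max_step,
    conv_tol = settings$convergence_tol_factor * max(params$alpha, params$beta),
    window = settings$convergence_window,
    max_time = settings$max_time, t0 = state$time,
    save_interval = if (is.null(save_interval)) -1 else save_interval,
    onsite = params$onsite_only)
  u <- res$u; v <- res$v
  if (state$dim == 2L) {
    u <- matrix(u, side, side)
    v <- matrix(v, side, side)
  }
  out <- list(state = cdi_state(u, v, time = res$time),
              converged = res$converged,
              n_accepted = res$n_accepted, n_rejected = res$n_rejected,
              mean_step_change = res$mean_step_change,
              params = params, settings = settings)
  if (!is.null(res$trajectory)) out$trajectory <- res$trajectory
  class(out) <- "cdi_run"
  out
}

#' @export
print.cdi_run <- function(x, ...) {
  cat(sprintf("CDI model run: %s at t = %g (%d accepted / %d rejected steps)\n",
              if (x$converged) "converged" else "NOT converged (max_time hit)",
              x$state$time, x$n_accepted, x$n_rejected))
  print(x$state)
  invisible(x)
}

#' @export
plot.cdi_run <- function(x, ...) {
  if (!is.null(x$trajectory) && x$state$dim == 1L) {
    n <- length(x$state$u)
    graphics::image(x$trajectory[, 1], seq_len(n),
                    x$trajectory[, 2:(n + 1)],
                    xlab = "time", ylab = "site",
                    main = "CDI- concentration u", ...)
  } else {
    plot(x$state, ...)
  }
  invisible(x)
}

#' Write a recorded trajectory to CSV
#'
#' Long-format export of the snapshots recorded by
#' \code{\link{integrate_cdi}} with a \code{save_interval}: columns
#' \code{time}, \code{site}, \code{u}, \code{v}.
#'
#' @param run A \code{cdi_run} carrying a \code{trajectory}.
#' @param path Output CSV file.
#' @return \code{path}, invisibly.
#' @export
write_cdi_trajectory <- function(run, path) {
  stopifnot(inherits(run, "cdi_run"))
  if (is.null(run$trajectory)) stop("run has no recorded trajectory")
  tr <- run$trajectory
  n <- (ncol(tr) - 1L) / 2L
  df <- data.frame(
    time = rep(tr[, 1], each = n),
    site = rep(seq_len(n), times = nrow(tr)),
    u = as.vector(t(tr[, 1 + seq_len(n), drop = FALSE])),
    v = as.vector(t(tr[, 1 + n + seq_len(n), drop = FALSE])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
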