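#' Deterministic child seeds from a master seed
#'
#' Experiments that run many replicates derive one child seed per replicate
#' from a single master seed, so that whole result tables are reproducible
#' from one integer.
#'
#' @param master Master seed (integer).
#' @param n Number of child seeds.
#' @return Integer vector of \code{n} distinct seeds in \code{[1, 2^31 - 2]}.
#' @export
spawn_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Representative two-domain initial conditions (1D)
#'
#' The family of N-1 block initial conditions used to map the coexistence
#' phase boundary: initial condition j places the CDI+ species at its
#' carrying capacity on sites 1..j (\eqn{v_i = \beta}, \eqn{u_i = 0}) and
#' the CDI- species at its carrying capacity on sites j+1..N
#' (\eqn{u_i = \alpha}, \eqn{v_i = 0}), for j = 1, ..., N-1.
#'
#' @param params A \code{\link{cdi_params}}.
#' @param N Number of grid points (defaults to \code{params$n_grid}).
#' @return A list of N-1 \code{\link{cdi_state}} objects, element j holding
#'   initial condition j.
#' @examples
#' ics <- representative_ics_1d(cdi_params(alpha = 3.5, beta = 1, c1 = 2))
#' length(ics)  # 31 for N = 32
#' @export
representative_ics_1d <- function(params, N = params$n_grid) {
  stopifnot(inherits(params, "cdi_params"), N >= 2)
  lapply(seq_len(N - 1), function(j) {
    v <- c(rep(params$beta, j), rep(0, N - j))
    u <- c(rep(0, j), rep(params$alpha, N - j))
    cdi_state(u, v)
  })
}

#' Seeded random initial condition
#'
#' Draws independent uniform concentrations per site, bounded by the
#' carrying capacities: \eqn{u_i \sim U(0, \alpha)} and \eqn{v_i \sim
#' U(0, \beta)}. Identical seeds give identical states. The sampling law is
#' configurable so its influence on ensemble statistics can be probed.
#'
#' @param params A \code{\link{cdi_params}}.
#' @param shape \code{"wellmixed"} (a scalar pair), \code{"1d"} (a ring of
#'   \code{params$n_grid} sites), or \code{"2d"} (a
#'   \code{params$n_grid} x \code{params$n_grid} torus).
#' @param seed Seed for the draw (required, for reproducibility).
#' @param law \code{"uniform"} (default) or a function
#'   \code{function(n, cap)} returning \code{n} nonnegative draws bounded
#'   above in spirit by the carrying capacity \code{cap}.
#' @return A \code{\link{cdi_state}}.
#' @export
random_ic <- function(params, shape = c("1d", "2d", "wellmixed"), seed,
                      law = "uniform") {
  stopifnot(inherits(params, "cdi_params"))
  shape <- match.arg(shape)
  if (missing(seed)) stop("a seed is required for reproducible draws")
  n <- switch(shape, wellmixed = 1L, "1d" = params$n_grid,
              "2d" = params$n_grid^2L)
  draw <- if (is.function(law)) law
    else function(n, cap) stats::runif(n, 0, cap)
  fields <- with_seed(seed, list(u = draw(n, params$alpha),
                                 v = draw(n, params$beta)))
  if (any(fields$u < 0) || any(fields$v < 0))
    stop("sampling law produced negative concentrations")
  if (shape == "2d") {
    fields$u <- matrix(fields$u, params$n_grid, params$n_grid)
    fields$v <- matrix(fields$v, params$n_grid, params$n_grid)
  }
  cdi_state(fields$u, fields$v)
}

#' Nested-square initial condition (2D)
#'
#' A centred square of one species at its carrying capacity surrounded by a
#' sea of the other at its carrying capacity, on a \code{side x side}
#' periodic grid. The family used in the 2D scans ranges the interior from
#' 4 to 256 grid points (interior sides 2 to 16) on a 32 x 32 grid
#' (1024 sites).
#'
#' @param params A \code{\link{cdi_params}}.
#' @param side Grid side length (defaults to \code{params$n_grid}).
#' @param interior Which species fills the interior square: \code{"u"} or
#'   \code{"v"}.
#' @param interior_side Side length of the interior square (so the interior
#'   covers \code{interior_side^2} grid points); must be smaller than
#'   \code{side}.
#' @return A \code{\link{cdi_state}} (2D).
#' @examples
#' p <- cdi_params(alpha = 3.5, beta = 1, c2 = 1, D = 1e-3)
#' ic <- nested_square_ic(p, interior = "u", interior_side = 2)
#' sum(ic$u > 0)  # 4
#' @export
nested_square_ic <- function(params, side = params$n_grid,
                             interior = c("u", "v"), interior_side) {
  stopifnot(inherits(params, "cdi_params"), side >= 3)
  interior <- match.arg(interior)
  interior_side <- as.integer(interior_side)
  if (interior_side < 1) stop("interior square must be at least 1 x 1")
  if (interior_side >= side)
    stop("interior square must be strictly smaller than the grid")
  off <- (side - interior_side) %/% 2
  idx <- off + seq_len(interior_side)
  inner <- matrix(FALSE, side, side)
  inner[idx, idx] <- TRUE
  u <- matrix(0, side, side); v <- matrix(0, side, side)
  if (interior == "u") {
    u[inner] <- params$alpha; v[!inner] <- params$beta
  } else {
    v[inner] <- params$beta; u[!inner] <- params$alpha
  }
  cdi_state(u, v)
}
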