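#' Model parameters for the CDI competition model
#'
#' Bundles the constants of the two-species contact-dependent-inhibition
#' (CDI) competition model: the dimensionless growth rates \code{alpha}
#' (CDI- species, u) and \code{beta} (CDI+ species, v), the total inhibition
#' strength \code{c}, the shared diffusion constant \code{D}, the grid
#' spacing \code{delta} and the grid size \code{n_grid}.
#'
#' The per-site inhibition couplings are derived views of \code{c}, never set
#' independently: \code{c1 = c/3} (one dimension: on-site plus two
#' neighbours) and \code{c2 = c/5} (two dimensions: on-site plus four
#' von-Neumann neighbours). For convenience the inhibition may be supplied as
#' any one of \code{c}, \code{c1} or \code{c2}; exactly one must be given.
#'
#' @param alpha Growth rate of the CDI- species (its carrying capacity in
#'   nondimensional units). Must be positive.
#' @param beta Growth rate of the CDI+ species. Must be positive.
#' @param c Total inhibition strength (\code{c >= 0}).
#' @param c1 One-dimensional per-site inhibition; sets \code{c = 3*c1}.
#' @param c2 Two-dimensional per-site inhibition; sets \code{c = 5*c2}.
#' @param D Diffusion constant, shared by both species (\code{D >= 0}).
#' @param delta Grid spacing. The default \code{10/n_grid} discretizes a
#'   nondimensional domain of length 10 (so \code{delta = 0.3125} on the
#'   standard 32-point grid); only \code{D/delta^2} enters the dynamics, and
#'   stripe widths are reported in these space units.
#' @param n_grid Number of grid points (1D) or side length (2D); at least 3.
#' @param onsite_only If \code{TRUE}, collapse the inhibition kernel to the
#'   site itself with full weight \code{c} (a control that removes the
#'   nearest-neighbour character of CDI while keeping its total strength).
#' @return An object of class \code{"cdi_params"}: a list with elements
#'   \code{alpha}, \code{beta}, \code{c}, \code{c1}, \code{c2}, \code{D},
#'   \code{delta}, \code{n_grid}, \code{onsite_only}.
#' @examples
#' p <- cdi_params(alpha = 3.5, beta = 1, c1 = 2.0, D = 1e-3)
#' p$c   # 6
#' p$c2  # 1.2
#' @export
cdi_params <- function(alpha, beta, c = NULL, c1 = NULL, c2 = NULL,
                       D = 0, delta = NULL, n_grid = 32,
                       onsite_only = FALSE) {
  given <- !vapply(list(c, c1, c2), is.null, logical(1))
  if (sum(given) != 1L)
    stop("supply exactly one of `c`, `c1`, `c2`")
  if (!is.null(c1)) c <- 3 * c1
  if (!is.null(c2)) c <- 5 * c2
  if (is.null(delta)) delta <- 10 / n_grid
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(delta), length(delta) == 1L)
  if (alpha <= 0 || beta <= 0) stop("growth rates alpha, beta must be > 0")
  if (c < 0) stop("inhibition strength c must be >= 0")
  if (D < 0) stop("diffusion constant D must be >= 0")
  if (delta <= 0) stop("grid spacing delta must be > 0")
  n_grid <- as.integer(n_grid)
  if (n_grid < 3L) stop("n_grid must be >= 3")
  structure(
    list(alpha = alpha, beta = beta, c = c, c1 = c / 3, c2 = c / 5,
         D = D, delta = delta, n_grid = n_grid,
         onsite_only = isTRUE(onsite_only)),
    class = "cdi_params")
}

#' @export
print.cdi_params <- function(x, ...) {
  cat("CDI competition model parameters\n")
  cat(sprintf("  growth rates:  alpha = %g (CDI-), beta = %g (CDI+), alpha/beta = %g\n",
              x$alpha, x$beta, x$alpha / x$beta))
  cat(sprintf("  inhibition:    c = %g (c1 = %g, c2 = %g)%s\n",
              x$c, x$c1, x$c2,
              if (x$onsite_only) " [on-site-only kernel]" else ""))
  cat(sprintf("  diffusion:     D = %g, grid spacing delta = %g\n", x$D, x$delta))
  cat(sprintf("  grid:          n_grid = %d\n", x$n_grid))
  invisible(x)
}

#' Serialize parameters to a flat key-value config
#'
#' @param params A \code{\link{cdi_params}} object.
#' @param path File to write; one \code{key = value} per line.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_cdi_params}}
#' @export
write_cdi_params <- function(params, path) {
  stopifnot(inherits(params, "cdi_params"))
  keys <- c("alpha", "beta", "c", "D", "delta", "n_grid", "onsite_only")
  vals <- vapply(params[keys], function(v) format(v, digits = 17), character(1))
  writeLines(paste(keys, vals, sep = " = "), path)
  invisible(path)
}

#' Read parameters from a flat key-value config
#'
#' @param path File written by \code{\link{write_cdi_params}} (or hand-edited
#'   in the same \code{key = value} format).
#' @return A \code{\link{cdi_params}} object.
#' @export
read_cdi_params <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  cdi_params(alpha = as.numeric(vals[["alpha"]]),
             beta = as.numeric(vals[["beta"]]),
             c = as.numeric(vals[["c"]]),
             D = as.numeric(vals[["D"]]),
             delta = as.numeric(vals[["delta"]]),
             n_grid = as.integer(as.numeric(vals[["n_grid"]])),
             onsite_only = as.logical(vals[["onsite_only"]]))
}
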