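#' Population state on a 0D, 1D, or 2D periodic grid
#'
#' A pair of nonnegative concentration fields: \code{u} for the CDI-
#' (inhibition-deficient) species and \code{v} for the CDI+ (inhibition-
#' equipped) species. Both fields must have identical shape: scalars
#' (well-mixed), equal-length vectors (a periodic ring), or equal-dimension
#' square matrices (a periodic torus). Spatial indexing is periodic in every
#' dimension.
#'
#' @param u Nonnegative numeric scalar, vector, or square matrix.
#' @param v Same shape as \code{u}.
#' @param time Elapsed dimensionless time carried with the state.
#' @return An object of class \code{"cdi_state"} with elements \code{u},
#'   \code{v}, \code{time}, and \code{dim} (0, 1, or 2).
#' @examples
#' cdi_state(u = rep(3.5, 32), v = rep(0, 32))
#' @export
cdi_state <- function(u, v, time = 0) {
  if (is.matrix(u) || is.matrix(v)) {
    if (!is.matrix(u) || !is.matrix(v) || !identical(dim(u), dim(v)))
      stop("u and v must have identical shape")
    if (nrow(u) != ncol(u)) stop("2D fields must be square")
    d <- 2L
  } else {
    if (length(u) != length(v)) stop("u and v must have identical shape")
    d <- if (length(u) == 1L) 0L else 1L
  }
  if (anyNA(u) || anyNA(v) || any(u < 0) || any(v < 0))
    stop("concentrations must be nonnegative and non-missing")
  structure(list(u = u, v = v, time = time, dim = d), class = "cdi_state")
}

#' @export
print.cdi_state <- function(x, ...) {
  geom <- switch(as.character(x$dim),
                 "0" = "well-mixed",
                 "1" = sprintf("1D ring of %d sites", length(x$u)),
                 "2" = sprintf("2D torus %d x %d", nrow(x$u), ncol(x$u)))
  cat(sprintf("CDI population state (%s), time = %g\n", geom, x$time))
  cat(sprintf("  u (CDI-): mean %.4g, max %.4g\n", mean(x$u), max(x$u)))
  cat(sprintf("  v (CDI+): mean %.4g, max %.4g\n", mean(x$v), max(x$v)))
  invisible(x)
}

#' @export
plot.cdi_state <- function(x, ...) {
  if (x$dim == 2L) {
    graphics::image(seq_len(nrow(x$u)), seq_len(ncol(x$u)), x$u,
                    xlab = "row", ylab = "col",
                    main = "CDI- concentration u", ...)
  } else {
    n <- length(x$u)
    graphics::plot(seq_len(n), x$u, type = "s", col = "steelblue",
                   ylim = range(0, x$u, x$v), xlab = "site",
                   ylab = "concentration", ...)
    graphics::lines(seq_len(n), x$v, type = "s", col = "darkorange")
    graphics::legend("topright", legend = c("u (CDI-)", "v (CDI+)"),
                     col = c("steelblue", "darkorange"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Write a state snapshot to CSV
#'
#' One row per site with columns \code{site} (1D) or \code{row,col} (2D)
#' plus \code{u} and \code{v}.
#'
#' @param state A \code{\link{cdi_state}}.
#' @param path Output CSV file.
#' @return \code{path}, invisibly.
#' @export
write_cdi_state <- function(state, path) {
  stopifnot(inherits(state, "cdi_state"))
  df <- as.data.frame(state)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.cdi_state <- function(x, ...) {
  if (x$dim == 2L) {
    n <- nrow(x$u)
    data.frame(row = rep(seq_len(n), times = n),
               col = rep(seq_len(n), each = n),
               u = as.vector(x$u), v = as.vector(x$v))
  } else {
    data.frame(site = seq_along(x$u), u = as.vector(x$u), v = as.vector(x$v))
  }
}
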