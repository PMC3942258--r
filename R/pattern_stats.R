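#' Per-site dominant species labels
#'
#' Labels each grid point by its dominant species: \code{"u"} where
#' \eqn{u_i > v_i}, otherwise \code{"v"}.
#'
#' @param state A converged \code{\link{cdi_state}} (1D or 2D).
#' @return Character vector (1D) or matrix (2D) of \code{"u"}/\code{"v"}
#'   labels.
#' @export
dominant_species <- function(state) {
  stopifnot(inherits(state, "cdi_state"))
  lab <- ifelse(state$u > state$v, "u", "v")
  if (state$dim == 2L) lab <- matrix(lab, nrow(state$u), ncol(state$u))
  lab
}

#' Run lengths of dominance stripes on a periodic ring
#'
#' Maximal runs of identical labels under periodic wraparound; a run that
#' spans the seam (site N back to site 1) is counted once with its full
#' length.
#'
#' @param labels Character vector of per-site labels (from
#'   \code{\link{dominant_species}}).
#' @return A list with components \code{u} and \code{v}: integer vectors of
#'   stripe widths (grid points) for each species, empty when the species
#'   dominates nowhere.
#' @examples
#' stripe_widths(rep(c("u", "v"), c(9, 23)))  # u: 9, v: 23
#' @export
stripe_widths <- function(labels) {
  n <- length(labels)
  r <- rle(labels)
  if (length(r$lengths) > 1L && r$values[1] == r$values[length(r$values)]) {
    # merge the run spanning the periodic seam
    r$lengths[1] <- r$lengths[1] + r$lengths[length(r$lengths)]
    r$lengths <- r$lengths[-length(r$lengths)]
    r$values <- r$values[-length(r$values)]
  }
  list(u = unname(r$lengths[r$values == "u"]),
       v = unname(r$lengths[r$values == "v"]))
}

#' Classify a converged state into a pattern record
#'
#' A species is extinct when its maximum concentration falls below
#' \code{threshold_factor * max(alpha, beta)} everywhere. States where both
#' species survive are coexistence patterns, categorized by the number of
#' distinct CDI- (u) domains under periodic wraparound: one
#' (\code{single_stripe}), two (\code{double_stripe}), or three or more
#' (\code{multi_stripe}). Stripe widths for both species and the fraction of
#' sites dominated by u are recorded. Classification is invariant under
#' cyclic shifts of the state.
#'
#' @param state A converged \code{\link{cdi_state}}.
#' @param params The \code{\link{cdi_params}} of the run (for carrying
#'   capacities).
#' @param threshold_factor Extinction threshold as a fraction of the largest
#'   carrying capacity. Default \code{1e-4}: far above integration
#'   tolerances, far below any patterned amplitude.
#' @param seed Optional provenance (the IC seed) stored in the record.
#' @return An object of class \code{"cdi_pattern"}: a list with
#'   \code{category} (one of \code{extinction_u}, \code{extinction_v},
#'   \code{single_stripe}, \code{double_stripe}, \code{multi_stripe}),
#'   \code{u_stripes}, \code{v_stripes} (width vectors, 1D only),
#'   \code{u_occupancy}, and \code{seed}.
#' @export
classify_pattern <- function(state, params, threshold_factor = 1e-4,
                             seed = NA_integer_) {
  stopifnot(inherits(state, "cdi_state"), inherits(params, "cdi_params"))
  thr <- threshold_factor * max(params$alpha, params$beta)
  u_ext <- max(state$u) < thr
  v_ext <- max(state$v) < thr
  lab <- dominant_species(state)
  occ <- mean(lab == "u")
  if (u_ext || v_ext) {
    cat_ <- if (u_ext && v_ext) "extinction_both"
      else if (u_ext) "extinction_u" else "extinction_v"
    rec <- list(category = cat_, u_stripes = integer(0),
                v_stripes = integer(0),
                u_occupancy = if (u_ext) 0 else 1, seed = seed)
  } else if (state$dim == 1L) {
    sw <- stripe_widths(lab)
    k <- length(sw$u)
    cat_ <- if (k == 1L) "single_stripe"
      else if (k == 2L) "double_stripe" else "multi_stripe"
    rec <- list(category = cat_, u_stripes = sw$u, v_stripes = sw$v,
                u_occupancy = occ, seed = seed)
  } else {
    rec <- list(category = "coexistence", u_stripes = integer(0),
                v_stripes = integer(0), u_occupancy = occ, seed = seed)
  }
  structure(rec, class = "cdi_pattern")
}

#' @export
print.cdi_pattern <- function(x, ...) {
  cat(sprintf("CDI pattern: %s (u occupancy %.3f)\n", x$category,
              x$u_occupancy))
  if (length(x$u_stripes))
    cat("  u stripes:", paste(x$u_stripes, collapse = ", "),
        "| v stripes:", paste(x$v_stripes, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate ensemble statistics over pattern records
#'
#' Category relative abundances (fractions of all records) and stripe-width
#' statistics pooled over all u-stripes of the records in each coexistence
#' category (each stripe is one observation, so multi-stripe categories show
#' the larger spread seen when domains of different sizes coexist in one
#' state).
#'
#' @param records A list of \code{\link{classify_pattern}} records.
#' @param delta Grid spacing used to convert stripe widths from grid points
#'   to space units (default 1 leaves them in grid points; pass
#'   \code{params$delta} for table-style widths).
#' @return An object of class \code{"cdi_ensemble_stats"}: a data frame with
#'   one row per category present: \code{category}, \code{n},
#'   \code{abundance}, \code{width_mean}, \code{width_sd} (NA for
#'   extinction categories), plus attributes \code{n_records} and
#'   \code{v_width_mean} per category for symmetry checks.
#' @export
ensemble_stats <- function(records, delta = 1) {
  if (!length(records)) stop("no records supplied")
  cats <- vapply(records, `[[`, character(1), "category")
  lev <- c("extinction_u", "extinction_v", "extinction_both",
           "single_stripe", "double_stripe", "multi_stripe", "coexistence")
  tab <- table(factor(cats, levels = lev))
  present <- names(tab)[tab > 0]
  rows <- lapply(present, function(cg) {
    idx <- which(cats == cg)
    uw <- unlist(lapply(records[idx], `[[`, "u_stripes")) * delta
    vw <- unlist(lapply(records[idx], `[[`, "v_stripes")) * delta
    data.frame(category = cg, n = length(idx),
               abundance = length(idx) / length(records),
               width_mean = if (length(uw)) mean(uw) else NA_real_,
               width_sd = if (length(uw) > 1) stats::sd(uw) else NA_real_,
               v_width_mean = if (length(vw)) mean(vw) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_records") <- length(records)
  class(out) <- c("cdi_ensemble_stats", class(out))
  out
}

#' Mean 2D occupancy of the CDI- species
#'
#' Mean over records of the fraction of grid points dominated by the CDI-
#' species u (extinction runs contribute 0 or 1).
#'
#' @param records A list of \code{\link{classify_pattern}} records from 2D
#'   runs.
#' @return A list with \code{mean}, \code{sd} (run-to-run spread), and
#'   \code{n}.
#' @export
occupancy_fraction_2d <- function(records) {
  occ <- vapply(records, `[[`, numeric(1), "u_occupancy")
  list(mean = mean(occ), sd = stats::sd(occ), n = length(occ))
}

#' Pattern records as a tidy data frame
#'
#' @param records A list of \code{\link{classify_pattern}} records.
#' @return Data frame with one row per record: \code{seed},
#'   \code{category}, \code{u_occupancy}, and stripe widths as
#'   semicolon-delimited strings.
#' @export
pattern_records_df <- function(records) {
  do.call(rbind, lapply(records, function(r)
    data.frame(seed = r$seed, category = r$category,
               u_occupancy = r$u_occupancy,
               u_stripes = paste(r$u_stripes, collapse = ";"),
               v_stripes = paste(r$v_stripes, collapse = ";"),
               stringsAsFactors = FALSE)))
}
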