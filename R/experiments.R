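#' Run and classify an ensemble of random initial conditions
#'
#' The workhorse behind all ensemble statistics: integrates \code{n}
#' seeded random initial conditions to convergence and classifies each
#' converged state. Unconverged runs (those that hit \code{max_time}) are
#' kept separate so they bias no statistic.
#'
#' @param params A \code{\link{cdi_params}}.
#' @param n Number of replicates.
#' @param seed Master seed; replicate seeds are spawned deterministically.
#' @param shape Passed to \code{\link{random_ic}} (\code{"1d"} or
#'   \code{"2d"}).
#' @param settings \code{\link{integration_settings}}.
#' @param threshold_factor Extinction threshold factor for classification.
#' @return A list with \code{records} (classified converged runs),
#'   \code{n_unconverged}, and \code{seeds}.
#' @export
run_random_ensemble <- function(params, n, seed, shape = "1d",
                                settings = integration_settings(),
                                threshold_factor = 1e-4) {
  seeds <- spawn_seeds(seed, n)
  records <- vector("list", n)
  bad <- 0L
  for (i in seq_len(n)) {
    run <- integrate_cdi(random_ic(params, shape, seeds[i]), params, settings)
    if (!run$converged) { bad <- bad + 1L; next }
    records[[i]] <- classify_pattern(run$state, params, threshold_factor,
                                     seed = seeds[i])
  }
  list(records = Filter(Negate(is.null), records),
       n_unconverged = bad, seeds = seeds)
}

#' 1D coexistence phase-diagram scan
#'
#' For each (growth advantage, inhibition, diffusion) combination, runs the
#' representative two-domain initial conditions
#' (\code{\link{representative_ics_1d}}) to convergence and marks the point
#' as coexistence-capable if at least one initial condition converges to a
#' state with both species above the extinction threshold.
#'
#' @param ratios Growth advantages \eqn{\alpha/\beta} to scan (\eqn{\beta}
#'   is fixed at 1 so \eqn{\alpha} carries the ratio).
#' @param c1s Inhibition values \eqn{c_1} to scan.
#' @param Ds Diffusion constants to scan.
#' @param N Grid size (default 32).
#' @param settings \code{\link{integration_settings}}.
#' @param early_exit Stop testing initial conditions at a parameter point
#'   once one coexistence outcome is found (default TRUE; only the
#'   \code{coexistence} flag and not \code{n_coexist} is then exhaustive).
#' @return Data frame of phase points: \code{ratio}, \code{c1}, \code{D},
#'   \code{coexistence} (logical), \code{n_coexist}, \code{n_tested},
#'   \code{n_unconverged}.
#' @export
scan_phase_diagram_1d <- function(ratios = seq(1, 5, by = 0.1),
                                  c1s = seq(0.1, 4, by = 0.1),
                                  Ds = c(1e-4, 1e-3, 1e-2),
                                  N = 32,
                                  settings = integration_settings(),
                                  early_exit = TRUE) {
  grid <- expand.grid(ratio = ratios, c1 = c1s, D = Ds,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    p <- cdi_params(alpha = grid$ratio[g], beta = 1, c1 = grid$c1[g],
                    D = grid$D[g], n_grid = N)
    thr <- 1e-4 * max(p$alpha, p$beta)
    ics <- representative_ics_1d(p, N)
    nco <- 0L; nbad <- 0L; ntest <- 0L
    for (ic in ics) {
      ntest <- ntest + 1L
      run <- integrate_cdi(ic, p, settings)
      if (!run$converged) { nbad <- nbad + 1L; next }
      if (max(run$state$u) >= thr && max(run$state$v) >= thr) {
        nco <- nco + 1L
        if (early_exit) break
      }
    }
    data.frame(ratio = grid$ratio[g], c1 = grid$c1[g], D = grid$D[g],
               coexistence = nco > 0L, n_coexist = nco, n_tested = ntest,
               n_unconverged = nbad)
  })
  do.call(rbind, res)
}

#' Numerical coexistence interval in growth advantage
#'
#' Scans the growth advantage at fixed inhibition and diffusion with the
#' representative initial conditions and returns the range of scanned values
#' showing coexistence, for comparison against the analytic slow-diffusion
#' interval \code{\link{coexistence_condition}}.
#'
#' @param c1 Inhibition.
#' @param D Diffusion constant.
#' @param ratios Growth advantages to scan.
#' @param N Grid size.
#' @param settings \code{\link{integration_settings}}.
#' @return List with \code{lower}, \code{upper} (NA when no coexistence
#'   found) and the full \code{scan} data frame.
#' @export
coexistence_interval_1d <- function(c1, D, ratios = seq(2.5, 5.5, by = 0.1),
                                    N = 32,
                                    settings = integration_settings()) {
  scan <- scan_phase_diagram_1d(ratios = ratios, c1s = c1, Ds = D, N = N,
                                settings = settings)
  hit <- scan$ratio[scan$coexistence]
  list(lower = if (length(hit)) min(hit) else NA_real_,
       upper = if (length(hit)) max(hit) else NA_real_,
       scan = scan)
}

#' Ensemble-statistics sweep over a parameter
#'
#' Reproduces the abundance/width tables: at each value of the swept
#' parameter (inhibition \code{c1} or growth advantage \code{ratio}), runs a
#' random-initial-condition ensemble and aggregates it with
#' \code{\link{ensemble_stats}}.
#'
#' @param sweep Named list with one element, \code{c1} or \code{ratio},
#'   giving the values to sweep.
#' @param ratio,c1 The fixed value of the parameter not swept.
#' @param D Diffusion constant.
#' @param n Replicates per sweep point.
#' @param seed Master seed (each sweep point gets an independent child
#'   seed).
#' @param N Grid size.
#' @param settings \code{\link{integration_settings}}.
#' @return A list (one element per sweep value) of lists with \code{value},
#'   \code{stats} (\code{\link{ensemble_stats}}), \code{records}, and
#'   \code{n_unconverged}.
#' @export
abundance_sweep <- function(sweep, ratio = 3.5, c1 = 2.0, D = 1e-3,
                            n = 1000, seed = 1, N = 32,
                            settings = integration_settings()) {
  stopifnot(is.list(sweep), length(sweep) == 1L,
            names(sweep) %in% c("c1", "ratio"))
  vals <- sweep[[1]]
  seeds <- spawn_seeds(seed, length(vals))
  lapply(seq_along(vals), function(i) {
    if (names(sweep) == "c1") c1 <- vals[i] else ratio <- vals[i]
    p <- cdi_params(alpha = ratio, beta = 1, c1 = c1, D = D, n_grid = N)
    ens <- run_random_ensemble(p, n, seeds[i], "1d", settings)
    list(value = vals[i], stats = ensemble_stats(ens$records, p$delta),
         records = ens$records, n_unconverged = ens$n_unconverged)
  })
}

#' Diffusion-driven destruction of localized patterns
#'
#' Integrates one fixed seeded random initial condition under increasing
#' diffusion constants. Diffusion merges and eventually destroys localized
#' stripes, so the number of surviving CDI- stripes is non-increasing along
#' the sequence and large diffusion ends in the extinction of one species.
#'
#' @param ratio,c1 Growth advantage and inhibition (defaults: the patterned
#'   regime 3.5 and 2.1).
#' @param Ds Increasing diffusion constants.
#' @param seed Seed of the shared initial condition.
#' @param N Grid size.
#' @param settings \code{\link{integration_settings}}.
#' @param save_interval Optional snapshot interval for space-time plots.
#' @return Data frame with one row per D: \code{D}, \code{category},
#'   \code{n_u_stripes}, \code{coexistence}, plus attribute \code{"runs"}
#'   (the \code{cdi_run} objects).
#' @export
diffusion_demo <- function(ratio = 3.5, c1 = 2.1,
                           Ds = c(1e-3, 1e-2, 1e-1), seed = 1, N = 32,
                           settings = integration_settings(),
                           save_interval = NULL) {
  runs <- list(); rows <- list()
  for (i in seq_along(Ds)) {
    p <- cdi_params(alpha = ratio, beta = 1, c1 = c1, D = Ds[i], n_grid = N)
    ic <- random_ic(p, "1d", seed)   # same seed => same field for every D
    run <- integrate_cdi(ic, p, settings, save_interval = save_interval)
    rec <- classify_pattern(run$state, p, seed = seed)
    runs[[i]] <- run
    rows[[i]] <- data.frame(
      D = Ds[i], category = rec$category,
      n_u_stripes = length(rec$u_stripes),
      coexistence = !startsWith(rec$category, "extinction"))
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  out
}

#' 2D scan over inhibition with nested-square initial conditions
#'
#' For each value of the 2D inhibition \code{c2}, runs both nested-square
#' initial-condition families (interior u in a sea of v, and the mirrored
#' set) over a range of interior sizes, and counts how many initial
#' conditions converge to a stable two-species pattern.
#'
#' @param c2s Inhibition values \eqn{c_2} to scan.
#' @param ratio Growth advantage (beta fixed at 1).
#' @param D Diffusion constant.
#' @param side Grid side length.
#' @param interior_sides Interior square side lengths for both families.
#' @param settings \code{\link{integration_settings}}.
#' @return Data frame: \code{c2}, \code{count_u_inside},
#'   \code{count_v_inside}, \code{overlap} (both families produced at least
#'   one stable pattern), \code{n_unconverged}.
#' @export
scan_2d <- function(c2s, ratio = 3.5, D = 1e-3, side = 32,
                    interior_sides = seq(2, 16, by = 2),
                    settings = integration_settings()) {
  res <- lapply(c2s, function(c2) {
    p <- cdi_params(alpha = ratio, beta = 1, c2 = c2, D = D, n_grid = side)
    thr <- 1e-4 * max(p$alpha, p$beta)
    counts <- c(u = 0L, v = 0L); nbad <- 0L
    for (sp in c("u", "v")) {
      for (s in interior_sides) {
        ic <- nested_square_ic(p, side, interior = sp, interior_side = s)
        run <- integrate_cdi(ic, p, settings)
        if (!run$converged) { nbad <- nbad + 1L; next }
        if (max(run$state$u) >= thr && max(run$state$v) >= thr)
          counts[sp] <- counts[sp] + 1L
      }
    }
    data.frame(c2 = c2, count_u_inside = counts[["u"]],
               count_v_inside = counts[["v"]],
               overlap = all(counts > 0L), n_unconverged = nbad)
  })
  do.call(rbind, res)
}

#' 2D occupancy ensemble
#'
#' Random-initial-condition ensemble on the 2D torus; reports the mean
#' fraction of space occupied by the CDI- species.
#'
#' @param c2 Inhibition \eqn{c_2}.
#' @param ratio Growth advantage.
#' @param D Diffusion constant.
#' @param n Number of random initial conditions.
#' @param seed Master seed.
#' @param side Grid side length.
#' @param settings \code{\link{integration_settings}}.
#' @return A list with \code{occupancy} (see
#'   \code{\link{occupancy_fraction_2d}}), \code{records}, and
#'   \code{n_unconverged}.
#' @export
occupancy_ensemble_2d <- function(c2, ratio = 3.5, D = 1e-3, n = 20,
                                  seed = 1, side = 32,
                                  settings = integration_settings()) {
  p <- cdi_params(alpha = ratio, beta = 1, c2 = c2, D = D, n_grid = side)
  ens <- run_random_ensemble(p, n, seed, "2d", settings)
  list(occupancy = occupancy_fraction_2d(ens$records),
       records = ens$records, n_unconverged = ens$n_unconverged)
}
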