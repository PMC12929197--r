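#' Empirical electron-tunneling rate-law constants
#'
#' Parameters of the empirical single-step tunneling ruler for intraprotein
#' and interprotein electron transfer.  At van-der-Waals contact (3.6
#' angstroms) and optimal driving force the log10 rate is 13.0; the rate
#' falls off with edge-to-edge distance at (1.2 - 0.8 rho) decades per
#' angstrom, where rho is the packing density of the intervening protein
#' medium, and with driving force through a Marcus-type Franck-Condon term
#' with coefficient 3.1 per eV.  Uphill (endergonic) transfer pays an
#' additional Boltzmann penalty of one decade per 0.06 eV.
#'
#' @param lambda_reorg reorganization energy in eV (default 0.65, the value
#'   proposed for a cellular environment).
#' @param rho packing density, dimensionless in \[0, 1\] (default 0.76,
#'   accounting for protein heterogeneity).
#' @param intercept log10 rate (s^-1) at contact and optimal driving force.
#' @param slope_a,slope_b distance-decay coefficients: the decay is
#'   `slope_a - slope_b * rho` decades per angstrom.
#' @param contact_distance van-der-Waals contact distance in angstroms.
#' @param franck_condon_coeff coefficient of the (dG + lambda)^2 / lambda
#'   term, in decades per eV.
#' @param thermal_factor eV per decade for the endergonic penalty.
#' @return A `tunneling_params` object.
#' @examples
#' p <- tunneling_params()
#' p$lambda_reorg
#' @export
tunneling_params <- function(lambda_reorg = 0.65, rho = 0.76,
                             intercept = 13.0, slope_a = 1.2, slope_b = 0.8,
                             contact_distance = 3.6,
                             franck_condon_coeff = 3.1,
                             thermal_factor = 0.06) {
  stopifnot(is.finite(lambda_reorg), lambda_reorg > 0,
            is.finite(rho), rho >= 0, rho <= 1,
            is.finite(intercept), is.finite(slope_a), is.finite(slope_b),
            is.finite(contact_distance), contact_distance > 0,
            is.finite(franck_condon_coeff), is.finite(thermal_factor),
            thermal_factor > 0)
  structure(list(lambda_reorg = lambda_reorg, rho = rho,
                 intercept = intercept, slope_a = slope_a, slope_b = slope_b,
                 contact_distance = contact_distance,
                 franck_condon_coeff = franck_condon_coeff,
                 thermal_factor = thermal_factor),
            class = "tunneling_params")
}

#' @export
print.tunneling_params <- function(x, ...) {
  cat(sprintf(paste0("<tunneling_params> lambda = %.2f eV, rho = %.2f, ",
                     "intercept = %.1f, decay = %.3f /A, contact = %.1f A\n"),
              x$lambda_reorg, x$rho, x$intercept,
              x$slope_a - x$slope_b * x$rho, x$contact_distance))
  invisible(x)
}

#' Driving force of electron transfer from midpoint potentials
#'
#' dG0 (eV) = (E_donor - E_acceptor) / 1000 with potentials in mV.  Negative
#' when the acceptor potential is higher (downhill, exergonic); positive when
#' transfer is uphill (endergonic).
#'
#' @param donor_potential_mV,acceptor_potential_mV midpoint potentials in mV.
#' @return Driving force in eV (vectorised).
#' @examples
#' driving_force(-321, -415)  # uphill: +0.094 eV
#' @export
driving_force <- function(donor_potential_mV, acceptor_potential_mV) {
  stopifnot(all(is.finite(donor_potential_mV)),
            all(is.finite(acceptor_potential_mV)))
  (donor_potential_mV - acceptor_potential_mV) / 1000
}

#' Empirical log10 electron-tunneling rate
#'
#' Evaluates the tunneling ruler at edge-to-edge distance R and driving force
#' dG0.  For exergonic transfer (dG0 <= 0):
#' \deqn{\log_{10} k = 13.0 - (1.2 - 0.8\rho)(R - 3.6) -
#'   3.1(\Delta G + \lambda)^2/\lambda}
#' and for endergonic transfer (dG0 > 0) the same expression with dG0 negated
#' in the Franck-Condon term plus an uphill penalty of dG0 / 0.06 decades.
#' The two branches are continuous at dG0 = 0.
#'
#' @param R edge-to-edge distance(s) in angstroms; values below the contact
#'   distance are permitted with a warning.
#' @param delta_g driving force(s) in eV.
#' @param params a [tunneling_params()] object.
#' @return A data frame (class `tunneling_result`) with columns `R`,
#'   `delta_g`, `regime`, `log10_rate`, `rate`.
#' @examples
#' log10_tunneling_rate(3.6, -0.65)$log10_rate  # 13.0 at contact, dG = -lambda
#' @export
log10_tunneling_rate <- function(R, delta_g, params = tunneling_params()) {
  stopifnot(inherits(params, "tunneling_params"),
            all(is.finite(R)), all(is.finite(delta_g)))
  n <- max(length(R), length(delta_g))
  R <- rep_len(R, n); delta_g <- rep_len(delta_g, n)
  if (any(R < params$contact_distance))
    warning("distance below van-der-Waals contact (",
            params$contact_distance, " A); rate extrapolated")
  decay <- params$slope_a - params$slope_b * params$rho
  dist_term <- decay * (R - params$contact_distance)
  endergonic <- delta_g > 0
  g_eff <- ifelse(endergonic, -delta_g, delta_g)
  fc <- params$franck_condon_coeff * (g_eff + params$lambda_reorg)^2 /
    params$lambda_reorg
  lg <- params$intercept - dist_term - fc -
    ifelse(endergonic, delta_g / params$thermal_factor, 0)
  structure(data.frame(R = R, delta_g = delta_g,
                       regime = ifelse(endergonic, "endergonic", "exergonic"),
                       log10_rate = lg, rate = 10^lg,
                       stringsAsFactors = FALSE),
            class = c("tunneling_result", "data.frame"))
}

#' Tunneling-rate grid over donor potential and cofactor distance
#'
#' Evaluates the tunneling ruler on the full cross of donor midpoint
#' potentials (default -1000 to -200 mV in 25 mV steps, 33 values) and
#' edge-to-edge distances (default 4 to 20 angstroms in 1 angstrom steps,
#' 17 values) for a fixed acceptor potential.  Used to ask how far a carrier's
#' potential or docking distance would have to move to reach a target rate.
#'
#' @param acceptor_potential_mV Fe-protein midpoint potential in mV
#'   (default -415).
#' @param params a [tunneling_params()] object.
#' @param potentials donor potential grid in mV.
#' @param distances distance grid in angstroms.
#' @return A `rate_grid`: a potentials x distances matrix of log10 rates with
#'   the grids and acceptor potential as attributes.
#' @examples
#' g <- build_rate_grid()
#' dim(g)  # 33 x 17
#' @export
build_rate_grid <- function(acceptor_potential_mV = -415,
                            params = tunneling_params(),
                            potentials = seq(-1000, -200, by = 25),
                            distances = seq(4, 20, by = 1)) {
  stopifnot(length(potentials) > 0, length(distances) > 0)
  dg <- driving_force(potentials, acceptor_potential_mV)
  m <- outer(dg, distances,
             function(g, r) log10_tunneling_rate(r, g, params)$log10_rate)
  dimnames(m) <- list(potential_mV = as.character(potentials),
                      distance_A = as.character(distances))
  structure(m, potentials = potentials, distances = distances,
            acceptor_potential_mV = acceptor_potential_mV, params = params,
            class = c("rate_grid", "matrix"))
}

#' @export
print.rate_grid <- function(x, ...) {
  p <- attr(x, "potentials"); d <- attr(x, "distances")
  cat(sprintf("<rate_grid> %d potentials (%g..%g mV) x %d distances (%g..%g A), acceptor %g mV\n",
              length(p), min(p), max(p), length(d), min(d), max(d),
              attr(x, "acceptor_potential_mV")))
  cat("log10 rate range:", sprintf("%.2f .. %.2f", min(x), max(x)), "\n")
  invisible(x)
}

#' @export
as.data.frame.rate_grid <- function(x, ...) {
  p <- attr(x, "potentials"); d <- attr(x, "distances")
  data.frame(potential_mV = rep(p, times = length(d)),
             distance_A = rep(d, each = length(p)),
             log10_rate = as.vector(unclass(x)))
}

#' Plot a rate grid as a family of distance curves
#'
#' Log10 tunneling rate against donor potential, one curve per grid distance
#' (shortest distance on top), with a horizontal reference at the rate
#' threshold.
#'
#' @param x a `rate_grid`.
#' @param threshold_log10 reference line (default 6, i.e. 10^6 s^-1).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rate_grid <- function(x, threshold_log10 = 6, ...) {
  p <- attr(x, "potentials"); d <- attr(x, "distances")
  cols <- grDevices::hcl.colors(length(d), "Blues 3", rev = TRUE)
  graphics::matplot(p, unclass(x), type = "l", lty = 1, col = cols,
                    xlab = "donor midpoint potential (mV)",
                    ylab = expression(log[10] ~ k[ET] ~ (s^-1)), ...)
  graphics::abline(h = threshold_log10, lty = 2)
  invisible(x)
}

#' Largest distance sustaining a target tunneling rate
#'
#' Scans a discrete distance grid and returns the largest distance whose
#' log10 rate meets the threshold, or `NA` if no grid point qualifies.
#' Operates on the discrete grid (1-angstrom steps by default) rather than a
#' continuous root, matching how the rate surface is modelled.
#'
#' @param donor_potential_mV,acceptor_potential_mV midpoint potentials in mV.
#' @param threshold_log10 required log10 rate (default 6).
#' @param params a [tunneling_params()] object.
#' @param distances ascending distance grid in angstroms.
#' @return Distance in angstroms, or `NA_real_` if unattainable.
#' @examples
#' max_distance_for_rate(-321, -415, 6)  # 10
#' @export
max_distance_for_rate <- function(donor_potential_mV, acceptor_potential_mV,
                                  threshold_log10 = 6,
                                  params = tunneling_params(),
                                  distances = seq(4, 20, by = 1)) {
  if (length(distances) == 0L) stop("empty distance grid")
  stopifnot(!is.unsorted(distances))
  dg <- driving_force(donor_potential_mV, acceptor_potential_mV)
  lg <- log10_tunneling_rate(distances, dg, params)$log10_rate
  ok <- which(lg >= threshold_log10)
  if (length(ok) == 0L) NA_real_ else max(distances[ok])
}

#' Highest donor potential sustaining a target tunneling rate
#'
#' Scans a discrete donor-potential grid at fixed distance and returns the
#' highest (least negative) potential whose log10 rate meets the threshold,
#' or `NA` if no grid point qualifies.
#'
#' @param distance_A edge-to-edge distance in angstroms.
#' @param acceptor_potential_mV acceptor midpoint potential in mV.
#' @param threshold_log10 required log10 rate (default 6).
#' @param params a [tunneling_params()] object.
#' @param potentials donor potential grid in mV.
#' @return Potential in mV, or `NA_real_` if unattainable.
#' @examples
#' required_potential_for_rate(14.7, -415, 6)  # -775 on the 25 mV grid
#' @export
required_potential_for_rate <- function(distance_A, acceptor_potential_mV,
                                        threshold_log10 = 6,
                                        params = tunneling_params(),
                                        potentials = seq(-1000, -200, by = 25)) {
  if (length(potentials) == 0L) stop("empty potential grid")
  dg <- driving_force(potentials, acceptor_potential_mV)
  lg <- log10_tunneling_rate(distance_A, dg, params)$log10_rate
  ok <- which(lg >= threshold_log10)
  if (length(ok) == 0L) NA_real_ else max(potentials[ok])
}
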