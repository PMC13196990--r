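# Current sources. Two routes produce the shared CompartmentCurrents source
# term: the closed-form cylindrical-axon profile (first/second derivative of
# the membrane potential) and a prescribed traveling action potential on a
# compartmental morphology. Units: um, ms, mV, nA, S/m throughout; with these
# units the axial conductance sigma_i*pi*r^2/L (um) times a potential drop in
# mV is a current in nA with no extra constant.

#' Gaussian action-potential waveform
#'
#' The membrane potential along the process is modelled as a Gaussian bump
#' `phi_m(z) = amplitude * exp(-z^2 / (2 sigma^2))`; the default width of
#' 167 um is the canonical depolarization length used throughout the scaling
#' analysis.
#'
#' @param sigma spatial standard deviation (um).
#' @param amplitude peak membrane potential (mV).
#' @param velocity propagation speed (um/ms) used by [propagate_ap()].
#' @return An `ap_waveform` object with a vectorised `$phi(z)` profile.
#' @export
gaussian_ap <- function(sigma = 167, amplitude = 100, velocity = 500) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(
    list(
      sigma = sigma, amplitude = amplitude, velocity = velocity,
      phi = function(z) amplitude * exp(-z^2 / (2 * sigma^2))
    ),
    class = "ap_waveform"
  )
}

#' Asymmetric (fast-rise, slow-fall) action-potential waveform
#'
#' Physiological action potentials depolarize much faster than they
#' repolarize, so the forward longitudinal current lobe (ahead of the peak)
#' is stronger than the reverse lobe. This waveform is a piecewise Gaussian
#' with width `sigma` ahead of the peak and `skew * sigma` behind it
#' (continuous with zero slope at the peak). With `skew = 1` it reduces to
#' [gaussian_ap()]. Used by the polarity-based reconstruction fixtures,
#' where a dominant forward lobe gives the clean bipolar normal-field split
#' seen for real cells.
#'
#' @param sigma leading-edge spatial standard deviation (um).
#' @param skew trailing-edge width multiplier (>= 1).
#' @param amplitude peak membrane potential (mV).
#' @param velocity propagation speed (um/ms).
#' @return An `ap_waveform`.
#' @export
asymmetric_ap <- function(sigma = 167, skew = 3, amplitude = 100,
                          velocity = 500) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(skew) || skew < 1) stop("skew must be >= 1")
  structure(
    list(
      sigma = sigma, skew = skew, amplitude = amplitude, velocity = velocity,
      phi = function(z) {
        s <- ifelse(z >= 0, sigma, skew * sigma)
        amplitude * exp(-z^2 / (2 * s^2))
      }
    ),
    class = "ap_waveform"
  )
}

#' Closed-form axon surface currents of the cylinder model
#'
#' For an infinitely long cylindrical axon of radius `a` with prescribed
#' membrane potential `phi_m(z)`, the longitudinal and transmembrane surface
#' current densities are `i_long = -sigma_i * dphi/dz` and
#' `i_trans = (sigma_i * a / 2) * d2phi/dz2`. Derivatives are second-order
#' central finite differences on the (uniform) grid.
#'
#' @param wave an `ap_waveform`.
#' @param sigma_i intracellular conductivity (S/m).
#' @param a axon radius (um).
#' @param z_grid uniform axial grid (um), spacing much smaller than
#'   `wave$sigma`.
#' @return An `axon_current_profile` with elements `z`, `i_long`, `i_trans`,
#'   `sigma_i`, `a`.
#' @export
analytic_axon_currents <- function(wave, sigma_i = 0.3, a = 1, z_grid) {
  stopifnot(inherits(wave, "ap_waveform"))
  dz <- diff(z_grid)
  if (length(dz) < 2L) stop("z_grid needs at least 3 points")
  if (max(abs(dz - dz[1])) > 1e-9 * abs(dz[1])) {
    stop("z_grid must be uniform")
  }
  h <- dz[1]
  phi <- wave$phi(z_grid)
  n <- length(phi)
  d1 <- c(
    (-3 * phi[1] + 4 * phi[2] - phi[3]) / (2 * h),
    (phi[-(1:2)] - phi[-((n - 1):n)]) / (2 * h),
    (3 * phi[n] - 4 * phi[n - 1] + phi[n - 2]) / (2 * h)
  )
  d2 <- c(
    (2 * phi[1] - 5 * phi[2] + 4 * phi[3] - phi[4]) / h^2,
    (phi[-(1:2)] - 2 * phi[-c(1, n)] + phi[-((n - 1):n)]) / h^2,
    (2 * phi[n] - 5 * phi[n - 1] + 4 * phi[n - 2] - phi[n - 3]) / h^2
  )
  structure(
    list(z = z_grid, i_long = -sigma_i * d1, i_trans = sigma_i * a / 2 * d2,
         sigma_i = sigma_i, a = a),
    class = "axon_current_profile"
  )
}

#' Count strict sign reversals of a sampled profile
#'
#' Samples whose magnitude is below `noise_floor * max(|values|)` are skipped
#' so float dust near zero crossings is not miscounted. A unimodal membrane
#' potential gives exactly 1 reversal for the longitudinal current and 2 for
#' the transmembrane current; these counts set the multipole order of the
#' resulting fields.
#'
#' @param values numeric profile (at least 2 samples).
#' @param noise_floor fraction of the maximum magnitude below which samples
#'   are ignored (default 0.01).
#' @return Integer number of sign changes between consecutive retained
#'   samples.
#' @export
count_sign_reversals <- function(values, noise_floor = 0.01) {
  if (length(values) < 2L) stop("need at least 2 samples")
  keep <- abs(values) > noise_floor * max(abs(values))
  v <- values[keep]
  if (length(v) == 0L) stop("all samples are below the noise floor")
  sum(diff(sign(v)) != 0)
}

new_compartment_currents <- function(starts, ends, radii, I_a, I_m, dt, t,
                                     labels = NULL, check = TRUE) {
  starts <- as.matrix(starts); ends <- as.matrix(ends)
  I_a <- as.matrix(I_a); I_m <- as.matrix(I_m)
  obj <- structure(
    list(
      starts = starts, ends = ends,
      midpoints = (starts + ends) / 2,
      directions = ends - starts,
      radii = radii, I_a = I_a, I_m = I_m, dt = dt, t = t,
      labels = labels %||% rep("process", nrow(starts))
    ),
    class = "compartment_currents"
  )
  if (check) {
    resid <- max(abs(colSums(I_m)))
    scale <- max(abs(I_m), 1e-300)
    if (resid > 1e-6 * scale) {
      warning(sprintf(
        "transmembrane currents violate conservation (max |sum| = %.3g of peak)",
        resid / scale
      ))
    }
  }
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.compartment_currents <- function(x, ...) {
  cat(sprintf("<compartment_currents> %d compartments x %d time steps (dt = %s ms)\n",
              nrow(x$I_a), ncol(x$I_a),
              if (is.null(x$dt)) "?" else format(x$dt)))
  invisible(x)
}

#' Discretise an analytic axon profile into compartment currents
#'
#' Turns the closed-form cylinder profile into a straight chain of
#' compartments along +x: axial current per slice `I_a = 2 pi a * i_long`,
#' transmembrane point source per slice `I_m = 2 pi a * dz * i_trans`
#' (single time step). Absolute units are arbitrary-but-consistent; the
#' object is intended for scaling and sign-structure analyses.
#'
#' @param prof an `axon_current_profile`.
#' @return A `compartment_currents` with one time column.
#' @export
profile_to_currents <- function(prof) {
  stopifnot(inherits(prof, "axon_current_profile"))
  z <- prof$z
  dz <- z[2] - z[1]
  starts <- cbind(z - dz / 2, 0, 0)
  ends <- cbind(z + dz / 2, 0, 0)
  I_a <- matrix(2 * pi * prof$a * prof$i_long, ncol = 1)
  I_m <- matrix(2 * pi * prof$a * dz * prof$i_trans, ncol = 1)
  # remove the tiny discretisation residual so the monopole term vanishes
  # exactly, as it does for the continuum profile
  I_m <- I_m - mean(I_m)
  new_compartment_currents(starts, ends, rep(prof$a, length(z)),
                           I_a, I_m, dt = NA_real_, t = 0)
}

#' Propagate a traveling action potential over a morphology
#'
#' The intracellular potential is prescribed as a traveling wave of the
#' morphology's path distance from the soma,
#' `phi_i(s, t) = phi_m(s - s_offset - v t)`. Axial current on each segment
#' follows from the core-conductor conductance `g = sigma_i pi r^2 / L`, and
#' the transmembrane current of each compartment is the net axial current it
#' loses to its children (Kirchhoff), so current conservation holds exactly
#' by construction. The soma is a single isopotential compartment supplying
#' its child processes.
#'
#' @param m a `neuro_morphology` (must be a connected tree).
#' @param wave an `ap_waveform` (carries the propagation velocity).
#' @param sigma_i intracellular conductivity (S/m).
#' @param t_grid uniform time grid (ms); default 224 steps of 31.25 us.
#' @param s_offset wave start offset (um): the wave peak is at path distance
#'   `s_offset + v t`. Default places the peak at half the maximum path
#'   length at the middle of the time window.
#' @return A `compartment_currents` (`I_a`, `I_m` in nA).
#' @export
propagate_ap <- function(m, wave = gaussian_ap(), sigma_i = 0.3,
                         t_grid = default_time_grid(), s_offset = NULL) {
  stopifnot(inherits(m, "neuro_morphology"), inherits(wave, "ap_waveform"))
  dt_all <- diff(t_grid)
  if (length(t_grid) > 1L && max(abs(dt_all - dt_all[1])) > 1e-9 * dt_all[1]) {
    stop("t_grid must be uniform")
  }
  seg <- m$segments
  n <- nrow(seg)
  lens <- segment_lengths(m)
  # path distance from the soma to each segment's distal node
  s_end <- rep(NA_real_, n)
  s_end[1] <- 0
  for (pass in seq_len(n)) {
    todo <- which(is.na(s_end) & !is.na(s_end[seg$parent]))
    if (length(todo) == 0L) break
    s_end[todo] <- s_end[seg$parent[todo]] + lens[todo]
  }
  if (any(is.na(s_end))) stop("morphology is not connected")
  s_start <- ifelse(is.na(seg$parent), 0, s_end[seg$parent])
  if (is.null(s_offset)) {
    s_offset <- max(s_end) / 2 - wave$velocity * stats::median(t_grid)
  }
  v <- wave$velocity
  # intracellular potential at proximal/distal nodes for all times (n x T)
  phi_at <- function(s) {
    outer(s, t_grid, function(si, ti) wave$phi(si - s_offset - v * ti))
  }
  phi0 <- phi_at(s_start)
  phi1 <- phi_at(s_end)
  g <- ifelse(lens > 1e-12, sigma_i * pi * seg$radius^2 / lens, 0)
  I_a <- g * (phi0 - phi1) # nA; positive = proximal-to-distal flow
  # transmembrane current: axial inflow minus outflow at each distal node
  I_m <- I_a
  for (k in which(!is.na(seg$parent))) {
    p <- seg$parent[k]
    I_m[p, ] <- I_m[p, ] - I_a[k, ]
  }
  starts <- as.matrix(seg[, c("x0", "y0", "z0")])
  ends <- as.matrix(seg[, c("x1", "y1", "z1")])
  dimnames(starts) <- dimnames(ends) <- NULL
  new_compartment_currents(
    starts, ends, seg$radius, I_a, I_m,
    dt = if (length(t_grid) > 1L) dt_all[1] else NA_real_,
    t = t_grid, labels = seg$label
  )
}

#' Default spike time grid: 224 steps of 31.25 us (7 ms)
#' @export
default_time_grid <- function(n_t = 224, dt = 0.03125) {
  seq(0, by = dt, length.out = n_t)
}
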