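# Extracellular fields from compartment currents.
#
# Unit conventions (fixed, see vignette): positions um, currents nA,
# magnetic field pT, potential uV, conductivity S/m. With those units the
# Biot-Savart prefactor mu0/(4 pi) becomes exactly 100 pT um / nA and the
# point-source potential prefactor 1/(4 pi sigma_e) becomes
# 1000/(4 pi sigma_e) uV um / nA.

.MU0_4PI_PT <- 100        # pT * um^2 / (nA * um)
.PHI_PREF <- 1000          # uV * um / nA, divided by 4 pi sigma_e

.as_points <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) == 2L) p <- cbind(p, 0)
  if (ncol(p) != 3L) stop("points must be N x 3 (or N x 2, z = 0)")
  storage.mode(p) <- "double"
  p
}

#' Magnetic field of compartmental axial currents (Biot-Savart)
#'
#' Sums the per-compartment contribution
#' `B = mu0/(4 pi) * I_a * d x r_hat / |r|^2` over all compartments, with
#' `r` pointing from the compartment midpoint to the evaluation point. Only
#' intracellular axial currents contribute; extracellular return currents
#' are neglected. The field is linear in the currents.
#'
#' @param c a `compartment_currents`.
#' @param points evaluation points, N x 3 matrix (um).
#' @return A `field_samples` with `values = list(Bx, By, Bz)` (pT), each an
#'   N_points x N_time matrix.
#' @export
biot_savart <- function(c, points) {
  stopifnot(inherits(c, "compartment_currents"))
  p <- .as_points(points)
  mid <- c$midpoints
  d <- c$directions
  np <- nrow(p); nc <- nrow(mid)
  Gx <- matrix(0, np, nc); Gy <- matrix(0, np, nc); Gz <- matrix(0, np, nc)
  for (j in seq_len(nc)) {
    rx <- p[, 1] - mid[j, 1]
    ry <- p[, 2] - mid[j, 2]
    rz <- p[, 3] - mid[j, 3]
    r2 <- rx^2 + ry^2 + rz^2
    if (any(r2 < 0.01)) {
      stop(sprintf(
        "evaluation point within 0.1 um of compartment %d midpoint", j))
    }
    r3 <- r2 * sqrt(r2)
    # d x r / |r|^3
    Gx[, j] <- .MU0_4PI_PT * (d[j, 2] * rz - d[j, 3] * ry) / r3
    Gy[, j] <- .MU0_4PI_PT * (d[j, 3] * rx - d[j, 1] * rz) / r3
    Gz[, j] <- .MU0_4PI_PT * (d[j, 1] * ry - d[j, 2] * rx) / r3
  }
  structure(
    list(points = p,
         values = list(Bx = Gx %*% c$I_a, By = Gy %*% c$I_a,
                       Bz = Gz %*% c$I_a),
         signal_type = "Bvec", t = c$t, dt = c$dt),
    class = "field_samples"
  )
}

.point_seg_distance <- function(p, a, b) {
  # distance from each row of p to segment a-b
  ab <- b - a
  l2 <- sum(ab^2)
  if (l2 < 1e-18) {
    return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2 + (p[, 3] - a[3])^2))
  }
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
          (p[, 3] - a[3]) * ab[3]) / l2
  t <- pmin(1, pmax(0, t))
  qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]; qz <- a[3] + t * ab[3]
  sqrt((p[, 1] - qx)^2 + (p[, 2] - qy)^2 + (p[, 3] - qz)^2)
}

#' Extracellular potential of transmembrane currents (line-source)
#'
#' Each compartment's transmembrane current is spread uniformly along the
#' segment line and integrated in closed form; zero-length compartments (the
#' soma sphere) fall back to a point source `I_m / (4 pi sigma_e R)`.
#' The reference electrode is at infinity.
#'
#' @param c a `compartment_currents`.
#' @param points evaluation points, N x 3 matrix (um); must stand off all
#'   source segments by at least 0.1 um.
#' @param sigma_e extracellular conductivity (S/m).
#' @return A `field_samples` with scalar `values` (uV), N_points x N_time.
#' @export
line_source_potential <- function(c, points, sigma_e = 0.3) {
  stopifnot(inherits(c, "compartment_currents"))
  p <- .as_points(points)
  np <- nrow(p); nc <- nrow(c$starts)
  M <- matrix(0, np, nc)
  pref <- .PHI_PREF / (4 * pi * sigma_e)
  for (j in seq_len(nc)) {
    a <- c$starts[j, ]; b <- c$ends[j, ]
    dmin <- .point_seg_distance(p, a, b)
    if (any(dmin < 0.1)) {
      stop(sprintf("evaluation point within 0.1 um of source segment %d", j))
    }
    ab <- b - a
    L <- sqrt(sum(ab^2))
    if (L < 1e-9) {
      M[, j] <- pref / dmin
    } else {
      u <- ab / L
      t <- (p[, 1] - a[1]) * u[1] + (p[, 2] - a[2]) * u[2] +
        (p[, 3] - a[3]) * u[3]
      rho2 <- pmax((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2 +
                     (p[, 3] - a[3])^2 - t^2, 1e-12)
      rho <- sqrt(rho2)
      M[, j] <- pref / L * (asinh(t / rho) - asinh((t - L) / rho))
    }
  }
  structure(
    list(points = p, values = M %*% c$I_m, signal_type = "phi",
         sigma_e = sigma_e, t = c$t, dt = c$dt),
    class = "field_samples"
  )
}

#' Current dipole moment of the transmembrane distribution
#'
#' `p(t) = sum_n I_m,n(t) * position_n`, reported in pA m. Translation
#' invariant when the net transmembrane current vanishes; otherwise the
#' result carries a `net_current_violated` attribute.
#'
#' @param c a `compartment_currents`.
#' @return An N_time x 3 matrix (pA m) with columns px, py, pz.
#' @export
current_dipole <- function(c) {
  stopifnot(inherits(c, "compartment_currents"))
  net <- colSums(c$I_m)
  p <- 1e-3 * t(c$I_m) %*% c$midpoints # nA um -> pA m
  colnames(p) <- c("px", "py", "pz")
  tol <- 1e-6 * max(abs(c$I_m), 1e-300)
  if (any(abs(net) > tol)) {
    warning("net transmembrane current is nonzero; dipole is origin-dependent")
    attr(p, "net_current_violated") <- TRUE
  } else {
    attr(p, "net_current_violated") <- FALSE
  }
  p
}

#' Numerical divergence of the magnetic field
#'
#' Central-difference divergence on a 6-point stencil, used to confirm the
#' solenoidality of the computed field away from sources.
#'
#' @param c a `compartment_currents`.
#' @param point single evaluation point (length 3, um).
#' @param h stencil half-spacing (um).
#' @return List with `div` (pT/um, per time step) and `b_scale` (local
#'   peak |B| in pT).
#' @export
b_divergence <- function(c, point, h = 1) {
  point <- as.numeric(point)
  stencil <- rbind(
    point + c(h, 0, 0), point - c(h, 0, 0),
    point + c(0, h, 0), point - c(0, h, 0),
    point + c(0, 0, h), point - c(0, 0, h)
  )
  f <- biot_savart(c, stencil)
  div <- (f$values$Bx[1, , drop = FALSE] - f$values$Bx[2, , drop = FALSE] +
            f$values$By[3, , drop = FALSE] - f$values$By[4, , drop = FALSE] +
            f$values$Bz[5, , drop = FALSE] - f$values$Bz[6, , drop = FALSE]) /
    (2 * h)
  bmag <- sqrt(f$values$Bx^2 + f$values$By^2 + f$values$Bz^2)
  list(div = as.numeric(div), b_scale = max(bmag))
}

#' Fit a power-law scaling exponent
#'
#' Least-squares line of `log(magnitude)` against `log(distance)` restricted
#' to `fit_window`; the reported exponent is the negated slope, so a field
#' decaying as `R^-n` yields `exponent = n`.
#'
#' @param distances distances (um), positive.
#' @param magnitudes field magnitudes at those distances, positive inside the
#'   window.
#' @param fit_window length-2 distance range used for the fit (default: all).
#' @return A `scaling_fit` with elements `exponent`, `intercept`,
#'   `distances`, `magnitudes`, `fit_window`.
#' @export
fit_scaling_exponent <- function(distances, magnitudes,
                                 fit_window = range(distances)) {
  keep <- distances >= fit_window[1] & distances <= fit_window[2]
  if (sum(keep) < 5L) stop("need at least 5 points inside fit_window")
  if (any(magnitudes[keep] <= 0)) {
    stop("magnitudes must be positive inside fit_window")
  }
  fit <- stats::lm(log(magnitudes[keep]) ~ log(distances[keep]))
  structure(
    list(exponent = -unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         distances = distances, magnitudes = magnitudes,
         fit_window = fit_window),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> exponent n = %.3f over R in [%g, %g] um\n",
              x$exponent, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Supra-threshold signal area of a spike template
#'
#' Counts sensors whose peak magnitude over the spike reaches
#' `fraction * max` of the global template peak and multiplies by the sensor
#' pitch cell area, e.g. each qualifying sensor on a 5 um grid contributes
#' 25 um^2.
#'
#' @param template a `spike_template` on a regular grid with known pitch.
#' @param fraction threshold as a fraction of the global peak (0 < f <= 1).
#' @return Area in um^2.
#' @export
suprathreshold_area <- function(template, fraction) {
  stopifnot(inherits(template, "spike_template"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  pitch <- template$sensors$pitch
  if (is.null(pitch) || any(!is.finite(pitch))) {
    stop("sensor array has no known pitch")
  }
  peak_per_sensor <- apply(abs(template$values), 1, max)
  n <- sum(peak_per_sensor >= fraction * max(peak_per_sensor))
  n * pitch[1] * pitch[2]
}
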