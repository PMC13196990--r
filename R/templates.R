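# Spike templates: one signal modality sampled on a sensor array over one
# spike (N_R x N_T matrix), plus the rotation / translation / sweep machinery
# used by the similarity analyses.

new_spike_template <- function(values, sensors, dt, signal_type,
                               cell_id = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(sensors$positions)) {
    stop("template rows must match sensor count")
  }
  if (!all(is.finite(values))) stop("template values must be finite")
  structure(
    list(values = values, sensors = sensors, dt = dt,
         signal_type = signal_type, cell_id = cell_id),
    class = "spike_template"
  )
}

#' @export
print.spike_template <- function(x, ...) {
  cat(sprintf("<spike_template> %s: %d sensors x %d time steps (dt = %s ms)\n",
              x$signal_type, nrow(x$values), ncol(x$values), format(x$dt)))
  invisible(x)
}

#' Compute a spike template on a sensor array
#'
#' Evaluates one signal modality at every sensor for the duration of the
#' spike: `"phi"` via the line-source potential (uV), `"Bx"/"By"/"Bz"` via
#' the compartmental Biot-Savart sum (pT). At the defaults the template has
#' 224 time columns (dt = 31.25 us, 7 ms).
#'
#' @param c a `compartment_currents` carrying the spike.
#' @param sensors a `sensor_array`.
#' @param s signal type, one of `"phi"`, `"Bx"`, `"By"`, `"Bz"`.
#' @param sigma_e extracellular conductivity (S/m), used for `"phi"`.
#' @param cell_id optional identifier stored on the template.
#' @return A `spike_template`.
#' @export
compute_template <- function(c, sensors, s = c("phi", "Bx", "By", "Bz"),
                             sigma_e = 0.3, cell_id = NULL) {
  s <- match.arg(s)
  stopifnot(inherits(sensors, "sensor_array"))
  vals <- if (s == "phi") {
    line_source_potential(c, sensors$positions, sigma_e)$values
  } else {
    biot_savart(c, sensors$positions)$values[[s]]
  }
  new_spike_template(vals, sensors, c$dt, s, cell_id)
}

#' Inverse-distance interpolation weights
#'
#' The K-nearest-neighbour weights used when resampling rotated templates:
#' `w_k = (1/d_k) / sum_k' (1/d_k')`. They always sum to 1; an exact match
#' (`d_k = 0`) short-circuits to that sample.
#'
#' @param d numeric vector of neighbour distances.
#' @return Normalised weights, same length as `d`.
#' @export
idw_weights <- function(d) {
  if (any(d <= .Machine$double.eps)) {
    w <- as.numeric(d <= .Machine$double.eps)
    return(w / sum(w))
  }
  w <- 1 / d
  w / sum(w)
}

.rotation_center <- function(sensors) {
  colMeans(sensors$positions[, 1:2, drop = FALSE])
}

# Build the sparse interpolation operator for a rotation by theta degrees:
# original sensors are queried at their position rotated by -theta about the
# array centre, and each query value is the IDW mean of the K nearest
# original sensors. Returns a list(idx N x K, w N x K).
.rotation_interp <- function(sensors, theta, K = 5, divide_by_k = FALSE) {
  pos <- sensors$positions[, 1:2, drop = FALSE]
  ctr <- .rotation_center(sensors)
  a <- -theta * pi / 180
  qx <- ctr[1] + cos(a) * (pos[, 1] - ctr[1]) - sin(a) * (pos[, 2] - ctr[2])
  qy <- ctr[2] + sin(a) * (pos[, 1] - ctr[1]) + cos(a) * (pos[, 2] - ctr[2])
  K <- min(K, nrow(pos))
  nn <- FNN::get.knnx(pos, cbind(qx, qy), k = K)
  w <- t(apply(nn$nn.dist, 1, idw_weights))
  if (K == 1L) w <- matrix(w, ncol = 1L)
  if (divide_by_k) w <- w / K
  list(idx = nn$nn.index, w = w)
}

.apply_interp <- function(interp, values) {
  out <- matrix(0, nrow(values), ncol(values))
  for (k in seq_len(ncol(interp$idx))) {
    out <- out + interp$w[, k] * values[interp$idx[, k], , drop = FALSE]
  }
  out
}

#' Rotate a spike template about the array centre
#'
#' Equivalent to rotating the source by `+theta` degrees: sensor coordinates
#' are rotated by `-theta`, and values at the original sensor positions are
#' re-estimated as the inverse-distance-weighted mean of the `K` nearest
#' samples. Scalar modalities (`phi`, `Bz`) transform as scalars; the planar
#' components mix as vectors, `Bx' = cos(t) Bx - sin(t) By`,
#' `By' = sin(t) Bx + cos(t) By`, which requires the orthogonal planar
#' `partner` template.
#'
#' @param t a `spike_template`.
#' @param theta rotation angle (degrees, counterclockwise source rotation).
#' @param K neighbour count for the inverse-distance resampling.
#' @param partner the other planar component (`By` when rotating a `Bx`
#'   template and vice versa); ignored for scalar modalities.
#' @param divide_by_k reproduce the literal published interpolation rule, which
#'   divides the already-normalised weighted sum by `K` (uniformly scales
#'   values by 1/K); default uses the normalised convex combination.
#' @return The rotated `spike_template`.
#' @export
rotate_template <- function(t, theta, K = 5, partner = NULL,
                            divide_by_k = FALSE) {
  stopifnot(inherits(t, "spike_template"))
  interp <- .rotation_interp(t$sensors, theta, K, divide_by_k)
  if (t$signal_type %in% c("phi", "Bz")) {
    vals <- .apply_interp(interp, t$values)
  } else {
    if (is.null(partner) || !inherits(partner, "spike_template")) {
      stop("rotating a planar component requires the orthogonal partner template")
    }
    a <- theta * pi / 180
    this_rot <- .apply_interp(interp, t$values)
    partner_rot <- .apply_interp(interp, partner$values)
    vals <- if (t$signal_type == "Bx") {
      if (partner$signal_type != "By") stop("partner of Bx must be By")
      cos(a) * this_rot - sin(a) * partner_rot
    } else {
      if (partner$signal_type != "Bx") stop("partner of By must be Bx")
      sin(a) * partner_rot + cos(a) * this_rot
    }
  }
  new_spike_template(vals, t$sensors, t$dt, t$signal_type, t$cell_id)
}

.grid_shift_steps <- function(sensors, delta) {
  if (is.null(sensors$pitch) || is.null(sensors$nx)) {
    stop("translation requires a regular grid array")
  }
  s <- delta / sensors$pitch
  si <- round(s)
  if (max(abs(s - si)) > 1e-9) {
    warning(sprintf(
      "translation (%.3g, %.3g) um is not a grid multiple; snapped to (%g, %g)",
      delta[1], delta[2], si[1] * sensors$pitch[1], si[2] * sensors$pitch[2]))
  }
  as.integer(si)
}

# Shift grid-ordered values (x fastest) by (sx, sy) grid steps, zero fill.
.shift_grid_values <- function(values, nx, ny, sx, sy) {
  out <- matrix(0, nrow(values), ncol(values))
  xs <- seq_len(nx); ys <- seq_len(ny)
  dst_x <- xs[xs - sx >= 1 & xs - sx <= nx]
  dst_y <- ys[ys - sy >= 1 & ys - sy <= ny]
  if (length(dst_x) == 0L || length(dst_y) == 0L) return(out)
  src_x <- dst_x - sx; src_y <- dst_y - sy
  dst_idx <- as.vector(outer(dst_x, (dst_y - 1L) * nx, `+`))
  src_idx <- as.vector(outer(src_x, (src_y - 1L) * nx, `+`))
  out[dst_idx, ] <- values[src_idx, , drop = FALSE]
  out
}

#' Translate a spike template on its grid
#'
#' Shifts the template by `delta` (um), equivalent to translating the source;
#' vacated sensors are zero-filled. Deltas that are not integer multiples of
#' the pitch are snapped to the nearest grid vector with a warning.
#'
#' @param t a `spike_template` on a grid array.
#' @param delta length-2 in-plane translation (um).
#' @return The translated `spike_template`.
#' @export
translate_template <- function(t, delta) {
  stopifnot(inherits(t, "spike_template"), length(delta) == 2L)
  s <- .grid_shift_steps(t$sensors, as.numeric(delta))
  vals <- .shift_grid_values(t$values, t$sensors$nx, t$sensors$ny, s[1], s[2])
  new_spike_template(vals, t$sensors, t$dt, t$signal_type, t$cell_id)
}

#' Rotation-averaged (spread) template
#'
#' Arithmetic mean of [rotate_template()] over theta = 0, step, ...,
#' 360 - step degrees (24 rotations at the default 15 degree step). The
#' spread template characterises how a cell's signal disperses through space
#' irrespective of orientation.
#'
#' @inheritParams rotate_template
#' @param theta_step sweep increment in degrees; must divide 360.
#' @return A `spike_template` carrying attribute-like fields `theta_step`;
#'   class `c("spread_template", "spike_template")`.
#' @export
spread_template <- function(t, theta_step = 15, K = 5, partner = NULL,
                            divide_by_k = FALSE) {
  stopifnot(inherits(t, "spike_template"))
  if (360 %% theta_step != 0) stop("theta_step must divide 360")
  thetas <- seq(0, 360 - theta_step, by = theta_step)
  acc <- matrix(0, nrow(t$values), ncol(t$values))
  for (th in thetas) {
    acc <- acc + rotate_template(t, th, K, partner, divide_by_k)$values
  }
  out <- new_spike_template(acc / length(thetas), t$sensors, t$dt,
                            t$signal_type, t$cell_id)
  out$theta_step <- theta_step
  class(out) <- c("spread_template", class(out))
  out
}
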