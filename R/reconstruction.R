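# Polarity-boundary morphology reconstruction. The normal magnetic field of
# a dominant process flips sign across the process; a kernel SVM trained on
# sensor positions vs. signal polarity yields a decision boundary tracing
# the process (GNBE), refined near the soma by excluding sensors behind the
# axon hillock (CNBE).

#' Per-sensor polarity labels of a Bz template
#'
#' The label is the sign of the sample with the largest absolute value in
#' each sensor's waveform (robust to noise compared to, e.g., the time-mean
#' sign); the mean signal power is recorded per sensor. Exactly-zero
#' waveforms are excluded.
#'
#' @param t a `spike_template` (normal magnetic field).
#' @return A `polarity_labels`: list with `positions` (N x 2), `labels`
#'   (+1/-1), `power` (mean square per sensor), `included` (logical mask on
#'   the original sensors).
#' @export
sensor_polarity <- function(t) {
  stopifnot(inherits(t, "spike_template"))
  peak_idx <- max.col(abs(t$values), ties.method = "first")
  peak <- t$values[cbind(seq_len(nrow(t$values)), peak_idx)]
  included <- peak != 0
  structure(
    list(positions = t$sensors$positions[included, 1:2, drop = FALSE],
         labels = sign(peak[included]),
         power = rowMeans(t$values^2)[included],
         included = included,
         pitch = t$sensors$pitch),
    class = "polarity_labels"
  )
}

# Soft-margin SVM with RBF kernel via the standard dual QP (quadprog).
# Per-sample box constraints 0 <= alpha_i <= C * w_i allow weighting the
# slack penalty, e.g. by signal power so that noise-dominated sensors far
# from the cell cannot pull the boundary. Returns a decision function over
# N x 2 query points.
.svm_rbf <- function(X, y, kernel_scale, C = 1, weights = NULL) {
  n <- nrow(X)
  ub <- C * (weights %||% rep(1, n))
  ub <- pmax(ub, 1e-10 * C)
  gamma <- 1 / (2 * kernel_scale^2)
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-gamma * d2)
  Dmat <- (y %o% y) * K
  Dmat <- Dmat + diag(1e-8 * n, n) # PD jitter
  dvec <- rep(1, n)
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), -ub)
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), ub)
  sv <- alpha > 1e-8 * max(ub)
  coef <- alpha * y
  # bias from the primal: minimise the weighted hinge loss in b directly
  # (robust when few alphas sit strictly inside their box)
  f0 <- as.numeric(K %*% coef)
  hinge <- function(bb) sum(ub * pmax(0, 1 - y * (f0 + bb)))
  b <- stats::optimize(hinge, interval = range(-y - f0, y - f0))$minimum
  list(
    decision = function(Q) {
      Q <- as.matrix(Q)
      # cross kernel in chunks to bound memory
      out <- numeric(nrow(Q))
      idx <- which(sv)
      Xs <- X[idx, , drop = FALSE]
      cs <- coef[idx]
      step <- 20000L
      for (st in seq(1L, nrow(Q), by = step)) {
        en <- min(st + step - 1L, nrow(Q))
        d2q <- outer(rowSums(Q[st:en, , drop = FALSE]^2), rowSums(Xs^2), `+`) -
          2 * Q[st:en, , drop = FALSE] %*% t(Xs)
        out[st:en] <- exp(-gamma * pmax(d2q, 0)) %*% cs + b
      }
      out
    },
    alpha = alpha, b = b
  )
}

.infer_pitch <- function(positions, pitch = NULL) {
  if (!is.null(pitch)) return(mean(pitch))
  ux <- sort(unique(round(positions[, 1], 6)))
  if (length(ux) > 1) min(diff(ux)) else 1
}

#' General Neural Boundary Estimation (GNBE)
#'
#' Fits a maximum-margin radial-basis-kernel classifier on sensor positions
#' versus signal polarity and extracts the zero level-set of its decision
#' function on a dense grid (4x the sensor density) as the boundary
#' polyline, interpreted as the dominant process's orientation.
#'
#' @param labels a `polarity_labels` (or a `spike_template`, which is
#'   labelled first).
#' @param kernel_scale RBF length scale (um); default 2x the sensor pitch.
#' @param regularization soft-margin cost C.
#' @param grid_factor evaluation-grid densification factor.
#' @param bbox optional evaluation bounding box,
#'   `list(xlim = c(..), ylim = c(..))`; default the labelled sensors'
#'   extent.
#' @param power_weight exponent of the per-sensor slack weighting
#'   `(power / max power)^power_weight`: sensors whose waveform is
#'   noise-dominated get proportionally less say in where the boundary
#'   runs. 0 disables weighting (plain SVM).
#' @return A `boundary_estimate`: list with `boundary` (M x 2 polyline, the
#'   longest zero contour), `polylines` (all contours), `grid_x`, `grid_y`,
#'   `decision` (matrix), `hillock_estimate` (NULL for GNBE),
#'   `excluded_sensor_mask`.
#' @export
gnbe <- function(labels, kernel_scale = NULL, regularization = 1,
                 grid_factor = 4, bbox = NULL, power_weight = 0.25) {
  if (inherits(labels, "spike_template")) labels <- sensor_polarity(labels)
  stopifnot(inherits(labels, "polarity_labels"))
  y <- labels$labels
  if (length(unique(y)) < 2L) {
    stop("both polarities are required to estimate a boundary")
  }
  X <- labels$positions
  pitch <- .infer_pitch(X, labels$pitch)
  kernel_scale <- kernel_scale %||% (2 * pitch)
  w <- if (is.null(labels$power) || power_weight <= 0) NULL else
    (labels$power / max(labels$power))^power_weight
  fit <- .svm_rbf(X, y, kernel_scale, regularization, weights = w)
  xlim <- bbox$xlim %||% range(X[, 1])
  ylim <- bbox$ylim %||% range(X[, 2])
  gx <- seq(xlim[1], xlim[2], by = pitch / grid_factor)
  gy <- seq(ylim[1], ylim[2], by = pitch / grid_factor)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  dec <- matrix(fit$decision(grid), length(gx), length(gy))
  cl <- grDevices::contourLines(gx, gy, dec, levels = 0)
  if (length(cl) == 0L) {
    stop("decision function has no zero level-set on the array")
  }
  polylines <- lapply(cl, function(li) cbind(x = li$x, y = li$y))
  arc <- vapply(polylines, function(p) {
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  structure(
    list(boundary = polylines[[which.max(arc)]], polylines = polylines,
         grid_x = gx, grid_y = gy, decision = dec,
         hillock_estimate = NULL, excluded_sensor_mask = NULL,
         kernel_scale = kernel_scale, regularization = regularization,
         labels = labels),
    class = "boundary_estimate"
  )
}

#' @export
print.boundary_estimate <- function(x, ...) {
  cat(sprintf("<boundary_estimate> %d polyline points (%d contours)%s\n",
              nrow(x$boundary), length(x$polylines),
              if (!is.null(x$hillock_estimate)) {
                sprintf(", hillock at (%.1f, %.1f) um",
                        x$hillock_estimate[1], x$hillock_estimate[2])
              } else ""))
  invisible(x)
}

# nearest point on a polyline (and all polylines) to each query point
.nearest_on_polyline <- function(points, polylines) {
  best_d <- rep(Inf, nrow(points))
  best_p <- matrix(NA_real_, nrow(points), 2)
  for (pl in polylines) {
    if (nrow(pl) < 2L) next
    for (k in seq_len(nrow(pl) - 1L)) {
      a <- pl[k, ]; b <- pl[k + 1L, ]
      ab <- b - a
      l2 <- sum(ab^2)
      t <- if (l2 < 1e-18) rep(0, nrow(points)) else
        pmin(1, pmax(0, ((points[, 1] - a[1]) * ab[1] +
                           (points[, 2] - a[2]) * ab[2]) / l2))
      qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
      d <- sqrt((points[, 1] - qx)^2 + (points[, 2] - qy)^2)
      upd <- d < best_d
      best_d[upd] <- d[upd]
      best_p[upd, 1] <- qx[upd]; best_p[upd, 2] <- qy[upd]
    }
  }
  list(dist = best_d, point = best_p)
}

#' Customized Neural Boundary Estimation (CNBE)
#'
#' Second-pass refinement of [gnbe()] correcting the near-soma bias caused
#' by opposing dendrites: (1) the axon hillock is estimated as the
#' power-weighted centroid of the 4 highest-power sensors; (2) the next 96
#' sensors by power form 24 consecutive groups of 4, each yielding a
#' power-weighted centroid; (3) each centroid is snapped to its nearest
#' point on the first-pass boundary; (4) points whose mean distance to
#' their 4 nearest neighbours exceeds 50 um are discarded as outliers;
#' (5) a weighted least-squares line is fit through the survivors with the
#' hillock given `hillock_weight` times a point's weight; (6) a cut line
#' perpendicular to that fit is placed 10 um behind the hillock (opposite
#' the surviving points' centroid); (7) sensors behind the cut are excluded
#' and the boundary re-estimated on the remainder. Arrays with fewer than
#' 100 sensors use proportional ranks. If every candidate point is removed
#' as an outlier the first pass is returned with a warning.
#'
#' @param t a `spike_template` (Bz).
#' @param first_pass optional existing GNBE `boundary_estimate`.
#' @param hillock_weight weight multiplier of the hillock in the line fit.
#' @param outlier_dist neighbour-distance cutoff for outlier removal (um).
#' @param cut_back distance behind the hillock of the exclusion line (um).
#' @param ... passed to [gnbe()].
#' @return A `boundary_estimate` with `hillock_estimate` and
#'   `excluded_sensor_mask` filled in.
#' @export
cnbe <- function(t, first_pass = NULL, hillock_weight = 50,
                 outlier_dist = 50, cut_back = 10, ...) {
  stopifnot(inherits(t, "spike_template"))
  labels <- sensor_polarity(t)
  if (is.null(first_pass)) first_pass <- gnbe(labels, ...)
  n <- length(labels$labels)
  ord <- order(labels$power, decreasing = TRUE)
  if (n >= 100L) {
    n_top <- 4L
    rest <- ord[5:100]
    group_size <- 4L
  } else {
    n_top <- max(1L, round(0.04 * n))
    rest <- ord[(n_top + 1L):n]
    group_size <- max(1L, floor(length(rest) / 24))
    message(sprintf(
      "cnbe: array has %d (< 100) sensors; using proportional ranks (top %d, groups of %d)",
      n, n_top, group_size))
  }
  wcentroid <- function(idx) {
    w <- labels$power[idx]
    c(sum(labels$positions[idx, 1] * w), sum(labels$positions[idx, 2] * w)) / sum(w)
  }
  hillock <- wcentroid(ord[seq_len(n_top)])
  n_groups <- min(24L, length(rest) %/% group_size)
  centroids <- matrix(unlist(lapply(seq_len(n_groups), function(g) {
    wcentroid(rest[((g - 1L) * group_size + 1L):(g * group_size)])
  })), ncol = 2, byrow = TRUE)
  near <- .nearest_on_polyline(centroids, first_pass$polylines)
  pts <- near$point
  # outlier removal by mean distance to 4 nearest neighbours
  if (nrow(pts) > 1L) {
    dmat <- as.matrix(stats::dist(pts))
    diag(dmat) <- Inf
    kk <- min(4L, nrow(pts) - 1L)
    mean_nn <- apply(dmat, 1, function(d) mean(sort(d)[seq_len(kk)]))
    pts <- pts[mean_nn <= outlier_dist, , drop = FALSE]
  }
  if (nrow(pts) == 0L) {
    warning("cnbe: all boundary points removed as outliers; falling back to the first pass")
    return(first_pass)
  }
  # weighted line fit through surviving points + hillock (weighted PCA)
  P <- rbind(pts, hillock)
  w <- c(rep(1, nrow(pts)), hillock_weight)
  ctr <- colSums(P * w) / sum(w)
  Pc <- sweep(P, 2, ctr)
  cov_w <- crossprod(Pc * sqrt(w)) / sum(w)
  v <- eigen(cov_w, symmetric = TRUE)$vectors[, 1]
  # direction from the hillock towards the surviving points
  towards <- colMeans(pts) - hillock
  if (sum(v * towards) < 0) v <- -v
  cut_point <- hillock - cut_back * v
  sensor_side <- (labels$positions[, 1] - cut_point[1]) * v[1] +
    (labels$positions[, 2] - cut_point[2]) * v[2]
  keep <- sensor_side >= 0
  if (length(unique(labels$labels[keep])) < 2L || sum(keep) < 5L) {
    warning("cnbe: exclusion left a degenerate sensor set; falling back to the first pass")
    return(first_pass)
  }
  kept <- structure(
    list(positions = labels$positions[keep, , drop = FALSE],
         labels = labels$labels[keep],
         power = labels$power[keep],
         included = keep,
         pitch = labels$pitch),
    class = "polarity_labels"
  )
  out <- gnbe(kept, ...)
  out$hillock_estimate <- hillock
  out$excluded_sensor_mask <- !keep
  out$first_pass <- first_pass
  out
}

#' Mean distance between a morphology and an estimated boundary
#'
#' Projects the midpoints of the selected segments to the array plane and
#' averages their minimum Euclidean distance to the boundary polyline. Also
#' returns the per-segment error profile against path distance from the
#' soma, for error-vs-distance analyses.
#'
#' @param b a `boundary_estimate`.
#' @param truth the ground-truth `neuro_morphology`.
#' @param process_filter segment labels to evaluate (default the dominant
#'   process, `"axon"`).
#' @return List with `mean_error` (um) and `profile` (data.frame:
#'   `path_dist`, `error`).
#' @export
reconstruction_error <- function(b, truth, process_filter = "axon") {
  stopifnot(inherits(b, "boundary_estimate"),
            inherits(truth, "neuro_morphology"))
  if (nrow(b$boundary) == 0L) stop("boundary estimate is empty")
  seg <- truth$segments
  keep <- seg$label %in% process_filter
  if (!any(keep)) stop("no segments match process_filter")
  mids <- segment_midpoints(truth)[keep, 1:2, drop = FALSE]
  lens <- segment_lengths(truth)
  s_end <- rep(NA_real_, nrow(seg))
  s_end[1] <- 0
  for (pass in seq_len(nrow(seg))) {
    todo <- which(is.na(s_end) & !is.na(s_end[seg$parent]))
    if (length(todo) == 0L) break
    s_end[todo] <- s_end[seg$parent[todo]] + lens[todo]
  }
  path_dist <- (s_end - lens / 2)[keep]
  d <- .nearest_on_polyline(mids, list(b$boundary))$dist
  list(mean_error = mean(d),
       profile = data.frame(path_dist = path_dist, error = d))
}

#' Add noise to a spike template at a target array-wide SNR
#'
#' i.i.d. Gaussian noise with power `mean(template^2) / 10^(snr_db/10)`:
#' "average SNR" is interpreted array-wide, over all sensors and samples.
#'
#' @param t a `spike_template`.
#' @param snr_db target average SNR in dB (`Inf` returns the template
#'   unchanged).
#' @param seed integer seed.
#' @return The noisy `spike_template`.
#' @export
add_template_noise <- function(t, snr_db, seed = 1) {
  stopifnot(inherits(t, "spike_template"))
  if (!is.finite(snr_db)) return(t)
  noise_sd <- sqrt(mean(t$values^2) / 10^(snr_db / 10))
  set.seed(as.integer(seed))
  vals <- t$values + matrix(stats::rnorm(length(t$values), 0, noise_sd),
                            nrow(t$values), ncol(t$values))
  new_spike_template(vals, t$sensors, t$dt, t$signal_type, t$cell_id)
}

#' Export a boundary polyline as CSV
#'
#' @param b a `boundary_estimate`.
#' @param path output CSV path (columns x, y in um).
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(b, path) {
  stopifnot(inherits(b, "boundary_estimate"))
  utils::write.csv(as.data.frame(b$boundary), path, row.names = FALSE)
  invisible(path)
}
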