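# Orientation-averaged cosine similarity between spike templates on a
# displacement grid, and the effective-radius resolution metric derived
# from it.

# Frobenius inner product <A, shift(B)> without materialising the shifted
# matrix: only overlapping grid cells contribute.
.shift_inner <- function(A, B, nx, ny, sx, sy) {
  xs <- seq_len(nx); ys <- seq_len(ny)
  dst_x <- xs[xs - sx >= 1 & xs - sx <= nx]
  dst_y <- ys[ys - sy >= 1 & ys - sy <= ny]
  if (length(dst_x) == 0L || length(dst_y) == 0L) return(0)
  src_x <- dst_x - sx; src_y <- dst_y - sy
  dst_idx <- as.vector(outer(dst_x, (dst_y - 1L) * nx, `+`))
  src_idx <- as.vector(outer(src_x, (src_y - 1L) * nx, `+`))
  sum(A[dst_idx, , drop = FALSE] * B[src_idx, , drop = FALSE])
}

# ||shift(B)||^2: squared entries of B that survive the shift (zero fill
# discards the rest).
.shift_norm2 <- function(B, nx, ny, sx, sy) {
  xs <- seq_len(nx); ys <- seq_len(ny)
  src_x <- xs[xs + sx >= 1 & xs + sx <= nx]
  src_y <- ys[ys + sy >= 1 & ys + sy <= ny]
  if (length(src_x) == 0L || length(src_y) == 0L) return(0)
  src_idx <- as.vector(outer(src_x, (src_y - 1L) * nx, `+`))
  sum(B[src_idx, , drop = FALSE]^2)
}

#' Default displacement grids
#'
#' The coarse grid spans +-400 um at 50 um steps, the fine grid +-200 um at
#' 20 um steps (in the x-y plane).
#'
#' @param kind `"fine"` or `"coarse"`.
#' @return List with vectors `dx`, `dy` (um).
#' @export
displacement_grid <- function(kind = c("fine", "coarse")) {
  kind <- match.arg(kind)
  if (kind == "fine") {
    list(dx = seq(-200, 200, by = 20), dy = seq(-200, 200, by = 20))
  } else {
    list(dx = seq(-400, 400, by = 50), dy = seq(-400, 400, by = 50))
  }
}

#' Displacement-resolved template similarity map
#'
#' For each displacement `(dx, dy)` the similarity is the Frobenius cosine
#' `<M_n, T(dr) G_m> / (||M_n|| ||T(dr) M_m||)`, where `G_m` is the
#' rotation-averaged spread template of cell m (set `sweep = FALSE` to use
#' `M_m` itself) and `T(dr)` the grid translation with zero fill. Values near
#' 1 mean the two cells are hard to tell apart at that separation.
#'
#' @param t_n,t_m `spike_template`s on the same grid array and time base.
#' @param displacements list with vectors `dx`, `dy` (um); defaults to the
#'   fine grid of [displacement_grid()].
#' @param sweep average cell m over orientations first (default `TRUE`).
#' @param theta_step,K,partner passed to [spread_template()].
#' @return A `similarity_map`: list with `dx`, `dy`, `values`
#'   (length(dx) x length(dy)), `pitch`, `cell_ids`, `signal_type`.
#' @export
similarity_map <- function(t_n, t_m, displacements = displacement_grid("fine"),
                           sweep = TRUE, theta_step = 15, K = 5,
                           partner = NULL) {
  stopifnot(inherits(t_n, "spike_template"), inherits(t_m, "spike_template"))
  sn <- t_n$sensors
  if (!isTRUE(all.equal(sn$positions, t_m$sensors$positions)) ||
      !identical(dim(t_n$values), dim(t_m$values))) {
    stop("templates must share the sensor array and time base")
  }
  if (is.null(sn$nx)) stop("similarity_map requires a grid array")
  norm_n <- sqrt(sum(t_n$values^2))
  norm_m <- sqrt(sum(t_m$values^2))
  if (norm_n == 0 || norm_m == 0) stop("zero-norm template")
  G <- if (sweep) {
    spread_template(t_m, theta_step = theta_step, K = K,
                    partner = partner)$values
  } else {
    t_m$values
  }
  dx <- displacements$dx; dy <- displacements$dy
  vals <- matrix(NA_real_, length(dx), length(dy))
  for (ix in seq_along(dx)) {
    sx <- .grid_shift_steps(sn, c(dx[ix], 0))[1]
    for (iy in seq_along(dy)) {
      sy <- .grid_shift_steps(sn, c(0, dy[iy]))[2]
      num <- .shift_inner(t_n$values, G, sn$nx, sn$ny, sx, sy)
      den_m2 <- .shift_norm2(t_m$values, sn$nx, sn$ny, sx, sy)
      vals[ix, iy] <- if (den_m2 <= 0) 0 else num / (norm_n * sqrt(den_m2))
    }
  }
  structure(
    list(dx = dx, dy = dy, values = vals,
         pitch = c(if (length(dx) > 1) diff(dx)[1] else NA_real_,
                   if (length(dy) > 1) diff(dy)[1] else NA_real_),
         cell_ids = c(t_n$cell_id %||% NA, t_m$cell_id %||% NA),
         signal_type = t_n$signal_type),
    class = "similarity_map"
  )
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("<similarity_map> %s: %d x %d displacements, range [%.3g, %.3g]\n",
              x$signal_type, length(x$dx), length(x$dy),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Effective radius of a similarity region
#'
#' Radius of the circle whose area equals the displacement-grid region where
#' the similarity exceeds `gamma`: `r = sqrt(count * dx * dy / pi)`. The
#' operational pairwise resolution limit: cells closer than `r` look alike.
#'
#' @param map a `similarity_map`.
#' @param gamma similarity threshold in (-1, 1).
#' @param dx,dy displacement-grid pitches (um); default from the map.
#' @return Radius in um (0 when no grid point exceeds `gamma`).
#' @export
effective_radius <- function(map, gamma, dx = NULL, dy = NULL) {
  stopifnot(inherits(map, "similarity_map"))
  if (!(gamma > -1 && gamma < 1)) stop("gamma must be in (-1, 1)")
  dx <- dx %||% map$pitch[1]
  dy <- dy %||% map$pitch[2]
  n <- sum(map$values > gamma)
  sqrt(n * dx * dy / pi)
}
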