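# Deterministic synthetic fixtures: randomly placed and oriented cell
# populations and their per-modality templates, used by the discrimination
# and recording analyses so every experiment runs with no external data.

#' Templates of a randomly placed and oriented cell population
#'
#' Places `n_cells` copies of a base morphology uniformly over the sensor
#' array extent with uniform random in-plane orientation, suspends each
#' `suspend_z` um above the array, propagates the action potential and
#' computes one spike template per requested modality. At the stated
#' cortical surface density of 340 cells/mm^2 the default cell count follows
#' from the array area (`n_cells = NULL`).
#'
#' @param sensors a `sensor_array`.
#' @param n_cells population size; `NULL` derives it from `density`.
#' @param modalities character vector in `{"phi","Bx","By","Bz"}`.
#' @param base_cell base `neuro_morphology` (default a branched elongated
#'   cell, see [make_branched_cell()]).
#' @param wave an `ap_waveform`.
#' @param density surface density (cells/mm^2) used when `n_cells` is NULL.
#' @param suspend_z suspension height above the array plane (um).
#' @param sigma_i,sigma_e conductivities (S/m).
#' @param t_grid time grid (ms).
#' @param seed integer seed.
#' @return List over cells; each element a named list of `spike_template`s
#'   plus a `morphology` entry.
#' @export
population_templates <- function(sensors, n_cells = NULL,
                                 modalities = c("phi", "Bz"),
                                 base_cell = NULL, wave = gaussian_ap(),
                                 density = 340, suspend_z = 15,
                                 sigma_i = 0.3, sigma_e = 0.3,
                                 t_grid = default_time_grid(), seed = 1) {
  stopifnot(inherits(sensors, "sensor_array"))
  pos <- sensors$positions
  span_x <- diff(range(pos[, 1]))
  span_y <- diff(range(pos[, 2]))
  if (is.null(n_cells)) {
    n_cells <- max(2L, round(density * span_x * span_y / 1e6))
  }
  base_cell <- base_cell %||% make_branched_cell(seed = 1)
  set.seed(as.integer(seed))
  thetas <- stats::runif(n_cells, 0, 360)
  xs <- stats::runif(n_cells, min(pos[, 1]), max(pos[, 1]))
  ys <- stats::runif(n_cells, min(pos[, 2]), max(pos[, 2]))
  lapply(seq_len(n_cells), function(i) {
    m <- transform_morphology(base_cell, thetas[i], c(xs[i], ys[i]))
    m$segments$z0 <- m$segments$z0 + suspend_z
    m$segments$z1 <- m$segments$z1 + suspend_z
    m$soma_position[3] <- m$soma_position[3] + suspend_z
    cur <- propagate_ap(m, wave, sigma_i, t_grid)
    out <- lapply(modalities, function(s) {
      compute_template(cur, sensors, s, sigma_e, cell_id = i)
    })
    names(out) <- modalities
    out$morphology <- m
    out
  })
}

#' Elongated single-cell template fixture
#'
#' One cell (default a straight-axon ball-stick, trunk along +x through the
#' array centre) suspended above a grid array, with templates for the
#' requested modalities. Used by the similarity and reconstruction analyses.
#'
#' @param sensors a `sensor_array`.
#' @param morphology base cell; default [make_ball_stick()] with 10 um
#'   segments, shifted so the axon midpoint sits over the array centre.
#' @param center_axon centre the axon over the array (default TRUE).
#' @inheritParams population_templates
#' @return Named list of `spike_template`s plus `morphology` and `currents`.
#' @export
single_cell_templates <- function(sensors, modalities = c("phi", "Bz"),
                                  morphology = NULL, wave = gaussian_ap(),
                                  suspend_z = 15, sigma_i = 0.3,
                                  sigma_e = 0.3,
                                  t_grid = default_time_grid(),
                                  center_axon = TRUE) {
  stopifnot(inherits(sensors, "sensor_array"))
  m <- morphology %||% make_ball_stick(axon_length = 600, segment_length = 10)
  if (center_axon) {
    mids <- segment_midpoints(m)
    ctr <- c(mean(range(mids[, 1])), mean(range(mids[, 2])))
    m <- transform_morphology(m, 0, -ctr)
  }
  m$segments$z0 <- m$segments$z0 + suspend_z
  m$segments$z1 <- m$segments$z1 + suspend_z
  m$soma_position[3] <- m$soma_position[3] + suspend_z
  cur <- propagate_ap(m, wave, sigma_i, t_grid)
  out <- lapply(modalities, function(s) {
    compute_template(cur, sensors, s, sigma_e, cell_id = 1L)
  })
  names(out) <- modalities
  out$morphology <- m
  out$currents <- cur
  out
}
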