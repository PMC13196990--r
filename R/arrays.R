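# Planar sensor arrays (z = 0). Grid layouts store nx/ny/pitch so templates
# can be shifted on the grid; Neuropixels-like layouts are irregular.

new_sensor_array <- function(positions, pitch = NULL, nx = NULL, ny = NULL,
                             layout_tag = "custom") {
  positions <- as.matrix(positions)
  if (ncol(positions) == 2L) positions <- cbind(positions, 0)
  if (anyDuplicated(round(positions, 9))) {
    stop("sensor positions must be unique")
  }
  structure(
    list(positions = positions, pitch = pitch, nx = nx, ny = ny,
         layout_tag = layout_tag),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d sensors, layout = %s%s\n",
              nrow(x$positions), x$layout_tag,
              if (!is.null(x$pitch)) {
                sprintf(", pitch = (%g, %g) um", x$pitch[1], x$pitch[2])
              } else ""))
  invisible(x)
}

#' Regular planar sensor grid
#'
#' `nx * ny` sensors at the given pitch, centred on the origin in the z = 0
#' plane. Sensor ordering is x-fastest (row-major in y).
#'
#' @param nx,ny sensor counts along x and y.
#' @param pitch scalar or length-2 pitch (um).
#' @return A `sensor_array` with `layout_tag = "grid"`.
#' @export
make_sensor_grid <- function(nx, ny = nx, pitch = 50) {
  if (nx < 1 || ny < 1) stop("nx and ny must be >= 1")
  pitch <- rep(as.numeric(pitch), length.out = 2L)
  if (any(pitch <= 0)) stop("pitch must be positive")
  xs <- (seq_len(nx) - (nx + 1) / 2) * pitch[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * pitch[2]
  pos <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  new_sensor_array(pos, pitch = pitch, nx = as.integer(nx),
                   ny = as.integer(ny), layout_tag = "grid")
}

#' Neuropixels-like two-column staggered layout
#'
#' Parameterised stand-in for a Neuropixels 1.0 checkerboard: channels are
#' laid out in rows of two columns separated by `col_pitch`, rows separated
#' by `row_pitch`, with every other row shifted by `stagger` along x.
#' `stagger = 0` gives a plain two-column grid.
#'
#' @param n_channels total channel count (even).
#' @param row_pitch vertical pitch between rows (um).
#' @param col_pitch horizontal separation of the two columns (um).
#' @param stagger x-shift of odd rows (um).
#' @return A `sensor_array` with `layout_tag = "neuropixels_like"`.
#' @export
make_neuropixels_like <- function(n_channels = 384, row_pitch = 20,
                                  col_pitch = 32, stagger = 16) {
  if (n_channels < 2 || n_channels %% 2 != 0) {
    stop("n_channels must be a positive even number")
  }
  n_rows <- n_channels / 2
  row <- rep(seq_len(n_rows) - 1L, each = 2L)
  col <- rep(c(-0.5, 0.5), times = n_rows)
  x <- col * col_pitch + ifelse(row %% 2 == 1, stagger, 0)
  y <- row * row_pitch
  y <- y - mean(y)
  new_sensor_array(cbind(x, y, 0), pitch = NULL,
                   layout_tag = "neuropixels_like")
}

#' Export a sensor array as a JSON probe map
#'
#' Channel index, position and (optional) modality per channel, readable by
#' external tooling.
#'
#' @param sensors a `sensor_array`.
#' @param path output JSON path.
#' @param modalities optional character vector of per-channel modalities.
#' @return `path`, invisibly.
#' @export
write_probe_map <- function(sensors, path, modalities = NULL) {
  stopifnot(inherits(sensors, "sensor_array"))
  n <- nrow(sensors$positions)
  modalities <- rep(modalities %||% "phi", length.out = n)
  chan <- lapply(seq_len(n), function(i) {
    list(channel = i - 1L,
         x = sensors$positions[i, 1],
         y = sensors$positions[i, 2],
         z = sensors$positions[i, 3],
         modality = modalities[i])
  })
  jsonlite::write_json(
    list(layout = sensors$layout_tag,
         pitch = sensors$pitch,
         channels = chan),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
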