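# On-disk containers. The canonical format is JSON metadata plus float32
# binary payloads (portable, no extra dependencies); an HDF5 mirror of the
# same layout is available when rhdf5 is installed. Recordings export as
# flat binary (channel-major interleave) plus a JSON probe map, sufficient
# for external sorters.

.write_f32 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
}

.read_f32 <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, numeric(), n = n, size = 4L, endian = "little")
}

#' Save / load a spike template
#'
#' Directory container: `meta.json` (signal type, dt, sensor layout,
#' dimensions) plus `values.bin` and `positions.bin` (float32,
#' column-major). Set `format = "hdf5"` to write a single `.h5` file with
#' datasets `values`, `positions`, `dt`, `signal_type` instead (requires
#' rhdf5).
#'
#' @param t a `spike_template`.
#' @param path output directory (or `.h5` file for `format = "hdf5"`).
#' @param format `"binary"` (default) or `"hdf5"`.
#' @return `path`, invisibly.
#' @export
save_template <- function(t, path, format = c("binary", "hdf5")) {
  stopifnot(inherits(t, "spike_template"))
  format <- match.arg(format)
  if (format == "hdf5") {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("format = 'hdf5' requires the rhdf5 package")
    }
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(t$values, path, "values")
    rhdf5::h5write(t$sensors$positions, path, "positions")
    rhdf5::h5write(t$dt, path, "dt")
    rhdf5::h5write(t$signal_type, path, "signal_type")
    rhdf5::h5closeAll()
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    container = "neuromag_template", version = 1L,
    signal_type = t$signal_type, dt = t$dt,
    cell_id = t$cell_id,
    n_sensors = nrow(t$values), n_time = ncol(t$values),
    layout_tag = t$sensors$layout_tag, pitch = t$sensors$pitch,
    nx = t$sensors$nx, ny = t$sensors$ny
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .write_f32(t$values, file.path(path, "values.bin"))
  .write_f32(t$sensors$positions, file.path(path, "positions.bin"))
  invisible(path)
}

#' @rdname save_template
#' @export
load_template <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$container, "neuromag_template")) {
    stop("not a neuromag template container: ", path)
  }
  nr <- meta$n_sensors; nt <- meta$n_time
  values <- matrix(.read_f32(file.path(path, "values.bin"), nr * nt), nr, nt)
  pos <- matrix(.read_f32(file.path(path, "positions.bin"), nr * 3), nr, 3)
  sensors <- new_sensor_array(pos, pitch = meta$pitch,
                              nx = meta$nx, ny = meta$ny,
                              layout_tag = meta$layout_tag %||% "custom")
  new_spike_template(values, sensors, meta$dt, meta$signal_type, meta$cell_id)
}

#' Save / load compartment currents
#'
#' Directory container mirroring the documented dataset layout: positions
#' (midpoints), directions, I_a, I_m and dt.
#'
#' @param c a `compartment_currents`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
save_currents <- function(c, path) {
  stopifnot(inherits(c, "compartment_currents"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(container = "neuromag_currents", version = 1L,
               n_comp = nrow(c$I_a), n_time = ncol(c$I_a), dt = c$dt,
               t = c$t, labels = c$labels, radii = c$radii)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .write_f32(c$starts, file.path(path, "starts.bin"))
  .write_f32(c$ends, file.path(path, "ends.bin"))
  .write_f32(c$I_a, file.path(path, "I_a.bin"))
  .write_f32(c$I_m, file.path(path, "I_m.bin"))
  invisible(path)
}

#' @rdname save_currents
#' @export
load_currents <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$container, "neuromag_currents")) {
    stop("not a neuromag currents container: ", path)
  }
  nc <- meta$n_comp; nt <- meta$n_time
  new_compartment_currents(
    matrix(.read_f32(file.path(path, "starts.bin"), nc * 3), nc, 3),
    matrix(.read_f32(file.path(path, "ends.bin"), nc * 3), nc, 3),
    meta$radii,
    matrix(.read_f32(file.path(path, "I_a.bin"), nc * nt), nc, nt),
    matrix(.read_f32(file.path(path, "I_m.bin"), nc * nt), nc, nt),
    dt = meta$dt, t = meta$t, labels = meta$labels, check = FALSE
  )
}

#' Export a recording as flat binary plus probe map
#'
#' Float32 flat binary in channel-major interleave (sample-by-sample frames
#' of all channels) plus a JSON probe map (channel index, position,
#' modality) and a JSON ground-truth sidecar with the spike trains and
#' per-modality scale factors.
#'
#' @param rec a `neural_recording`.
#' @param path output stem; writes `<path>.bin`, `<path>.probe.json`,
#'   `<path>.truth.json`.
#' @param sensors the `sensor_array` the recording was generated on.
#' @return The `.bin` path, invisibly.
#' @export
export_recording <- function(rec, path, sensors) {
  stopifnot(inherits(rec, "neural_recording"))
  # channel-major interleave: frame of all channels per sample
  .write_f32(rec$data, paste0(path, ".bin"))
  pos <- sensors$positions
  n_rep <- nrow(rec$data) / nrow(pos)
  pos_all <- pos[rep(seq_len(nrow(pos)), times = n_rep), , drop = FALSE]
  chan <- lapply(seq_len(nrow(rec$data)), function(i) {
    list(channel = i - 1L, x = pos_all[i, 1], y = pos_all[i, 2],
         z = pos_all[i, 3], modality = rec$modality[i])
  })
  jsonlite::write_json(
    list(layout = sensors$layout_tag, pitch = sensors$pitch,
         channels = chan),
    paste0(path, ".probe.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(sampling_rate = rec$sampling_rate,
         n_channels = nrow(rec$data), n_samples = ncol(rec$data),
         noise_rms = rec$noise_rms,
         scale_factors = as.list(rec$scale_factors),
         truncated_spikes = rec$truncated_spikes,
         spike_trains = rec$trains$trains),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(path, ".bin"))
}
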