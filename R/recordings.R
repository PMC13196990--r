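# Ground-truthed recording generation: Poisson spike trains with a
# refractory rule, template convolution, modality power equalisation,
# thermal-noise calibration, and spike-train agreement metrics.

.BOLTZMANN <- 1.380649e-23 # J/K

#' Poisson spike trains with a refractory rule
#'
#' One homogeneous Poisson train per cell; each cell's rate is drawn from a
#' normal law (default mean 5 Hz, sd 1 Hz, truncated below at 0.1 Hz).
#' Spikes closer than the refractory period to their predecessor are removed
#' (the earlier spike is kept).
#'
#' @param n_cells number of cells.
#' @param duration recording duration (s).
#' @param rate_mean,rate_sd rate distribution (Hz).
#' @param refractory refractory period (ms).
#' @param seed integer seed.
#' @return A `spike_train_set`: list with `trains` (list of sorted spike
#'   times in s), `rates`, `duration`, `refractory`, `seed`.
#' @export
poisson_trains <- function(n_cells, duration, rate_mean = 5, rate_sd = 1,
                           refractory = 2, seed = 1) {
  if (duration <= 0) stop("duration must be positive")
  set.seed(as.integer(seed))
  rates <- pmax(stats::rnorm(n_cells, rate_mean, rate_sd), 0.1)
  trains <- lapply(rates, function(r) {
    # expected count + slack, then truncate to the duration
    n_draw <- max(10L, ceiling(r * duration + 6 * sqrt(r * duration)))
    tt <- cumsum(stats::rexp(n_draw, rate = r))
    while (length(tt) > 0 && tt[length(tt)] < duration) {
      tt <- c(tt, tt[length(tt)] + cumsum(stats::rexp(n_draw, rate = r)))
    }
    tt <- tt[tt < duration]
    enforce_refractory(tt, refractory / 1000)
  })
  structure(
    list(trains = trains, rates = rates, duration = duration,
         refractory = refractory, seed = seed),
    class = "spike_train_set"
  )
}

# Keep the earlier spike of any pair violating the refractory gap (s).
enforce_refractory <- function(times, gap_s) {
  if (length(times) < 2L) return(times)
  keep <- times[1]
  for (t in times[-1]) {
    if (t - keep[length(keep)] >= gap_s) keep <- c(keep, t)
  }
  keep
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d cells, %g s, %d spikes total\n",
              length(x$trains), x$duration,
              sum(lengths(x$trains))))
  invisible(x)
}

#' Equalise average signal power across modalities
#'
#' The electrical potential (`phi`), when present, is the unscaled
#' reference. All magnetic components share one common factor chosen so the
#' highest-power magnetic modality matches the reference power, preserving
#' the relative magnitudes of Bx:By:Bz; with a single magnetic modality this
#' makes its mean-square power exactly equal to phi's. Idempotent.
#'
#' @param sets named list keyed by modality; each element either a numeric
#'   matrix or a list of numeric matrices (e.g. one template per cell).
#' @return List with `scaled` (same shape as `sets`) and `factors` (named
#'   scale factors).
#' @export
normalize_modal_power <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  as_list <- lapply(sets, function(x) if (is.list(x)) x else list(x))
  power <- vapply(as_list, function(mats) {
    mean(unlist(lapply(mats, function(m) mean(m^2))))
  }, numeric(1))
  if (any(power == 0)) {
    stop("zero-power modality: ", paste(names(power)[power == 0], collapse = ", "))
  }
  factors <- stats::setNames(rep(1, length(sets)), names(sets))
  magnetic <- setdiff(names(sets), "phi")
  if (length(magnetic) > 0) {
    ref_power <- if ("phi" %in% names(sets)) power[["phi"]] else
      max(power[magnetic])
    common <- sqrt(ref_power / max(power[magnetic]))
    factors[magnetic] <- common
  }
  scaled <- lapply(names(sets), function(s) {
    mats <- lapply(as_list[[s]], function(m) m * factors[[s]])
    if (is.list(sets[[s]])) mats else mats[[1]]
  })
  names(scaled) <- names(sets)
  list(scaled = scaled, factors = factors)
}

#' Assemble a multimodal recording from templates and spike trains
#'
#' Each spike adds its cell's template starting at the spike sample;
#' contributions sum linearly. Modalities are power-equalised with
#' [normalize_modal_power()] and stacked channel-wise, then i.i.d. zero-mean
#' Gaussian noise of the configured RMS is added per channel. Spikes whose
#' template would overrun the recording end are truncated (counted in
#' `$truncated_spikes`).
#'
#' @param templates list over cells; each a named list of `spike_template`s
#'   keyed by modality (all sharing `dt` and sensor count per modality).
#' @param trains a `spike_train_set` with one train per cell.
#' @param noise_rms noise RMS in the (power-equalised) recording units.
#' @param seed integer seed for the noise.
#' @param duration recording length (s); default the train set's duration.
#' @return A `neural_recording`: list with `data` (channels x samples),
#'   `sampling_rate` (Hz), `modality` (per channel), `trains`,
#'   `scale_factors`, `noise_rms`, `truncated_spikes`.
#' @export
assemble_recording <- function(templates, trains, noise_rms = 0, seed = 1,
                               duration = NULL) {
  stopifnot(inherits(trains, "spike_train_set"))
  if (length(templates) != length(trains$trains)) {
    stop("one template set per spike train is required")
  }
  modalities <- names(templates[[1]])
  dt_ms <- templates[[1]][[1]]$dt
  fs <- 1000 / dt_ms
  duration <- duration %||% trains$duration
  n_samp <- ceiling(duration * fs)
  sets <- lapply(modalities, function(s) {
    lapply(templates, function(tt) tt[[s]]$values)
  })
  names(sets) <- modalities
  norm <- normalize_modal_power(sets)
  n_chan_per <- vapply(modalities, function(s) nrow(norm$scaled[[s]][[1]]), 1L)
  data <- matrix(0, sum(n_chan_per), n_samp)
  chan_mod <- rep(modalities, times = n_chan_per)
  offsets <- cumsum(c(0L, n_chan_per[-length(n_chan_per)]))
  names(offsets) <- modalities
  truncated <- 0L
  for (i in seq_along(templates)) {
    starts <- floor(trains$trains[[i]] * fs) + 1L
    for (s in modalities) {
      tv <- norm$scaled[[s]][[i]]
      nt <- ncol(tv)
      rows <- offsets[[s]] + seq_len(nrow(tv))
      for (st in starts) {
        en <- min(st + nt - 1L, n_samp)
        if (en < st + nt - 1L) truncated <- truncated + 1L
        if (en >= st) {
          data[rows, st:en] <- data[rows, st:en] +
            tv[, seq_len(en - st + 1L), drop = FALSE]
        }
      }
    }
  }
  # one truncation count per spike, not per modality
  truncated <- truncated %/% max(1L, length(modalities))
  if (noise_rms > 0) {
    set.seed(as.integer(seed))
    data <- data + matrix(stats::rnorm(length(data), 0, noise_rms),
                          nrow(data), ncol(data))
  }
  structure(
    list(data = data, sampling_rate = fs, modality = chan_mod,
         trains = trains, scale_factors = norm$factors,
         noise_rms = noise_rms, truncated_spikes = truncated),
    class = "neural_recording"
  )
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("<neural_recording> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              paste(unique(x$modality), collapse = ", ")))
  invisible(x)
}

#' Thermal (Johnson) noise RMS of a resistor
#'
#' `sqrt(4 k_B T R B)` for resistance `R`, bandwidth `B` and temperature
#' `T`; e.g. 100 kOhm over 32 kHz at 300 K gives 7.28 uVrms.
#'
#' @param resistance Ohms.
#' @param bandwidth Hz.
#' @param temperature Kelvin.
#' @return RMS voltage (V).
#' @export
thermal_noise_rms <- function(resistance, bandwidth, temperature = 300) {
  if (any(c(resistance, bandwidth, temperature) < 0)) {
    stop("arguments must be non-negative")
  }
  sqrt(4 * .BOLTZMANN * temperature * resistance * bandwidth)
}

#' Rescale a white-noise RMS to a different bandwidth
#'
#' `rms * sqrt(band_to / band_from)`; e.g. 7.1 uVrms over 300 Hz-10 kHz
#' becomes 12.9 uVrms over 32 kHz.
#'
#' @param rms input RMS.
#' @param band_from,band_to bandwidth widths (Hz), `band_from > 0`.
#' @return Rescaled RMS.
#' @export
rescale_noise_bandwidth <- function(rms, band_from, band_to) {
  if (band_from <= 0) stop("band_from must be positive")
  rms * sqrt(band_to / band_from)
}

# matched spike count between two sorted trains within tolerance (s),
# one-to-one by a greedy two-pointer sweep
.match_count <- function(a, b, tol) {
  i <- 1L; j <- 1L; n <- 0L
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= tol) {
      n <- n + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  n
}

#' Match predicted spike trains against ground truth
#'
#' Greedy one-to-one pairing of predicted and truth units maximising
#' matched-spike counts within `tolerance`; per-pair accuracy is
#' `TP / (TP + FP + FN)` and units with accuracy > 0.8 count as
#' well-detected.
#'
#' @param predicted,truth `spike_train_set`s (or bare lists of sorted spike
#'   time vectors in s).
#' @param tolerance matching tolerance (ms).
#' @return List with `pairs` (data.frame: predicted, truth, tp, fp, fn,
#'   accuracy), `accuracy` (spike-weighted overall TP/(TP+FP+FN)),
#'   `well_detected` count.
#' @export
match_spike_trains <- function(predicted, truth, tolerance = 1) {
  if (tolerance <= 0) stop("tolerance must be positive")
  p <- if (inherits(predicted, "spike_train_set")) predicted$trains else predicted
  g <- if (inherits(truth, "spike_train_set")) truth$trains else truth
  tol <- tolerance / 1000
  if (length(p) == 0L || length(g) == 0L || sum(lengths(p)) == 0L) {
    return(list(pairs = data.frame(), accuracy = 0, well_detected = 0L))
  }
  counts <- matrix(0L, length(p), length(g))
  for (i in seq_along(p)) {
    for (j in seq_along(g)) counts[i, j] <- .match_count(p[[i]], g[[j]], tol)
  }
  pairs <- data.frame()
  used_p <- logical(length(p)); used_g <- logical(length(g))
  repeat {
    best <- which(counts == max(counts), arr.ind = TRUE)[1, , drop = TRUE]
    if (counts[best[1], best[2]] <= 0L && nrow(pairs) > 0L) break
    i <- best[1]; j <- best[2]
    tp <- counts[i, j]
    fp <- length(p[[i]]) - tp
    fn <- length(g[[j]]) - tp
    pairs <- rbind(pairs, data.frame(
      predicted = i, truth = j, tp = tp, fp = fp, fn = fn,
      accuracy = if (tp + fp + fn > 0) tp / (tp + fp + fn) else 0
    ))
    used_p[i] <- TRUE; used_g[j] <- TRUE
    counts[i, ] <- -1L; counts[, j] <- -1L
    if (all(used_p) || all(used_g)) break
  }
  tp_all <- sum(pairs$tp)
  fp_all <- sum(pairs$fp) + sum(lengths(p[!used_p]))
  fn_all <- sum(pairs$fn) + sum(lengths(g[!used_g]))
  acc <- if (tp_all + fp_all + fn_all > 0) {
    tp_all / (tp_all + fp_all + fn_all)
  } else 0
  list(pairs = pairs, accuracy = acc,
       well_detected = sum(pairs$accuracy > 0.8))
}
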