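# Network-level separability: channel matrices of flattened spike templates,
# their condition number, and bootstrap capacity estimation.

#' Build a channel matrix from per-cell templates
#'
#' Column n is the concatenation of cell n's flattened (sensors x time)
#' templates over the requested modalities. Before stacking, modality blocks
#' are power-normalised with [normalize_modal_power()] so volts and teslas
#' are numerically comparable: phi is never rescaled, magnetic components
#' share a common factor that preserves their relative magnitudes.
#'
#' @param templates list over cells; each element a named list of
#'   `spike_template`s keyed by modality.
#' @param modalities character vector of modalities to stack (default: those
#'   of the first cell).
#' @return A `channel_matrix`: list with `matrix` (rows = sensors x time x
#'   modalities, cols = cells), `cell_ids`, `modalities`, `scale_factors`.
#' @export
build_channel_matrix <- function(templates, modalities = NULL) {
  stopifnot(length(templates) >= 1L)
  modalities <- modalities %||% names(templates[[1]])
  if (is.null(modalities)) stop("modalities could not be inferred")
  sets <- lapply(modalities, function(s) {
    lapply(seq_along(templates), function(i) {
      t <- templates[[i]][[s]]
      if (is.null(t)) stop(sprintf("cell %d has no %s template", i, s))
      t$values
    })
  })
  names(sets) <- modalities
  for (i in seq_along(templates)) {
    if (all(vapply(modalities, function(s) all(sets[[s]][[i]] == 0), TRUE))) {
      stop(sprintf("cell %d has an all-zero template", i))
    }
  }
  norm <- normalize_modal_power(sets)
  cols <- vapply(seq_along(templates), function(i) {
    unlist(lapply(modalities, function(s) as.vector(norm$scaled[[s]][[i]])))
  }, numeric(length(modalities) * length(as.vector(sets[[1]][[1]]))))
  ids <- vapply(seq_along(templates), function(i) {
    templates[[i]][[modalities[1]]]$cell_id %||% i
  }, numeric(1))
  structure(
    list(matrix = cols, cell_ids = ids, modalities = modalities,
         scale_factors = norm$factors),
    class = "channel_matrix"
  )
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat(sprintf("<channel_matrix> %d x %d (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$modalities, collapse = ", ")))
  invisible(x)
}

#' Condition number of a channel matrix
#'
#' Ratio of the largest to smallest singular value; values near 1 mean the
#' cells' templates are well separated, large values mean poor separability.
#' Returns `Inf` when the smallest singular value is below `1e-12` of the
#' largest (e.g. duplicated columns).
#'
#' @param cm a `channel_matrix` or plain numeric matrix with at least as
#'   many rows as columns.
#' @return Scalar condition number (possibly `Inf`).
#' @export
condition_number <- function(cm) {
  x <- if (inherits(cm, "channel_matrix")) cm$matrix else as.matrix(cm)
  if (ncol(x) > nrow(x)) {
    stop("channel matrix has more columns (cells) than rows: underdetermined")
  }
  d <- svd(x, nu = 0, nv = 0)$d
  if (d[length(d)] < 1e-12 * d[1]) return(Inf)
  d[1] / d[length(d)]
}

#' Bootstrap capacity estimate from condition-number samples
#'
#' For each bootstrap replicate the per-population condition numbers are
#' resampled with replacement within each cell count, the mean of
#' `-log10(condition)` is linearly interpolated across cell counts, and the
#' largest cell count where the curve stays at or above `threshold` is
#' recorded; the estimate is the median over replicates. `Inf` condition
#' numbers enter as `-log10 = -16` (condition 1e16) so a degenerate draw
#' cannot poison a replicate mean.
#'
#' @param samples named list mapping cell count (names coercible to numeric)
#'   to a numeric vector of condition numbers (>= 2 counts, >= 5 samples
#'   each).
#' @param threshold capacity threshold on `-log10(condition)`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed (deterministic given the seed).
#' @return Largest supportable cell count (0 if the threshold is above the
#'   whole curve).
#' @export
capacity_estimate <- function(samples, threshold, n_boot = 1000, seed = 1) {
  ns <- as.numeric(names(samples))
  if (length(ns) < 2L || anyNA(ns)) {
    stop("samples must map >= 2 distinct cell counts to condition numbers")
  }
  if (any(vapply(samples, length, 1L) < 5L)) {
    stop("each cell count needs >= 5 condition-number samples")
  }
  ord <- order(ns)
  ns <- ns[ord]; samples <- samples[ord]
  neglog <- lapply(samples, function(v) {
    out <- -log10(v)
    out[!is.finite(out)] <- -16
    out
  })
  xout <- if (diff(range(ns)) <= 10000) {
    seq(min(ns), max(ns), by = 1)
  } else {
    seq(min(ns), max(ns), length.out = 10001)
  }
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_boot), function(b) {
    m <- vapply(neglog, function(v) mean(sample(v, replace = TRUE)), 1)
    curve <- stats::approx(ns, m, xout = xout)$y
    ok <- which(curve >= threshold)
    if (length(ok) == 0L) 0 else xout[max(ok)]
  }, numeric(1))
  stats::median(reps)
}
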