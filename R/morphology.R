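# Morphologies are trees of tapered cylindrical segments in micrometres.
# The soma is a zero-length segment whose radius is the sphere radius; it is
# always segment 1 and the origin of rotations. Sensor plane is z = 0 and
# cells occupy z > 0 (right-handed axes).

#' Construct a morphology object
#'
#' Low-level constructor. Most users should call [make_ball_stick()],
#' [make_branched_cell()] or [read_swc()] instead.
#'
#' @param segments data.frame with columns `x0,y0,z0,x1,y1,z1,radius,parent,
#'   label`. Coordinates in micrometres; `parent` is the index of the parent
#'   segment (`NA` for the soma root); `label` is one of `"soma"`, `"axon"`,
#'   `"dendrite"`. Segment 1 must be the soma.
#' @param soma_position numeric length-3 soma centre (um).
#' @param validate check tree invariants (default `TRUE`).
#' @return An object of class `neuro_morphology`.
#' @export
new_morphology <- function(segments, soma_position = c(0, 0, 0),
                           validate = TRUE) {
  stopifnot(is.data.frame(segments))
  needed <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "parent", "label")
  missing_cols <- setdiff(needed, names(segments))
  if (length(missing_cols) > 0L) {
    stop("segments is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  m <- structure(
    list(segments = segments, soma_position = as.numeric(soma_position)),
    class = "neuro_morphology"
  )
  if (validate) validate_morphology(m)
  m
}

validate_morphology <- function(m) {
  seg <- m$segments
  coords <- as.matrix(seg[, c("x0", "y0", "z0", "x1", "y1", "z1")])
  if (!all(is.finite(coords))) stop("morphology has non-finite coordinates")
  if (any(seg$radius <= 0)) stop("all segment radii must be > 0")
  if (sum(seg$label == "soma") != 1L) stop("morphology must have exactly one soma")
  if (seg$label[1] != "soma") stop("the soma must be segment 1")
  if (!is.na(seg$parent[1])) stop("the soma segment cannot have a parent")
  lens <- segment_lengths(m)
  if (any(lens < 1e-12 & seg$label != "soma")) {
    stop("zero-length segment outside the soma")
  }
  n <- nrow(seg)
  if (n > 1L) {
    par <- seg$parent[-1]
    if (any(is.na(par))) stop("morphology has multiple roots")
    if (any(par < 1 | par > n)) stop("parent index out of range")
    # connectivity: every segment must reach the soma through parents
    depth <- rep(NA_integer_, n)
    depth[1] <- 0L
    for (pass in seq_len(n)) {
      newly <- which(is.na(depth) & !is.na(depth[seg$parent]))
      if (length(newly) == 0L) break
      depth[newly] <- depth[seg$parent[newly]] + 1L
    }
    if (any(is.na(depth))) stop("morphology is not a single connected tree")
    # child start must coincide with parent end
    ps <- seg$parent[-1]
    pend <- as.matrix(seg[ps, c("x1", "y1", "z1")])
    # children of the soma attach at the soma position (zero-length root)
    gap <- sqrt(rowSums((as.matrix(seg[-1, c("x0", "y0", "z0")]) - pend)^2))
    if (any(gap > 1e-6)) {
      stop("child segment start does not coincide with parent end (gap > 1e-6 um)")
    }
  }
  invisible(m)
}

segment_lengths <- function(m) {
  seg <- m$segments
  sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
}

segment_midpoints <- function(m) {
  seg <- m$segments
  cbind(
    x = (seg$x0 + seg$x1) / 2,
    y = (seg$y0 + seg$y1) / 2,
    z = (seg$z0 + seg$z1) / 2
  )
}

#' @export
print.neuro_morphology <- function(x, ...) {
  seg <- x$segments
  cat(sprintf(
    "<neuro_morphology> %d segments (%s), soma at (%.1f, %.1f, %.1f) um\n",
    nrow(seg),
    paste(sprintf("%d %s", table(seg$label), names(table(seg$label))),
          collapse = ", "),
    x$soma_position[1], x$soma_position[2], x$soma_position[3]
  ))
  invisible(x)
}

#' Ball-and-stick model cell
#'
#' A spherical soma at the origin with a single straight cylindrical axon
#' along +x, divided into `ceiling(axon_length / segment_length)` segments.
#' Defaults are the canonical ball-stick parameters: 1 mm axon of 2 um
#' diameter, 20 um soma, 0.5 um segments.
#'
#' @param axon_length total axon length (um).
#' @param axon_diameter axon diameter (um).
#' @param soma_diameter soma diameter (um).
#' @param segment_length axon discretisation length (um); the final segment
#'   absorbs any remainder.
#' @param taper_ratio proximal-to-distal diameter ratio (>= 1). The default
#'   1 gives a uniform cylinder; larger values taper the axon linearly away
#'   from the hillock, concentrating axial current (proportional to r^2)
#'   near the soma as in real initial segments.
#' @param hillock_factor,hillock_length optional conical axon-hillock
#'   thickening: the radius is multiplied by
#'   `1 + (hillock_factor - 1) * exp(-s / hillock_length)` at path distance
#'   `s` from the soma. The default factor 1 keeps the plain uniform
#'   cylinder of the canonical ball-stick.
#' @return A `neuro_morphology`.
#' @export
make_ball_stick <- function(axon_length = 1000, axon_diameter = 2,
                            soma_diameter = 20, segment_length = 0.5,
                            taper_ratio = 1, hillock_factor = 1,
                            hillock_length = 50) {
  args <- c(axon_length, axon_diameter, soma_diameter, segment_length)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("all ball-stick parameters must be positive")
  }
  if (!is.finite(taper_ratio) || taper_ratio < 1) {
    stop("taper_ratio must be >= 1")
  }
  if (segment_length > axon_length) {
    stop("segment_length must not exceed axon_length")
  }
  n <- ceiling(axon_length / segment_length)
  brk <- seq(0, axon_length, length.out = n + 1L)
  mids <- (brk[-(n + 1L)] + brk[-1L]) / 2
  radii <- (axon_diameter / 2) * (1 - mids / axon_length * (1 - 1 / taper_ratio)) *
    (1 + (hillock_factor - 1) * exp(-mids / hillock_length))
  seg <- data.frame(
    x0 = c(0, brk[-(n + 1L)]),
    y0 = 0, z0 = 0,
    x1 = c(0, brk[-1L]),
    y1 = 0, z1 = 0,
    radius = c(soma_diameter / 2, radii),
    parent = c(NA_integer_, seq_len(n)),
    label = c("soma", rep("axon", n)),
    stringsAsFactors = FALSE
  )
  new_morphology(seg, c(0, 0, 0))
}

#' Branched synthetic cell with one dominant process
#'
#' Emulates the salient geometry of elongated layer-V pyramidal cells: a long
#' trunk along +x plus `n_minor_branches` shorter processes from the soma at
#' randomized angles, at least one of which points opposite the trunk (the
#' configuration whose opposing longitudinal currents flip nearby magnetic
#' polarity and motivate the CNBE near-soma correction).
#'
#' @param trunk_length dominant process length (um).
#' @param n_minor_branches number of minor processes (0 reduces to a
#'   ball-stick topology).
#' @param branch_length minor process length (um).
#' @param seed integer seed; the same seed reproduces the morphology.
#' @param trunk_diameter,branch_diameter,soma_diameter diameters (um).
#' @param segment_length discretisation length (um).
#' @param taper_ratio proximal-to-distal trunk diameter ratio (default 3):
#'   the initial segment near the hillock is the thickest part of the
#'   dominant process and carries the largest axial current.
#' @param hillock_factor,hillock_length conical axon-hillock thickening of
#'   the trunk (see [make_ball_stick()]); on by default here because the
#'   polarity-boundary analyses rely on the hillock region producing the
#'   strongest normal-field signal, as it does for real cells.
#' @return A `neuro_morphology`.
#' @export
make_branched_cell <- function(trunk_length = 600, n_minor_branches = 2,
                               branch_length = 150, seed = 1,
                               trunk_diameter = 2, branch_diameter = 1.5,
                               soma_diameter = 20, segment_length = 10,
                               taper_ratio = 3, hillock_factor = 2.5,
                               hillock_length = 50) {
  if (!is.finite(trunk_length) || trunk_length <= 0) {
    stop("trunk_length must be positive")
  }
  if (n_minor_branches < 0) stop("n_minor_branches must be >= 0")
  if (n_minor_branches > 0 && (!is.finite(branch_length) || branch_length <= 0)) {
    stop("branch_length must be positive")
  }
  set.seed(as.integer(seed))
  straight_process <- function(angle_deg, length, radius, label, first_index,
                               taper = 1, hf = 1) {
    n <- max(1L, ceiling(length / segment_length))
    brk <- seq(0, length, length.out = n + 1L)
    mids <- (brk[-(n + 1L)] + brk[-1L]) / 2
    a <- angle_deg * pi / 180
    data.frame(
      x0 = brk[-(n + 1L)] * cos(a), y0 = brk[-(n + 1L)] * sin(a), z0 = 0,
      x1 = brk[-1L] * cos(a), y1 = brk[-1L] * sin(a), z1 = 0,
      radius = radius * (1 - mids / length * (1 - 1 / taper)) *
        (1 + (hf - 1) * exp(-mids / hillock_length)),
      parent = c(1L, first_index + seq_len(n - 1L) - 1L),
      label = label,
      stringsAsFactors = FALSE
    )
  }
  soma <- data.frame(
    x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = 0,
    radius = soma_diameter / 2, parent = NA_integer_, label = "soma",
    stringsAsFactors = FALSE
  )
  seg <- rbind(soma, straight_process(0, trunk_length, trunk_diameter / 2,
                                      "axon", 2L, taper = taper_ratio,
                                      hf = hillock_factor))
  if (n_minor_branches > 0) {
    # first minor branch opposes the trunk (180 deg +- 20); the rest are
    # uniform over directions at least 45 deg away from the trunk so no
    # branch shadows the dominant process
    angles <- c(
      180 + stats::runif(1, -20, 20),
      if (n_minor_branches > 1) stats::runif(n_minor_branches - 1, 45, 315)
    )
    for (a in angles) {
      seg <- rbind(seg, straight_process(a, branch_length,
                                         branch_diameter / 2, "dendrite",
                                         nrow(seg) + 1L))
    }
  }
  new_morphology(seg, c(0, 0, 0))
}

#' Flatten a morphology into a z-band
#'
#' Affine min-max rescale of all z coordinates into `[z_min, z_max]`
#' (x and y are untouched). A degenerate input range (all z equal) maps to the
#' interval midpoint. Used to keep cells within a thin slab above the sensor
#' plane, e.g. 5-25 um for in vitro arrays.
#'
#' @param m a `neuro_morphology`.
#' @param z_min,z_max band limits (um), `z_min < z_max`.
#' @return A flattened `neuro_morphology`.
#' @export
flatten_morphology <- function(m, z_min = 5, z_max = 25) {
  stopifnot(inherits(m, "neuro_morphology"))
  if (!(z_min < z_max)) stop("z_min must be < z_max")
  seg <- m$segments
  z <- c(seg$z0, seg$z1, m$soma_position[3])
  lo <- min(z); hi <- max(z)
  remap <- if (hi - lo < 1e-12) {
    function(v) rep((z_min + z_max) / 2, length(v))
  } else {
    function(v) z_min + (v - lo) / (hi - lo) * (z_max - z_min)
  }
  seg$z0 <- remap(seg$z0)
  seg$z1 <- remap(seg$z1)
  pos <- m$soma_position
  pos[3] <- remap(pos[3])
  new_morphology(seg, pos)
}

#' Rotate and translate a morphology in the sensor plane
#'
#' Rotation by `theta` degrees about the z-axis through the soma position
#' (counterclockwise viewed from +z), followed by an in-plane translation by
#' `delta`. A rigid transform: all pairwise distances are preserved.
#'
#' @param m a `neuro_morphology`.
#' @param theta rotation angle (degrees).
#' @param delta numeric length-2 in-plane translation (um).
#' @return The transformed `neuro_morphology`.
#' @export
transform_morphology <- function(m, theta = 0, delta = c(0, 0)) {
  stopifnot(inherits(m, "neuro_morphology"), length(delta) == 2L)
  a <- theta * pi / 180
  ca <- cos(a); sa <- sin(a)
  cx <- m$soma_position[1]; cy <- m$soma_position[2]
  rot <- function(x, y) {
    list(x = cx + ca * (x - cx) - sa * (y - cy) + delta[1],
         y = cy + sa * (x - cx) + ca * (y - cy) + delta[2])
  }
  seg <- m$segments
  p0 <- rot(seg$x0, seg$y0); p1 <- rot(seg$x1, seg$y1)
  seg$x0 <- p0$x; seg$y0 <- p0$y
  seg$x1 <- p1$x; seg$y1 <- p1$y
  pos <- m$soma_position
  pos[1] <- pos[1] + delta[1]
  pos[2] <- pos[2] + delta[2]
  new_morphology(seg, pos)
}
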