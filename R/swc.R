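# SWC import/export (standard 7-column node-per-line dialect).
# One node per segment endpoint: the root node is the soma (type 1, radius =
# sphere radius), every other node is a segment end whose parent is the node
# at the segment start. Round trips are lossless for coordinates, radii,
# topology and type codes.

.swc_type_to_label <- function(type) {
  out <- rep("dendrite", length(type))
  out[type == 1] <- "soma"
  out[type == 2] <- "axon"
  out
}

.label_to_swc_type <- function(label) {
  unname(c(soma = 1L, axon = 2L, dendrite = 3L)[label])
}

#' Read a morphology from an SWC file
#'
#' @param path file path to a 7-column SWC file
#'   (`id type x y z radius parent`).
#' @return A `neuro_morphology`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("SWC file contains no data lines")
  parse_line <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 7L) {
      stop(sprintf("malformed SWC line %d: expected 7 fields, got %d",
                   i, length(f)))
    }
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) stop(sprintf("malformed SWC line %d: non-numeric field", i))
    v
  }
  tab <- t(vapply(idx, parse_line, numeric(7)))
  colnames(tab) <- c("id", "type", "x", "y", "z", "radius", "parent")
  ids <- tab[, "id"]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate node id on SWC line %d",
                 idx[which(duplicated(ids))[1]]))
  }
  row_of <- function(id) match(id, ids)
  parents <- tab[, "parent"]
  roots <- which(parents == -1)
  if (length(roots) == 0L) stop("SWC file has no root node (parent = -1)")
  if (length(roots) > 1L) {
    stop(sprintf("multiple roots in SWC file (line %d)", idx[roots[2]]))
  }
  # cycle check by walking every node to the root
  n <- nrow(tab)
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (parents[j] != -1) {
      if (seen[j]) stop(sprintf("cyclic parent reference at SWC line %d", idx[i]))
      seen[j] <- TRUE
      pj <- row_of(parents[j])
      if (is.na(pj)) {
        stop(sprintf("SWC line %d references missing parent id %g",
                     idx[j], parents[j]))
      }
      j <- pj
    }
  }
  root <- roots[1]
  soma_pos <- tab[root, c("x", "y", "z")]
  # morphology segment k corresponds to SWC row order with root first
  ord <- c(root, setdiff(seq_len(n), root))
  seg_of_row <- match(seq_len(n), ord)
  seg <- data.frame(
    x0 = NA_real_, y0 = NA_real_, z0 = NA_real_,
    x1 = tab[ord, "x"], y1 = tab[ord, "y"], z1 = tab[ord, "z"],
    radius = tab[ord, "radius"],
    parent = NA_integer_,
    label = .swc_type_to_label(tab[ord, "type"]),
    stringsAsFactors = FALSE
  )
  for (k in seq_along(ord)) {
    r <- ord[k]
    if (parents[r] == -1) {
      seg$x0[k] <- tab[r, "x"]; seg$y0[k] <- tab[r, "y"]; seg$z0[k] <- tab[r, "z"]
    } else {
      pr <- row_of(parents[r])
      seg$x0[k] <- tab[pr, "x"]; seg$y0[k] <- tab[pr, "y"]; seg$z0[k] <- tab[pr, "z"]
      seg$parent[k] <- seg_of_row[pr]
    }
  }
  if (seg$label[1] != "soma") {
    stop("SWC root node must be a soma (type 1)")
  }
  new_morphology(seg, as.numeric(soma_pos))
}

#' Write a morphology to an SWC file
#'
#' @param m a `neuro_morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "neuro_morphology"))
  seg <- m$segments
  n <- nrow(seg)
  # node k = end point of segment k (node 1 = soma root)
  parent_node <- c(-1L, seg$parent[-1])
  lines <- sprintf(
    "%d %d %.9g %.9g %.9g %.9g %d",
    seq_len(n), .label_to_swc_type(seg$label),
    seg$x1, seg$y1, seg$z1, seg$radius, parent_node
  )
  writeLines(c("# SWC export (id type x y z radius parent)", lines), path)
  invisible(path)
}
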