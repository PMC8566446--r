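## SWC morphology container: read/write/validate/measure/rigid transform.
##
## Internal units are SI metres; SWC files carry micrometres and are
## converted at the I/O boundary. Nodes are kept in file order, which the
## format guarantees to be topologically sorted (parent id < node id).

SWC_SOMA <- 1L
SWC_AXON <- 2L
SWC_DEND <- c(3L, 4L)  # basal and apical dendrites are both "dendrite"

#' Construct a morphology from a node table
#'
#' @param nodes a data.frame with integer columns `id`, `type`, `parent` and
#'   numeric `x`, `y`, `z`, `radius` in metres. Must be topologically sorted
#'   (every `parent` appears before its children; root has parent -1).
#' @param name optional label carried through transforms.
#' @param validate check invariants (single root, sorted ids, positive radii,
#'   no axon/dendrite mixing along a path).
#' @return an object of class `morphology`.
#' @export
morphology <- function(nodes, name = "morphology", validate = TRUE) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(is.data.frame(nodes), all(req %in% names(nodes)))
  nodes <- as.data.frame(nodes)[, req]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  m <- structure(list(nodes = nodes, name = name), class = "morphology")
  if (validate) validate_morphology(m)
  m
}

#' @export
print.morphology <- function(x, ...) {
  n <- x$nodes
  cat(sprintf(
    "<morphology '%s': %d nodes (%d soma, %d axon, %d dendrite), cable %.1f um>\n",
    x$name, nrow(n), sum(n$type == SWC_SOMA), sum(n$type == SWC_AXON),
    sum(n$type %in% SWC_DEND), total_cable_length(x) / .unit_um))
  invisible(x)
}

#' Validate morphology invariants
#'
#' Checks: unique positive ids, topological sorting (`parent < id` or -1),
#' exactly one root, all parents present, positive radii, and that axon and
#' dendrite compartments never descend from one another.
#'
#' @param m a [morphology].
#' @return `m`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_morphology <- function(m) {
  n <- m$nodes
  if (nrow(n) == 0) stop("morphology has no nodes")
  if (anyDuplicated(n$id)) stop("duplicate node ids")
  if (any(n$id <= 0)) stop("node ids must be positive")
  root <- which(n$parent == -1L)
  if (length(root) != 1) stop("morphology must have exactly one root, found ",
                              length(root))
  if (any(n$parent >= n$id)) {
    bad <- which(n$parent >= n$id)[1]
    stop("node ", n$id[bad], " is not topologically sorted (parent ",
         n$parent[bad], " >= id); cycles are impossible in sorted files")
  }
  nonroot <- n$parent != -1L
  if (!all(n$parent[nonroot] %in% n$id)) {
    bad <- which(nonroot & !(n$parent %in% n$id))[1]
    stop("node ", n$id[bad], " references missing parent ", n$parent[bad])
  }
  if (any(!is.finite(c(n$x, n$y, n$z, n$radius)))) stop("non-finite coordinates")
  if (any(n$radius <= 0)) stop("radii must be positive")
  ptype <- n$type[match(n$parent, n$id)]
  mix <- nonroot &
    ((n$type == SWC_AXON & ptype %in% SWC_DEND) |
     (n$type %in% SWC_DEND & ptype == SWC_AXON))
  if (any(mix))
    stop("axon and dendrite compartments mix at node ", n$id[which(mix)[1]])
  invisible(m)
}

#' Read an SWC morphology file
#'
#' Seven whitespace-delimited columns (id, type, x, y, z, radius, parent),
#' `#` comment lines allowed; coordinates and radii in micrometres on disk,
#' converted to metres internally.
#'
#' @param path file path.
#' @param unknown_types `"error"` (default) rejects type codes >= 5;
#'   `"dendrite"` treats them as dendrite with a warning.
#' @return a [morphology].
#' @export
read_swc <- function(path, unknown_types = c("error", "dendrite")) {
  unknown_types <- match.arg(unknown_types)
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  rows <- raw[keep]
  if (length(rows) == 0) stop("empty SWC file: ", path)
  toks <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(toks)
  if (any(nf != 7))
    stop("SWC format error at line ", lineno[which(nf != 7)[1]],
         ": expected 7 columns, found ", nf[which(nf != 7)[1]])
  mat <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = 7,
                byrow = TRUE)
  if (anyNA(mat))
    stop("SWC format error at line ",
         lineno[which(rowSums(is.na(mat)) > 0)[1]], ": non-numeric field")
  nodes <- data.frame(
    id = as.integer(mat[, 1]), type = as.integer(mat[, 2]),
    x = mat[, 3] * .unit_um, y = mat[, 4] * .unit_um, z = mat[, 5] * .unit_um,
    radius = mat[, 6] * .unit_um, parent = as.integer(mat[, 7]))
  if (any(nodes$parent == nodes$id)) {
    bad <- which(nodes$parent == nodes$id)[1]
    stop("SWC format error at line ", lineno[bad], ": node ", nodes$id[bad],
         " is its own parent (cycle)")
  }
  unk <- nodes$type >= 5L | nodes$type < 0L
  if (any(unk)) {
    if (unknown_types == "dendrite") {
      warning("treating ", sum(unk), " nodes with unknown SWC type as dendrite")
      nodes$type[unk] <- 3L
    } else {
      stop("SWC format error at line ", lineno[which(unk)[1]],
           ": unknown type code ", nodes$type[which(unk)[1]])
    }
  }
  m <- try(morphology(nodes, name = basename(path)), silent = TRUE)
  if (inherits(m, "try-error"))
    stop("SWC format error in ", path, ": ",
         conditionMessage(attr(m, "condition")))
  m
}

#' Write a morphology to an SWC file
#'
#' Micrometres on disk, 6 significant digits, so that write -> read -> write
#' is bit-stable.
#'
#' @param m a [morphology].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  validate_morphology(m)
  n <- m$nodes
  fmt <- function(v) sprintf("%.6g", v / .unit_um)
  lines <- paste(n$id, n$type, fmt(n$x), fmt(n$y), fmt(n$z), fmt(n$radius),
                 n$parent)
  ok <- try(writeLines(c("# SWC written by touchnet", lines), path),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write SWC file: ", path)
  invisible(path)
}

# children index: list mapping row index -> integer vector of child row indices
morph_children <- function(m) {
  n <- m$nodes
  prow <- match(n$parent, n$id)
  split(seq_len(nrow(n))[!is.na(prow)], factor(prow[!is.na(prow)],
                                               levels = seq_len(nrow(n))))
}

# row indices of the subtree rooted at the node with the given id (inclusive)
subtree_rows <- function(m, node_id) {
  n <- m$nodes
  start <- match(node_id, n$id)
  if (is.na(start)) stop("unknown node id ", node_id)
  prow <- match(n$parent, n$id)
  inset <- logical(nrow(n))
  inset[start] <- TRUE
  # nodes are topologically sorted: one forward sweep suffices
  for (i in seq_len(nrow(n))[-seq_len(start)])
    if (!is.na(prow[i]) && inset[prow[i]]) inset[i] <- TRUE
  which(inset)
}

# per-node cumulative path distance to the root (metres), in row order
node_path_distances <- function(m) {
  n <- m$nodes
  prow <- match(n$parent, n$id)
  seg <- segment_lengths(m)
  d <- numeric(nrow(n))
  for (i in seq_len(nrow(n)))
    if (!is.na(prow[i])) d[i] <- d[prow[i]] + seg[i]
  d
}

# per-node length of the segment from its parent (0 for root / soma points)
segment_lengths <- function(m) {
  n <- m$nodes
  prow <- match(n$parent, n$id)
  seg <- numeric(nrow(n))
  ok <- !is.na(prow)
  seg[ok] <- sqrt((n$x[ok] - n$x[prow[ok]])^2 +
                  (n$y[ok] - n$y[prow[ok]])^2 +
                  (n$z[ok] - n$z[prow[ok]])^2)
  seg
}

#' Path distance from a node to the soma
#'
#' Sum of parent-child Euclidean segment lengths from the node up to the
#' root, in metres.
#'
#' @param m a [morphology].
#' @param node_id one or more node ids.
#' @return numeric vector of distances (metres); 0 for the root.
#' @export
path_distance_to_soma <- function(m, node_id) {
  rows <- match(node_id, m$nodes$id)
  if (anyNA(rows)) stop("unknown node id ", node_id[which(is.na(rows))[1]])
  node_path_distances(m)[rows]
}

#' Total cable length of a morphology
#'
#' @param m a [morphology].
#' @param types SWC type codes to include (default: dendrites and axon).
#' @return length in metres (soma points contribute nothing).
#' @export
total_cable_length <- function(m, types = c(SWC_AXON, SWC_DEND)) {
  seg <- segment_lengths(m)
  n <- m$nodes
  prow <- match(n$parent, n$id)
  # a segment belongs to its child node's compartment; segments leaving the
  # soma count fully (the usual morphometry convention)
  use <- !is.na(prow) & n$type %in% types
  sum(seg[use])
}

#' Rigidly transform a morphology
#'
#' Applies `p -> R p + t` to every node; radii unchanged. `R` must be a
#' proper rotation (orthonormal, det +1, checked to 1e-9).
#'
#' @param m a [morphology].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric, metres.
#' @return the transformed [morphology].
#' @export
transform_morphology <- function(m, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  if (!is_rotation_matrix(rotation))
    stop("rotation must be orthonormal with determinant +1")
  stopifnot(length(translation) == 3, is.finite(translation))
  n <- m$nodes
  xyz <- cbind(n$x, n$y, n$z) %*% t(rotation)
  n$x <- xyz[, 1] + translation[1]
  n$y <- xyz[, 2] + translation[2]
  n$z <- xyz[, 3] + translation[3]
  m$nodes <- n
  m
}

#' Soma centre and bounding radius
#'
#' Multi-point somas are collapsed to a sphere at the centroid of the soma
#' nodes whose radius is the largest of (distance from centroid to a soma
#' point) and the individual point radii (touch detection needs one body).
#'
#' @param m a [morphology].
#' @return list with `centre` (metres, length 3) and `radius` (metres).
#' @export
soma_sphere <- function(m) {
  s <- m$nodes[m$nodes$type == SWC_SOMA, , drop = FALSE]
  if (nrow(s) == 0) s <- m$nodes[m$nodes$parent == -1L, , drop = FALSE]
  ctr <- c(mean(s$x), mean(s$y), mean(s$z))
  dist <- sqrt((s$x - ctr[1])^2 + (s$y - ctr[2])^2 + (s$z - ctr[3])^2)
  list(centre = ctr, radius = max(dist + s$radius))
}

#' Neuron prototype descriptor
#'
#' Binds a morphology file to the opaque model metadata the simulator needs
#' (parameter/mechanism/modulation sets). Virtual prototypes (axons driven by
#' prescribed spike trains) need no mechanism or parameter sets.
#'
#' @param name prototype label.
#' @param neuron_type type label (e.g. `"dSPN"`).
#' @param morphology_path SWC file path.
#' @param parameter_set,mechanism_set,modulation_set opaque references.
#' @param is_virtual logical flag.
#' @return a `neuron_prototype` object.
#' @export
neuron_prototype <- function(name, neuron_type, morphology_path,
                             parameter_set = NULL, mechanism_set = NULL,
                             modulation_set = NULL, is_virtual = FALSE) {
  structure(list(name = name, neuron_type = neuron_type,
                 morphology_path = morphology_path,
                 parameter_set = parameter_set, mechanism_set = mechanism_set,
                 modulation_set = modulation_set,
                 is_virtual = isTRUE(is_virtual)),
            class = "neuron_prototype")
}
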