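## Synthetic fixtures: ball-and-stick grids with known synapse counts,
## distance ladders with prescribed path distances, and broken morphologies
## (z-jumps, slice cuts, zig-zags, asymmetric trees) with the ground truth
## recorded, so detection and repair can be verified against construction.

.mk_nodes <- function(type, xyz, radius, parent) {
  data.frame(id = seq_len(nrow(xyz)), type = type,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             radius = radius, parent = parent)
}

#' Ball-and-stick test morphology
#'
#' A soma with one straight dendrite (along +x) and one straight axon
#' (along -x), with the requested node counts and spacing.
#'
#' @param n_dend,n_axon nodes per neurite.
#' @param step node spacing, metres.
#' @param soma_radius metres.
#' @return a [morphology] with partitions of sizes 1 / `n_dend` / `n_axon`.
#' @export
make_ball_and_stick <- function(n_dend = 10, n_axon = 10, step = 10e-6,
                                soma_radius = 5e-6) {
  xyz <- rbind(c(0, 0, 0),
               cbind(seq_len(n_dend) * step, 0, 0),
               cbind(-seq_len(n_axon) * step, 0, 0))
  type <- c(1L, rep(3L, n_dend), rep(2L, n_axon))
  parent <- c(-1L,
              c(1L, seq_len(n_dend - 1) + 1L),
              c(1L, seq_len(n_axon - 1) + 1L + n_dend))
  morphology(.mk_nodes(type, xyz, c(soma_radius, rep(0.5e-6, n_dend + n_axon)),
                       parent),
             name = "ball_and_stick")
}

#' Grid fixture: neuron pairs with an exact synapse count
#'
#' Builds `pairs` disjoint pre/post ball-and-stick neuron pairs whose axon
#' and dendrite share exactly `syn_per_pair` voxels each, so touch
#' detection yields `syn_per_pair` putative synapses per directed pair and
#' none elsewhere. All coordinates sit on voxel-centre lattice points, so
#' counts are invariant under global translation by whole voxels.
#'
#' @param pairs number of directed pre -> post pairs (>= 1).
#' @param syn_per_pair synapses per pair (>= 1).
#' @param voxel_size voxel side, metres (default 3 um).
#' @param verify run touch detection and assert the construction
#'   post-condition (default `FALSE`; the acceptance tests do it anyway).
#' @return list: `morphologies` (prototypes `bas_post`, `bas_pre`),
#'   `placement` (a `placement_result`), `allowed_pairs`, `voxel_size`,
#'   `expected` data.frame of (pre, post, n) ground truth.
#' @export
make_grid_fixture <- function(pairs, syn_per_pair, voxel_size = 3e-6,
                              verify = FALSE) {
  stopifnot(pairs >= 1, syn_per_pair >= 1)
  v <- voxel_size
  k <- syn_per_pair
  # post (soma + dendrite): local coords, soma at origin
  dend_len_vox <- k + 9
  post <- morphology(.mk_nodes(
    type = c(1L, 3L, 3L),
    xyz = rbind(c(0, 0, 0), c(2 * v, 0, 0), c(dend_len_vox * v, 0, 0)),
    radius = c(1.2e-6, 0.5e-6, 0.5e-6),
    parent = c(-1L, 1L, 2L)), name = "bas_post")
  # pre (soma + L-shaped axon): soma at origin; axon runs along x at the
  # soma's y, drops 6 voxels in y to the dendrite row, then overlap run
  x0 <- 6 * v                  # world x of the vertical approach (voxel 4)
  pre <- morphology(.mk_nodes(
    type = c(1L, 2L, 2L, 2L),
    xyz = rbind(c(0, 0, 0), c(x0, 0, 0), c(x0, -6 * v, 0),
                c(x0 + (k - 1) * v, -6 * v, 0)),
    radius = c(1.2e-6, 0.5e-6, 0.5e-6, 0.5e-6),
    parent = c(-1L, 1L, 2L, 3L)), name = "bas_pre")
  # world positions: pair p occupies its own slab of 20 voxels in z
  post_pos <- function(p) c(-1.5 * v, 0.5 * v, (20 * p + 0.5) * v)
  pre_pos <- function(p) c(-1.5 * v, 6.5 * v, (20 * p + 0.5) * v)
  n2 <- 2L * pairs
  pos <- matrix(0, n2, 3)
  proto <- character(n2)
  for (p in seq_len(pairs)) {
    pos[2 * p - 1, ] <- post_pos(p - 1)
    pos[2 * p, ] <- pre_pos(p - 1)
    proto[2 * p - 1] <- "bas_post"
    proto[2 * p] <- "bas_pre"
  }
  neurons <- data.frame(id = seq_len(n2) - 1L, prototype = proto,
                        type = "bas", x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        volume = "fixture", unit = 0L,
                        stringsAsFactors = FALSE)
  placement <- structure(
    list(neurons = neurons, rotations = rep(list(diag(3)), n2),
         padding = matrix(numeric(0), 0, 3), d_min = 0, volume = "fixture"),
    class = "placement_result")
  expected <- data.frame(pre = neurons$id[seq(2, n2, by = 2)],
                         post = neurons$id[seq(1, n2, by = 2)],
                         n = syn_per_pair)
  fx <- list(morphologies = list(bas_post = post, bas_pre = pre),
             placement = placement,
             allowed_pairs = data.frame(pre = "bas", post = "bas"),
             voxel_size = voxel_size, expected = expected)
  if (verify) {
    det <- detect_network(placement, fx$morphologies, fx$allowed_pairs,
                          voxel_size = voxel_size)
    tab <- table(paste(det$synapses$pre, det$synapses$post))
    if (nrow(det$synapses) != pairs * syn_per_pair ||
        length(tab) != pairs || any(tab != syn_per_pair))
      stop("grid fixture post-condition failed: geometry infeasible at ",
           pairs, " x ", syn_per_pair)
  }
  fx
}

#' Distance-ladder fixture: synapses at prescribed path distances
#'
#' `length(distances)` presynaptic axons cross `syn_per_distance` parallel
#' straight dendrites, producing `syn_per_distance` putative synapses at
#' (within half a voxel of) each requested path distance to the
#' postsynaptic soma.
#'
#' @param distances increasing positive path distances, metres.
#' @param syn_per_distance synapses at each distance.
#' @param voxel_size voxel side, metres.
#' @return list like [make_grid_fixture()] plus `snapped_distances` (the
#'   voxel-centre distances actually realised, metres).
#' @export
make_distance_ladder <- function(distances, syn_per_distance = 20,
                                 voxel_size = 3e-6) {
  stopifnot(all(distances > 0), !is.unsorted(distances, strictly = TRUE),
            syn_per_distance >= 1)
  v <- voxel_size
  s <- syn_per_distance
  kx <- round(distances / v - 0.5)      # voxel column per distance
  if (anyDuplicated(kx)) stop("distances collide within one voxel")
  xcol <- (kx + 0.5) * v
  dend_len <- (max(kx) + 10) * v
  post <- morphology(.mk_nodes(
    type = c(1L, 3L, 3L),
    xyz = rbind(c(0, 0, 0), c(dend_len / 2, 0, 0), c(dend_len, 0, 0)),
    radius = c(1e-6, 0.5e-6, 0.5e-6), parent = c(-1L, 1L, 2L)),
    name = "ladder_post")
  # pre: soma below the dendrite plane, axon rising through all dendrite rows
  rise <- (s + 10) * v
  pre <- morphology(.mk_nodes(
    type = c(1L, 2L),
    xyz = rbind(c(0, 0, 0), c(0, rise, 0)),
    radius = c(1e-6, 0.5e-6), parent = c(-1L, 1L)), name = "ladder_pre")
  n_pre <- length(distances)
  ids <- seq_len(s + n_pre) - 1L
  neurons <- data.frame(
    id = ids,
    prototype = c(rep("ladder_post", s), rep("ladder_pre", n_pre)),
    type = "bas",
    x = c(rep(0, s), xcol),
    y = c((seq_len(s) - 1 + 0.5) * v, rep(-7.5 * v, n_pre)),
    z = 0.5 * v, volume = "fixture", unit = 0L, stringsAsFactors = FALSE)
  placement <- structure(
    list(neurons = neurons, rotations = rep(list(diag(3)), s + n_pre),
         padding = matrix(numeric(0), 0, 3), d_min = 0, volume = "fixture"),
    class = "placement_result")
  list(morphologies = list(ladder_post = post, ladder_pre = pre),
       placement = placement,
       allowed_pairs = data.frame(pre = "bas", post = "bas"),
       voxel_size = voxel_size,
       snapped_distances = xcol)
}

#' Dendrite fixture with one inserted z-jump
#'
#' A gently curved planar dendrite with the downstream part shifted along z
#' by `dz` at a known node (recorded in attribute `zjump_node`).
#'
#' @param dz signed z offset, metres.
#' @param n nodes in the dendrite.
#' @param step node spacing, metres.
#' @return a [morphology] with attributes `zjump_node` and `dz`.
#' @export
make_zjump_fixture <- function(dz = 5e-6, n = 12, step = 3e-6) {
  stopifnot(n >= 6)
  xs <- seq_len(n) * step
  ys <- 2e-6 * sin(seq_len(n) / 3)  # mild curvature, no vertical steps
  zs <- rep(0, n)
  at <- floor(n / 2)
  zs[at:n] <- zs[at:n] + dz
  nodes <- .mk_nodes(
    type = c(1L, rep(3L, n)),
    xyz = rbind(c(0, 0, 0), cbind(xs, ys, zs)),
    radius = c(4e-6, rep(0.5e-6, n)),
    parent = c(-1L, 1L, seq_len(n - 1) + 1L))
  m <- morphology(nodes, name = "zjump_fixture")
  attr(m, "zjump_node") <- at + 1L  # node ids offset by the soma
  attr(m, "dz") <- dz
  m
}

#' Star morphology with one branch pair truncated at a slice face
#'
#' Four primary dendrites, each bifurcating once. One primary points up and
#' its two daughter branches are clipped at the plane `z = cut_z`, leaving
#' two coincident leaves there (the cut points). The removed cable length is
#' recorded in attribute `removed_length`.
#'
#' @param cut truncate the +z branch pair (default `TRUE`; `FALSE` gives the
#'   intact control).
#' @param cut_z slice face, metres.
#' @return a [morphology]; attributes `removed_length`, `cut_leaves`.
#' @export
make_cut_fixture <- function(cut = TRUE, cut_z = 60e-6) {
  prim_dirs <- rbind(c(0, 0, 1), c(1, 0.2, -0.3), c(-0.8, 0.6, -0.2),
                     c(0.1, -1, -0.4))
  prim_dirs <- prim_dirs / sqrt(rowSums(prim_dirs^2))
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 5e-6, parent = -1L)
  nid <- 1L
  add <- function(nodes, from_id, dir, len, npts) {
    p0 <- as.numeric(nodes[match(from_id, nodes$id), c("x", "y", "z")])
    for (i in seq_len(npts)) {
      nid <<- nid + 1L
      nodes <- rbind(nodes, data.frame(
        id = nid, type = 3L,
        x = p0[1] + dir[1] * len * i / npts,
        y = p0[2] + dir[2] * len * i / npts,
        z = p0[3] + dir[3] * len * i / npts,
        radius = 0.6e-6, parent = if (i == 1) from_id else nid - 1L))
    }
    nodes
  }
  perp <- function(d) {
    p <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(d[2] * p[3] - d[3] * p[2], d[3] * p[1] - d[1] * p[3],
           d[1] * p[2] - d[2] * p[1])
    v / sqrt(sum(v^2))
  }
  for (b in seq_len(4)) {
    d <- prim_dirs[b, ]
    nodes <- add(nodes, 1L, d, 40e-6, 4)
    bp <- nid
    w <- perp(d)
    for (sgn in c(1, -1)) {
      dir2 <- d + 0.6 * sgn * w
      dir2 <- dir2 / sqrt(sum(dir2^2))
      # daughters differ slightly in length so intact leaves never share an
      # extreme z plane (a slice cut, by contrast, leaves coincident leaves)
      nodes <- add(nodes, bp, dir2, if (sgn > 0) 45e-6 else 43e-6, 5)
    }
  }
  m <- morphology(nodes, name = "cut_fixture")
  attr(m, "removed_length") <- 0
  if (!cut) return(m)
  # clip nodes above the face; move the last surviving node of each clipped
  # branch exactly onto the face
  n <- m$nodes
  removed <- 0
  drop <- which(n$z > cut_z)
  prow <- match(n$parent, n$id)
  seg <- segment_lengths(m)
  removed <- sum(seg[drop])
  keep <- setdiff(seq_len(nrow(n)), drop)
  n2 <- n[keep, ]
  # leaves created by the clip: nodes whose child was dropped; project the
  # clipped segment onto the face so the leaf sits exactly at z = cut_z
  clipped_parents <- unique(prow[drop][!(prow[drop] %in% drop)])
  cut_leaf_ids <- integer(0)
  for (cp in clipped_parents) {
    child <- drop[which(prow[drop] == cp)[1]]
    p0 <- as.numeric(n[cp, c("x", "y", "z")])
    p1 <- as.numeric(n[child, c("x", "y", "z")])
    t <- (cut_z - p0[3]) / (p1[3] - p0[3])
    newpt <- p0 + t * (p1 - p0)
    removed <- removed - sqrt(sum((newpt - p0)^2))
    nid2 <- max(n2$id) + 1L
    n2 <- rbind(n2, data.frame(id = nid2, type = 3L, x = newpt[1],
                               y = newpt[2], z = newpt[3], radius = 0.6e-6,
                               parent = n$id[cp]))
    cut_leaf_ids <- c(cut_leaf_ids, nid2)
  }
  m2 <- morphology(n2, name = "cut_fixture")
  attr(m2, "removed_length") <- removed
  attr(m2, "cut_leaves") <- cut_leaf_ids
  m2
}

#' Zig-zag dendrite section (contracted neurite stand-in)
#'
#' A single dendritic section zig-zagging in the xy plane: total cable
#' length much larger than its end-to-end distance, for unravelling tests.
#'
#' @param n nodes.
#' @param step zig-zag step, metres.
#' @return a [morphology].
#' @export
make_zigzag_fixture <- function(n = 20, step = 5e-6) {
  xs <- seq_len(n) * step
  ys <- step * 1.5 * (seq_len(n) %% 2)
  nodes <- .mk_nodes(
    type = c(1L, rep(3L, n)),
    xyz = rbind(c(0, 0, 0), cbind(xs, ys, 0)),
    radius = c(4e-6, rep(0.5e-6, n)),
    parent = c(-1L, 1L, seq_len(n - 1) + 1L))
  morphology(nodes, name = "zigzag_fixture")
}

#' Asymmetric bifurcating tree (fast-spiking-interneuron-like)
#'
#' All primary dendrites leave the soma within a cone about +x and each
#' bifurcates twice, with daughters bent consistently to one side, so the
#' cloud of dendritic terminations is strongly anisotropic. Random twisting
#' at the bifurcations restores symmetry around each primary axis.
#'
#' @param n_primary primary dendrites.
#' @return a [morphology].
#' @export
make_asymmetric_fixture <- function(n_primary = 4) {
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 5e-6, parent = -1L)
  nid <- 1L
  grow <- function(nodes, from_id, dir, len, npts) {
    p0 <- as.numeric(nodes[match(from_id, nodes$id), c("x", "y", "z")])
    dir <- dir / sqrt(sum(dir^2))
    for (i in seq_len(npts)) {
      nid <<- nid + 1L
      nodes <- rbind(nodes, data.frame(
        id = nid, type = 3L,
        x = p0[1] + dir[1] * len * i / npts,
        y = p0[2] + dir[2] * len * i / npts,
        z = p0[3] + dir[3] * len * i / npts,
        radius = 0.6e-6, parent = if (i == 1) from_id else nid - 1L))
    }
    nodes
  }
  for (b in seq_len(n_primary)) {
    ang <- 2 * pi * (b - 1) / n_primary
    d1 <- c(1, 0.3 * cos(ang), 0.3 * sin(ang))
    nodes <- grow(nodes, 1L, d1, 30e-6, 3)
    bp1 <- nid
    for (s1 in c(1, -1)) {
      d2 <- d1 + c(0, 0.35 * s1, 0.45)  # biased: both daughters bend up
      nodes <- grow(nodes, bp1, d2, 25e-6, 3)
      bp2 <- nid
      for (s2 in c(1, -1)) {
        d3 <- d2 + c(0, 0.25 * s2, 0.4)
        nodes <- grow(nodes, bp2, d3, 20e-6, 2)
      }
    }
  }
  morphology(nodes, name = "asymmetric_fixture")
}

#' Coordinates of dendritic terminations
#'
#' @param m a [morphology].
#' @return matrix (leaves x 3), metres.
#' @export
dendritic_terminations <- function(m) {
  nch <- .child_counts(m)
  rows <- which(nch == 0 & m$nodes$type %in% SWC_DEND)
  as.matrix(m$nodes[rows, c("x", "y", "z")])
}
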