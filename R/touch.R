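## Voxel-based touch detection.
##
## Neurites are rasterized into cubic voxels (default 3 um side). A voxel
## holding the axon of one neuron and the dendrite (or soma) of another is a
## putative synapse if the type pair is allowed; dendrite-dendrite
## co-occupancy gives gap junctions. Voxels are grouped into hypervoxels
## (default 100^3 voxels) which tile space without overlap and can be
## processed independently; voxel ownership by lattice floor division makes
## the decomposition exact.

VOXEL_SIZE_DEFAULT <- 3e-6
HYPERVOXEL_VOXELS_DEFAULT <- 100L

#' Create an empty voxel occupancy grid
#'
#' @param voxel_size voxel side, metres (default 3 um).
#' @param origin grid origin, metres; voxel indices are
#'   `floor((p - origin)/voxel_size)`.
#' @return a `voxel_grid` with separate axon and dendrite occupancy tables.
#' @export
voxel_grid <- function(voxel_size = VOXEL_SIZE_DEFAULT, origin = c(0, 0, 0)) {
  stopifnot(voxel_size > 0)
  empty <- data.table::data.table(
    vx = integer(), vy = integer(), vz = integer(), neuron = integer(),
    type = character(), section = integer(), offset = numeric(),
    dist_to_soma = numeric())
  structure(list(voxel_size = voxel_size, origin = origin,
                 axon = empty, dend = data.table::copy(empty)),
            class = "voxel_grid")
}

# Exact supercover traversal of segment [p0, p1]: all voxels whose interior
# the segment passes through (the limit of infinitesimal-step line parsing).
# Returns integer voxel indices and the parametric midpoint t of the
# in-voxel portion, used to interpolate path distance.
segment_voxels <- function(p0, p1, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(all(is.finite(p0)), all(is.finite(p1)))
  a <- (p0 - origin) / voxel_size
  b <- (p1 - origin) / voxel_size
  d <- b - a
  if (max(abs(d)) < 1e-12) {
    return(data.frame(vx = floor(a[1]), vy = floor(a[2]), vz = floor(a[3]),
                      t = 0.5))
  }
  ts <- c(0, 1)
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-12) next
    ks <- seq(ceiling(min(a[ax], b[ax])), floor(max(a[ax], b[ax])))
    if (length(ks)) ts <- c(ts, (ks - a[ax]) / d[ax])
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  tm <- (head(ts, -1) + tail(ts, -1)) / 2
  tm <- tm[diff(ts) > 1e-12]
  px <- floor(a[1] + tm * d[1])
  py <- floor(a[2] + tm * d[2])
  pz <- floor(a[3] + tm * d[3])
  keep <- !duplicated(cbind(px, py, pz))
  data.frame(vx = px[keep], vy = py[keep], vz = pz[keep], t = tm[keep])
}

#' Rasterize one neurite segment into the grid
#'
#' Marks every voxel the segment passes through (exact supercover; the limit
#' of the small-step line-parsing description). Duplicate marks for the same
#' (voxel, neuron, kind) collapse at detection time.
#'
#' @param grid a [voxel_grid()].
#' @param p0,p1 segment end points, metres.
#' @param neuron_id integer neuron id.
#' @param kind `"axon"` or `"dend"`.
#' @param section section (node) id for bookkeeping.
#' @param dist0,dist1 path distance to soma at `p0` and `p1`, metres.
#' @return the updated grid.
#' @export
rasterize_segment <- function(grid, p0, p1, neuron_id, kind = c("axon", "dend"),
                              section = 0L, dist0 = 0, dist1 = 0) {
  kind <- match.arg(kind)
  sv <- segment_voxels(p0, p1, grid$voxel_size, grid$origin)
  add <- data.table::data.table(
    vx = as.integer(sv$vx), vy = as.integer(sv$vy), vz = as.integer(sv$vz),
    neuron = as.integer(neuron_id), type = kind,
    section = as.integer(section), offset = sv$t,
    dist_to_soma = dist0 + sv$t * (dist1 - dist0))
  slot <- if (kind == "axon") "axon" else "dend"
  grid[[slot]] <- data.table::rbindlist(list(grid[[slot]], add))
  grid
}

#' Rasterize a soma sphere into the grid (as postsynaptic target)
#'
#' Marks every voxel whose centre lies within `radius` of `centre` as
#' dendrite-kind occupancy with path distance 0.
#'
#' @param grid a [voxel_grid()].
#' @param centre soma centre, metres.
#' @param radius soma radius, metres (> 0).
#' @param neuron_id integer neuron id.
#' @param section section id recorded for the soma voxels.
#' @return the updated grid.
#' @export
rasterize_soma <- function(grid, centre, radius, neuron_id, section = 0L) {
  stopifnot(radius > 0)
  vs <- grid$voxel_size
  c0 <- (centre - grid$origin) / vs
  rng <- function(ax) seq(floor(c0[ax] - radius / vs - 1),
                          floor(c0[ax] + radius / vs + 1))
  g <- expand.grid(vx = rng(1), vy = rng(2), vz = rng(3))
  ctr <- cbind(g$vx + 0.5, g$vy + 0.5, g$vz + 0.5)
  keep <- (ctr[, 1] - c0[1])^2 + (ctr[, 2] - c0[2])^2 +
    (ctr[, 3] - c0[3])^2 <= (radius / vs)^2
  if (!any(keep)) {  # tiny soma: mark its containing voxel
    g <- data.frame(vx = floor(c0[1]), vy = floor(c0[2]), vz = floor(c0[3]))
    keep <- TRUE
  }
  add <- data.table::data.table(
    vx = as.integer(g$vx[keep]), vy = as.integer(g$vy[keep]),
    vz = as.integer(g$vz[keep]), neuron = as.integer(neuron_id),
    type = "dend", section = as.integer(section), offset = 0,
    dist_to_soma = 0)
  grid$dend <- data.table::rbindlist(list(grid$dend, add))
  grid
}

#' Rasterize a whole placed morphology
#'
#' The morphology is transformed by the neuron's placement rotation and
#' position (soma centroid moved to the position), then axon segments go to
#' axon occupancy and dendrite segments plus the soma sphere to dendrite
#' occupancy.
#'
#' @param grid a [voxel_grid()].
#' @param m a [morphology] in local coordinates (soma near origin).
#' @param neuron_id integer id.
#' @param position placement position, metres.
#' @param rotation 3x3 rotation matrix.
#' @param voxel_filter optional function(vx, vy, vz) -> logical, used by the
#'   hypervoxel decomposition to keep only owned voxels.
#' @return the updated grid.
#' @export
rasterize_morphology <- function(grid, m, neuron_id, position = c(0, 0, 0),
                                 rotation = diag(3), voxel_filter = NULL) {
  mw <- transform_morphology(m, rotation, position)
  n <- mw$nodes
  prow <- match(n$parent, n$id)
  dists <- node_path_distances(mw)
  segs <- which(!is.na(prow) & n$type != SWC_SOMA)
  for (i in segs) {
    j <- prow[i]
    kind <- if (n$type[i] == SWC_AXON) "axon" else "dend"
    grid <- rasterize_segment(grid, c(n$x[j], n$y[j], n$z[j]),
                              c(n$x[i], n$y[i], n$z[i]),
                              neuron_id, kind, section = n$id[i],
                              dist0 = dists[j], dist1 = dists[i])
  }
  sp <- soma_sphere(mw)
  grid <- rasterize_soma(grid, sp$centre, sp$radius, neuron_id,
                         section = mw$nodes$id[mw$nodes$parent == -1L][1])
  if (!is.null(voxel_filter)) {
    for (slot in c("axon", "dend")) {
      tb <- grid[[slot]]
      if (nrow(tb)) grid[[slot]] <- tb[voxel_filter(tb$vx, tb$vy, tb$vz)]
    }
  }
  grid
}

# collapse occupancy to one row per (voxel, neuron): smallest path distance
# wins so the recorded synapse distance is the most proximal apposition.
.collapse_occupancy <- function(tb) {
  if (!nrow(tb)) return(tb)
  data.table::setorder(tb, vx, vy, vz, neuron, dist_to_soma, section)
  tb[!duplicated(tb[, c("vx", "vy", "vz", "neuron")]), ]
}

#' Detect putative synapses from a populated grid
#'
#' One putative synapse per (pre neuron, post neuron, voxel) where the pre
#' axon and the post dendrite/soma co-occupy the voxel and the (pre type,
#' post type) pair is allowed. Self-touches are excluded. Synapse positions
#' are voxel centres.
#'
#' @param grid a populated [voxel_grid()].
#' @param neuron_types named character vector mapping neuron id (as
#'   character) to neuron type.
#' @param allowed_pairs data.frame with columns `pre`, `post` of allowed
#'   type pairs; `NULL` allows everything.
#' @return data.frame: `pre`, `post`, voxel indices, position (metres),
#'   `section`, `offset`, `dist_to_soma` (post path distance), `type_pair`.
#' @export
detect_touches <- function(grid, neuron_types = NULL, allowed_pairs = NULL) {
  ax <- .collapse_occupancy(data.table::copy(grid$axon))
  dd <- .collapse_occupancy(data.table::copy(grid$dend))
  if (!nrow(ax) || !nrow(dd)) return(.empty_synapses())
  hits <- merge(ax, dd, by = c("vx", "vy", "vz"), allow.cartesian = TRUE,
                suffixes = c("_pre", "_post"))
  hits <- hits[hits$neuron_pre != hits$neuron_post, ]
  if (!nrow(hits)) return(.empty_synapses())
  if (!is.null(neuron_types)) {
    pre_t <- unname(neuron_types[as.character(hits$neuron_pre)])
    post_t <- unname(neuron_types[as.character(hits$neuron_post)])
    hits$type_pair <- paste(pre_t, post_t, sep = ",")
    if (!is.null(allowed_pairs)) {
      ok <- hits$type_pair %in% paste(allowed_pairs$pre, allowed_pairs$post,
                                      sep = ",")
      hits <- hits[ok, ]
    }
  } else hits$type_pair <- NA_character_
  if (!nrow(hits)) return(.empty_synapses())
  vs <- grid$voxel_size
  out <- data.frame(
    pre = hits$neuron_pre, post = hits$neuron_post,
    vx = hits$vx, vy = hits$vy, vz = hits$vz,
    x = grid$origin[1] + (hits$vx + 0.5) * vs,
    y = grid$origin[2] + (hits$vy + 0.5) * vs,
    z = grid$origin[3] + (hits$vz + 0.5) * vs,
    section = hits$section_post, offset = hits$offset_post,
    dist_to_soma = hits$dist_to_soma_post,
    type_pair = hits$type_pair, stringsAsFactors = FALSE)
  out[order(out$pre, out$post, out$vx, out$vy, out$vz), , drop = FALSE]
}

.empty_synapses <- function() {
  data.frame(pre = integer(), post = integer(), vx = integer(),
             vy = integer(), vz = integer(), x = numeric(), y = numeric(),
             z = numeric(), section = integer(), offset = numeric(),
             dist_to_soma = numeric(), type_pair = character(),
             stringsAsFactors = FALSE)
}

#' Detect gap junctions (dendrite-dendrite co-occupancy)
#'
#' Unordered neuron pairs, stored once with `a < b`, one junction per
#' co-occupied voxel.
#'
#' @inheritParams detect_touches
#' @param allowed_pairs allowed type pairs (unordered; both orders accepted).
#' @return data.frame: `a`, `b`, voxel indices, position, sections/offsets
#'   of both sides.
#' @export
detect_gap_junctions <- function(grid, neuron_types = NULL,
                                 allowed_pairs = NULL) {
  dd <- .collapse_occupancy(data.table::copy(grid$dend))
  empty <- data.frame(a = integer(), b = integer(), vx = integer(),
                      vy = integer(), vz = integer(), x = numeric(),
                      y = numeric(), z = numeric(),
                      section_a = integer(), section_b = integer(),
                      offset_a = numeric(), offset_b = numeric())
  if (!nrow(dd)) return(empty)
  hits <- merge(dd, dd, by = c("vx", "vy", "vz"), allow.cartesian = TRUE,
                suffixes = c("_a", "_b"))
  hits <- hits[hits$neuron_a < hits$neuron_b, ]
  if (!nrow(hits)) return(empty)
  if (!is.null(neuron_types) && !is.null(allowed_pairs)) {
    ta <- unname(neuron_types[as.character(hits$neuron_a)])
    tb <- unname(neuron_types[as.character(hits$neuron_b)])
    keys <- c(paste(allowed_pairs$pre, allowed_pairs$post, sep = ","),
              paste(allowed_pairs$post, allowed_pairs$pre, sep = ","))
    hits <- hits[paste(ta, tb, sep = ",") %in% keys, ]
  }
  if (!nrow(hits)) return(empty)
  vs <- grid$voxel_size
  out <- data.frame(
    a = hits$neuron_a, b = hits$neuron_b,
    vx = hits$vx, vy = hits$vy, vz = hits$vz,
    x = grid$origin[1] + (hits$vx + 0.5) * vs,
    y = grid$origin[2] + (hits$vy + 0.5) * vs,
    z = grid$origin[3] + (hits$vz + 0.5) * vs,
    section_a = hits$section_a, section_b = hits$section_b,
    offset_a = hits$offset_a, offset_b = hits$offset_b)
  out[order(out$a, out$b, out$vx, out$vy, out$vz), , drop = FALSE]
}

#' Map neurons to the hypervoxels their neurites reach
#'
#' A neuron is listed in every hypervoxel intersected by the axis-aligned
#' bounding box of any of its segments (or its soma sphere), after placement.
#'
#' @param placement a `placement_result`.
#' @param morphologies named list of [morphology] objects keyed by prototype.
#' @param voxel_size voxel side, metres.
#' @param hv_voxels hypervoxel extent in voxels per side (default 100).
#' @param origin grid origin.
#' @return named list: hypervoxel key `"i_j_k"` -> integer neuron ids.
#' @export
assign_neurons_to_hypervoxels <- function(placement, morphologies,
                                          voxel_size = VOXEL_SIZE_DEFAULT,
                                          hv_voxels = HYPERVOXEL_VOXELS_DEFAULT,
                                          origin = c(0, 0, 0)) {
  hv_size <- voxel_size * hv_voxels
  res <- new.env(parent = emptyenv())
  nn <- placement$neurons
  for (i in seq_len(nrow(nn))) {
    m <- morphologies[[nn$prototype[i]]]
    mw <- transform_morphology(m, placement$rotations[[i]],
                               c(nn$x[i], nn$y[i], nn$z[i]))
    nd <- mw$nodes
    prow <- match(nd$parent, nd$id)
    keys <- character(0)
    segs <- which(!is.na(prow))
    if (length(segs)) {
      lo <- cbind(pmin(nd$x[segs], nd$x[prow[segs]]),
                  pmin(nd$y[segs], nd$y[prow[segs]]),
                  pmin(nd$z[segs], nd$z[prow[segs]]))
      hi <- cbind(pmax(nd$x[segs], nd$x[prow[segs]]),
                  pmax(nd$y[segs], nd$y[prow[segs]]),
                  pmax(nd$z[segs], nd$z[prow[segs]]))
      for (s in seq_along(segs)) {
        r <- lapply(1:3, function(ax)
          seq(floor((lo[s, ax] - origin[ax]) / hv_size),
              floor((hi[s, ax] - origin[ax]) / hv_size)))
        g <- expand.grid(r[[1]], r[[2]], r[[3]])
        keys <- c(keys, paste(g[, 1], g[, 2], g[, 3], sep = "_"))
      }
    }
    sp <- soma_sphere(mw)
    r <- lapply(1:3, function(ax)
      seq(floor((sp$centre[ax] - sp$radius - origin[ax]) / hv_size),
          floor((sp$centre[ax] + sp$radius - origin[ax]) / hv_size)))
    g <- expand.grid(r[[1]], r[[2]], r[[3]])
    keys <- unique(c(keys, paste(g[, 1], g[, 2], g[, 3], sep = "_")))
    for (k in keys) res[[k]] <- c(res[[k]], nn$id[i])
  }
  out <- as.list(res)
  out[order(names(out))]
}

#' Hypervoxel processing order
#'
#' Most-populated hypervoxels first (load balancing); ties broken by
#' lexicographic lattice coordinates for stability.
#'
#' @param hv_map from [assign_neurons_to_hypervoxels()].
#' @return character vector of hypervoxel keys in processing order.
#' @export
order_hypervoxels <- function(hv_map) {
  if (!length(hv_map)) return(character(0))
  counts <- vapply(hv_map, length, integer(1))
  coords <- do.call(rbind, lapply(strsplit(names(hv_map), "_"), as.integer))
  names(hv_map)[order(-counts, coords[, 1], coords[, 2], coords[, 3])]
}

#' Full touch detection over a placed network
#'
#' Rasterizes every placed morphology and detects synapses and gap
#' junctions. With `by_hypervoxel = TRUE` the work is decomposed into
#' independent hypervoxels (each voxel owned by exactly one hypervoxel via
#' lattice floor division) and the per-hypervoxel results are concatenated;
#' the synapse set is identical to the single-grid computation.
#'
#' @param placement a `placement_result`.
#' @param morphologies named list of [morphology] keyed by prototype name.
#' @param allowed_pairs data.frame (`pre`, `post`) of allowed synapse type
#'   pairs, or `NULL` for all.
#' @param gj_pairs allowed gap-junction type pairs, or `NULL` for none.
#' @param voxel_size,hv_voxels,origin grid geometry.
#' @param by_hypervoxel use the hypervoxel decomposition.
#' @return list: `synapses`, `gap_junctions`, `hv_order` (processing order
#'   used, if decomposed).
#' @export
detect_network <- function(placement, morphologies, allowed_pairs = NULL,
                           gj_pairs = NULL,
                           voxel_size = VOXEL_SIZE_DEFAULT,
                           hv_voxels = HYPERVOXEL_VOXELS_DEFAULT,
                           origin = c(0, 0, 0), by_hypervoxel = FALSE) {
  nn <- placement$neurons
  ntypes <- stats::setNames(nn$type, as.character(nn$id))
  rast_one <- function(ids, voxel_filter = NULL) {
    g <- voxel_grid(voxel_size, origin)
    for (i in which(nn$id %in% ids)) {
      g <- rasterize_morphology(g, morphologies[[nn$prototype[i]]], nn$id[i],
                                c(nn$x[i], nn$y[i], nn$z[i]),
                                placement$rotations[[i]], voxel_filter)
    }
    g
  }
  if (!by_hypervoxel) {
    g <- rast_one(nn$id)
    syn <- detect_touches(g, ntypes, allowed_pairs)
    gj <- if (is.null(gj_pairs)) NULL else detect_gap_junctions(g, ntypes, gj_pairs)
    return(list(synapses = syn, gap_junctions = gj, hv_order = NULL))
  }
  hv_map <- assign_neurons_to_hypervoxels(placement, morphologies,
                                          voxel_size, hv_voxels, origin)
  ord <- order_hypervoxels(hv_map)
  syn_parts <- list(); gj_parts <- list()
  for (key in ord) {
    ijk <- as.integer(strsplit(key, "_")[[1]])
    filt <- function(vx, vy, vz) {
      floor(vx / hv_voxels) == ijk[1] & floor(vy / hv_voxels) == ijk[2] &
        floor(vz / hv_voxels) == ijk[3]
    }
    g <- rast_one(hv_map[[key]], voxel_filter = filt)
    syn_parts[[key]] <- detect_touches(g, ntypes, allowed_pairs)
    if (!is.null(gj_pairs))
      gj_parts[[key]] <- detect_gap_junctions(g, ntypes, gj_pairs)
  }
  syn <- do.call(rbind, syn_parts)
  rownames(syn) <- NULL
  syn <- syn[order(syn$pre, syn$post, syn$vx, syn$vy, syn$vz), , drop = FALSE]
  rownames(syn) <- NULL
  gj <- if (is.null(gj_pairs)) NULL else {
    gjx <- do.call(rbind, gj_parts)
    gjx <- gjx[order(gjx$a, gjx$b, gjx$vx, gjx$vy, gjx$vz), , drop = FALSE]
    rownames(gjx) <- NULL
    gjx
  }
  list(synapses = syn, gap_junctions = gj, hv_order = ord)
}

#' Synapse detection from an axonal probability cloud
#'
#' For morphologies without a reconstructed axon: every dendrite-occupied
#' voxel of an allowed postsynaptic neuron receives a putative synapse from
#' the presynaptic neuron with probability
#' `min(1, density(voxel centre - pre soma) * voxel volume)`.
#'
#' @param pre_placement data.frame with `id`, `type`, `x`, `y`, `z` of
#'   presynaptic (axonless) neurons.
#' @param density function taking an n x 3 matrix of positions relative to
#'   the pre soma (metres) and returning non-negative densities (synapses
#'   per m^3).
#' @param grid a populated [voxel_grid()] holding the postsynaptic dendrites.
#' @param neuron_types,allowed_pairs as in [detect_touches()].
#' @param rng_seed integer seed; draws are made in canonical
#'   (pre, post, voxel) order so results are reproducible.
#' @return data.frame in the same layout as [detect_touches()].
#' @export
axon_density_touch <- function(pre_placement, density, grid,
                               neuron_types = NULL, allowed_pairs = NULL,
                               rng_seed = 1L) {
  dd <- .collapse_occupancy(data.table::copy(grid$dend))
  if (!nrow(dd)) return(.empty_synapses())
  vs <- grid$voxel_size
  out <- list()
  set.seed(rng_seed)
  for (i in order(pre_placement$id)) {
    cand <- dd[dd$neuron != pre_placement$id[i], ]
    if (!is.null(neuron_types) && !is.null(allowed_pairs)) {
      tp <- paste(pre_placement$type[i],
                  unname(neuron_types[as.character(cand$neuron)]), sep = ",")
      cand <- cand[tp %in% paste(allowed_pairs$pre, allowed_pairs$post,
                                 sep = ","), ]
    }
    if (!nrow(cand)) next
    data.table::setorder(cand, neuron, vx, vy, vz)
    ctr <- cbind(grid$origin[1] + (cand$vx + 0.5) * vs,
                 grid$origin[2] + (cand$vy + 0.5) * vs,
                 grid$origin[3] + (cand$vz + 0.5) * vs)
    rel <- sweep(ctr, 2, c(pre_placement$x[i], pre_placement$y[i],
                           pre_placement$z[i]))
    dens <- density(rel)
    if (any(dens < 0)) stop("axonal density evaluated negative")
    p <- pmin(1, dens * vs^3)
    keep <- runif(nrow(cand)) < p
    if (!any(keep)) next
    kept <- cand[keep, ]
    out[[length(out) + 1L]] <- data.frame(
      pre = pre_placement$id[i], post = kept$neuron,
      vx = kept$vx, vy = kept$vy, vz = kept$vz,
      x = ctr[keep, 1], y = ctr[keep, 2], z = ctr[keep, 3],
      section = kept$section, offset = kept$offset,
      dist_to_soma = kept$dist_to_soma,
      type_pair = if (is.null(neuron_types)) NA_character_ else
        paste(pre_placement$type[i],
              unname(neuron_types[as.character(kept$neuron)]), sep = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_synapses())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
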