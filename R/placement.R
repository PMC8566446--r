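## Soma placement inside mesh- or cube-bounded volumes.
##
## Candidates are drawn uniformly from the mesh bounding box expanded by
## d_min; candidates outside the volume that still respect d_min are kept as
## "padding" somas so the accepted density stays flat up to the border, but
## they are not counted towards the requested totals.

#' Volume specification
#'
#' @param name volume label.
#' @param type `"cube"` or `"mesh"`.
#' @param d_min minimum soma-soma distance, metres.
#' @param side cube side, metres (cube type).
#' @param centre cube centre, metres (cube type).
#' @param mesh_file Wavefront OBJ path (mesh type).
#' @param mesh_bin_width voxelization bin for the inside/outside grid, metres.
#' @return a `volume_spec` object.
#' @export
volume_spec <- function(name, type = c("cube", "mesh"), d_min = 15e-6,
                        side = NULL, centre = c(0, 0, 0), mesh_file = NULL,
                        mesh_bin_width = NULL) {
  type <- match.arg(type)
  stopifnot(d_min >= 0)
  if (type == "cube") stopifnot(is.numeric(side), side > 0)
  if (type == "mesh") {
    stopifnot(!is.null(mesh_file))
    stopifnot(is.numeric(mesh_bin_width), mesh_bin_width > 0)
  }
  structure(list(name = name, type = type, d_min = d_min, side = side,
                 centre = centre, mesh_file = mesh_file,
                 mesh_bin_width = mesh_bin_width),
            class = "volume_spec")
}

#' Load a triangulated Wavefront OBJ mesh
#'
#' Reads `v` and `f` records; polygonal faces are fan-triangulated. Face
#' tokens of the form `i/t/n` use the vertex index only.
#'
#' @param path OBJ file path.
#' @return list with `vertices` (n x 3 matrix) and `faces` (m x 3 integer
#'   matrix of vertex row indices).
#' @export
load_obj <- function(path) {
  if (!file.exists(path)) stop("OBJ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(fl) == 0) stop("OBJ format error: no faces in ", path)
  if (length(vl) == 0) stop("OBJ format error: no vertices in ", path)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t)
    as.numeric(t[2:4])))
  if (anyNA(verts)) stop("OBJ format error: bad vertex record")
  faces <- list()
  for (ln in fl) {
    idx <- vapply(strsplit(ln, "\\s+")[[1]][-1], function(tok)
      as.integer(strsplit(tok, "/")[[1]][1]), integer(1))
    if (anyNA(idx) || length(idx) < 3) stop("OBJ format error: bad face record")
    idx <- ifelse(idx < 0, nrow(verts) + idx + 1L, idx)
    for (k in seq_len(length(idx) - 2))  # fan triangulation
      faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

# TRUE if every undirected edge is shared by exactly two faces.
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

# Count ray crossings from each origin along a fixed direction.
# Vectorised over origins, looped over triangles (Moller-Trumbore).
ray_crossings <- function(origins, mesh,
                          dir = c(0.801253, 0.469829, 0.370219)) {
  dir <- dir / sqrt(sum(dir^2))
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(origins)
  cnt <- integer(n)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    e1 <- b - a; e2 <- cc - a
    h <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * h)
    if (abs(det) < 1e-14) next
    s1 <- origins[, 1] - a[1]; s2 <- origins[, 2] - a[2]
    s3 <- origins[, 3] - a[3]
    u <- (s1 * h[1] + s2 * h[2] + s3 * h[3]) / det
    q1 <- s2 * e1[3] - s3 * e1[2]
    q2 <- s3 * e1[1] - s1 * e1[3]
    q3 <- s1 * e1[2] - s2 * e1[1]
    vv <- (dir[1] * q1 + dir[2] * q2 + dir[3] * q3) / det
    tt <- (e2[1] * q1 + e2[2] * q2 + e2[3] * q3) / det
    hit <- u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 1e-12
    cnt <- cnt + hit
  }
  cnt
}

#' Voxelize a closed mesh into an inside/outside/border grid
#'
#' Cells intersecting a triangle (detected by dense barycentric sampling of
#' the surface at `bin_width / 3` spacing) are labelled `border`; remaining
#' cells are classified by ray-casting parity from their centres.
#'
#' @param mesh from [load_obj()].
#' @param bin_width cell size, metres.
#' @param allow_open proceed on a non-watertight mesh using ray-parity
#'   (default `FALSE`: error).
#' @return a `mesh_grid` object: `origin`, `bin`, `dims`, and `label` array
#'   with values `"inside"`, `"outside"`, `"border"`.
#' @export
voxelize_mesh <- function(mesh, bin_width, allow_open = FALSE) {
  stopifnot(bin_width > 0)
  if (!mesh_is_watertight(mesh)) {
    if (!allow_open)
      stop("mesh is not watertight; pass allow_open = TRUE to classify by ",
           "ray-parity majority anyway")
  }
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  origin <- lo - bin_width / 2
  dims <- pmax(1L, as.integer(ceiling((hi - origin) / bin_width)) + 1L)
  label <- array("outside", dim = dims)
  # border: sample each triangle surface densely and mark containing cells
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    a <- v[mesh$faces[i, 1], ]; b <- v[mesh$faces[i, 2], ]
    cc <- v[mesh$faces[i, 3], ]
    lmax <- max(sqrt(sum((b - a)^2)), sqrt(sum((cc - a)^2)),
                sqrt(sum((cc - b)^2)))
    k <- max(2L, ceiling(lmax / (bin_width / 3)))
    s <- seq(0, 1, length.out = k + 1)
    g <- expand.grid(u = s, w = s)
    g <- g[g$u + g$w <= 1 + 1e-12, ]
    pts <- cbind(a[1] + g$u * (b[1] - a[1]) + g$w * (cc[1] - a[1]),
                 a[2] + g$u * (b[2] - a[2]) + g$w * (cc[2] - a[2]),
                 a[3] + g$u * (b[3] - a[3]) + g$w * (cc[3] - a[3]))
    ijk <- floor(sweep(pts, 2, origin) / bin_width) + 1
    ijk[, 1] <- pmin(pmax(ijk[, 1], 1), dims[1])
    ijk[, 2] <- pmin(pmax(ijk[, 2], 1), dims[2])
    ijk[, 3] <- pmin(pmax(ijk[, 3], 1), dims[3])
    label[unique(ijk[, 1] + dims[1] * (ijk[, 2] - 1) +
                   dims[1] * dims[2] * (ijk[, 3] - 1))] <- "border"
  }
  open_cells <- which(label == "outside")
  if (length(open_cells)) {
    idx <- arrayInd(open_cells, dims)
    ctr <- sweep((idx - 0.5) * bin_width, 2, origin, "+")
    par <- ray_crossings(ctr, mesh) %% 2L == 1L
    label[open_cells[par]] <- "inside"
  }
  structure(list(origin = origin, bin = bin_width, dims = dims,
                 label = label, mesh = mesh),
            class = "mesh_grid")
}

#' Volume estimate from a voxelized mesh
#'
#' Inside cells count fully, border cells at half weight (an unbiased
#' estimator that converges to the mesh volume as the bin shrinks).
#'
#' @param grid a `mesh_grid` from [voxelize_mesh()].
#' @return volume in cubic metres.
#' @export
grid_volume <- function(grid) {
  (sum(grid$label == "inside") + 0.5 * sum(grid$label == "border")) *
    grid$bin^3
}

#' Inside test against a voxelized mesh
#'
#' Grid lookup; points in border cells (or outside the grid's bounding box)
#' are resolved by ray-casting parity against the mesh.
#'
#' @param grid a `mesh_grid` from [voxelize_mesh()].
#' @param points n x 3 matrix or length-3 vector, metres.
#' @return logical vector.
#' @export
is_inside <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(all(is.finite(points)))
  ijk <- floor(sweep(points, 2, grid$origin) / grid$bin) + 1
  inb <- ijk[, 1] >= 1 & ijk[, 1] <= grid$dims[1] &
         ijk[, 2] >= 1 & ijk[, 2] <= grid$dims[2] &
         ijk[, 3] >= 1 & ijk[, 3] <= grid$dims[3]
  res <- logical(nrow(points))
  if (any(inb)) {
    lin <- ijk[inb, 1] + grid$dims[1] * (ijk[inb, 2] - 1) +
      grid$dims[1] * grid$dims[2] * (ijk[inb, 3] - 1)
    lab <- grid$label[lin]
    res[inb][lab == "inside"] <- TRUE
    amb <- which(inb)[lab == "border"]
    if (length(amb))
      res[amb] <- ray_crossings(points[amb, , drop = FALSE],
                                grid$mesh) %% 2L == 1L
  }
  res
}

#' Sample a rotation matrix
#'
#' `"none"` gives the identity; `"random"` draws uniformly from SO(3)
#' (uniform unit quaternions, Shoemake's method).
#'
#' @param mode `"none"` or `"random"`.
#' @param rng_seed optional seed; if `NULL` the current RNG stream is used.
#' @return a 3x3 rotation matrix.
#' @export
sample_rotation <- function(mode = c("none", "random"), rng_seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(diag(3))
  draw <- function() {
    u <- runif(3)
    q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]),
           sqrt(u[1]) * cos(2 * pi * u[3]))
    w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}

# spatial hash for exact d_min neighbour queries; cell size = d_min
.hash_key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = "_")

#' Place neuron somas in a volume
#'
#' Rejection sampling: uniform candidates in the bounding box expanded by
#' `d_min`; a candidate within `d_min` of any previous soma (accepted or
#' padding) is rejected; candidates outside the volume are kept as padding
#' (flat density up to the border) but not counted.
#'
#' @param vol a [volume_spec()] (cube volumes use an analytic inside test).
#' @param counts named integer vector: somas requested per prototype.
#' @param rng_seed integer seed; placement is deterministic given the seed.
#' @param rotation_mode passed to [sample_rotation()] per neuron.
#' @param padding keep out-of-volume candidates as padding somas
#'   (default `TRUE`). `FALSE` reproduces the border-density artifact and
#'   exists for validation only.
#' @param grid optional precomputed `mesh_grid` for mesh volumes.
#' @param max_reject abort after this many consecutive rejections.
#' @param types optional named vector mapping prototype -> neuron type
#'   (defaults to the prototype names).
#' @return a `placement_result`: data.frame `neurons` (0-based `id`,
#'   `prototype`, `type`, `x`, `y`, `z` metres, `volume`, `unit`), list
#'   `rotations`, matrix `padding` of padding soma positions.
#' @export
place_neurons <- function(vol, counts, rng_seed,
                          rotation_mode = c("random", "none"),
                          padding = TRUE, grid = NULL, max_reject = 1e6,
                          types = NULL) {
  rotation_mode <- match.arg(rotation_mode)
  stopifnot(inherits(vol, "volume_spec"), all(counts >= 0))
  n_total <- sum(counts)
  if (vol$type == "cube") {
    lo <- vol$centre - vol$side / 2
    hi <- vol$centre + vol$side / 2
    vol_m3 <- vol$side^3
    inside_fun <- function(p) all(p >= lo & p <= hi)
  } else {
    if (is.null(grid)) {
      mesh <- load_obj(vol$mesh_file)
      grid <- voxelize_mesh(mesh, vol$mesh_bin_width)
    }
    lo <- apply(grid$mesh$vertices, 2, min)
    hi <- apply(grid$mesh$vertices, 2, max)
    vol_m3 <- sum(grid$label == "inside") * grid$bin^3 +
      0.5 * sum(grid$label == "border") * grid$bin^3
    inside_fun <- function(p) is_inside(grid, p)
  }
  dmin <- vol$d_min
  if (n_total > 0 && dmin > 0 &&
      n_total * (4 * pi / 3) * (dmin / 2)^3 >= 0.3 * vol_m3)
    stop("infeasible packing: ", n_total, " somas at d_min = ", dmin,
         " exceed 30% of the volume")
  slo <- lo - dmin
  shi <- hi + dmin
  cell <- if (dmin > 0) dmin else (max(shi - slo) / 64)

  pts <- matrix(NA_real_, nrow = max(2 * n_total, 64), ncol = 3)
  accepted <- logical(nrow(pts))
  npts <- 0L
  hash <- new.env(parent = emptyenv())
  set.seed(rng_seed)
  n_acc <- 0L
  rejects <- 0L
  while (n_acc < n_total) {
    p <- slo + runif(3) * (shi - slo)
    ok <- TRUE
    if (dmin > 0 && npts > 0) {
      base <- floor(p / cell)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        key <- paste(base[1] + dx, base[2] + dy, base[3] + dz, sep = "_")
        idx <- hash[[key]]
        if (!is.null(idx)) {
          d2 <- (pts[idx, 1] - p[1])^2 + (pts[idx, 2] - p[2])^2 +
            (pts[idx, 3] - p[3])^2
          if (any(d2 < dmin^2)) { ok <- FALSE; break }
        }
      }
    }
    if (!ok) {
      rejects <- rejects + 1L
      if (rejects > max_reject)
        stop("placement failed: ", max_reject, " consecutive rejections")
      next
    }
    rejects <- 0L
    ins <- inside_fun(p)
    if (!ins && !padding) next  # control mode: discard, do not remember
    npts <- npts + 1L
    if (npts > nrow(pts)) {
      pts <- rbind(pts, matrix(NA_real_, nrow = nrow(pts), ncol = 3))
      accepted <- c(accepted, logical(length(accepted)))
    }
    pts[npts, ] <- p
    accepted[npts] <- ins
    if (ins) n_acc <- n_acc + 1L
    if (dmin > 0) {
      key <- .hash_key(matrix(floor(p / cell), ncol = 3))
      hash[[key]] <- c(hash[[key]], npts)
    }
  }
  pts <- pts[seq_len(npts), , drop = FALSE]
  accepted <- accepted[seq_len(npts)]
  acc <- pts[accepted, , drop = FALSE]
  # prototype multiset instantiated in (seeded) random order
  protos <- sample(rep(names(counts), times = counts))
  rots <- lapply(seq_len(n_total), function(i) sample_rotation(rotation_mode))
  if (is.null(types)) types <- stats::setNames(names(counts), names(counts))
  neurons <- data.frame(
    id = seq_len(n_total) - 1L, prototype = protos,
    type = unname(types[protos]),
    x = acc[, 1], y = acc[, 2], z = acc[, 3],
    volume = vol$name, unit = 0L, stringsAsFactors = FALSE)
  structure(list(neurons = neurons, rotations = rots,
                 padding = pts[!accepted, , drop = FALSE],
                 d_min = dmin, volume = vol$name),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("<placement: %d neurons in '%s', %d padding somas, d_min %.1f um>\n",
              nrow(x$neurons), x$volume, nrow(x$padding),
              x$d_min / .unit_um))
  invisible(x)
}

#' Population-unit specification
#'
#' @param unit_id positive integer unit label (0 is reserved for
#'   "no unit").
#' @param volume volume name the unit lives in.
#' @param neuron_types character vector of member types.
#' @param fraction numeric in `[0, 1]`, recycled over `neuron_types`:
#'   probability that a neuron of that type joins this unit.
#' @return a `population_unit_spec`.
#' @export
population_unit_spec <- function(unit_id, volume, neuron_types, fraction) {
  stopifnot(unit_id >= 1, all(fraction >= 0), all(fraction <= 1))
  fraction <- rep_len(fraction, length(neuron_types))
  structure(list(unit_id = as.integer(unit_id), volume = volume,
                 neuron_types = neuron_types, fraction = fraction),
            class = "population_unit_spec")
}

#' Assign neurons to population units
#'
#' Per neuron type, each neuron joins unit `u` with that unit's fraction for
#' the type, independently; leftover probability keeps the neuron in unit 0.
#'
#' @param placement a `placement_result`.
#' @param units list of [population_unit_spec()].
#' @param rng_seed integer seed.
#' @return the placement with the `unit` column filled in.
#' @export
assign_population_units <- function(placement, units, rng_seed) {
  if (length(units) == 0) return(placement)
  nn <- placement$neurons
  types <- unique(unlist(lapply(units, `[[`, "neuron_types")))
  for (tp in types) {
    fr <- vapply(units, function(u) {
      i <- match(tp, u$neuron_types)
      if (is.na(i)) 0 else u$fraction[i]
    }, numeric(1))
    if (sum(fr) > 1 + 1e-12)
      stop("population-unit fractions for type '", tp, "' sum to ", sum(fr),
           " > 1")
  }
  set.seed(rng_seed)
  for (tp in types) {
    rows <- which(nn$type == tp & nn$volume %in%
                    vapply(units, `[[`, "", "volume"))
    if (!length(rows)) next
    ids <- vapply(units, `[[`, integer(1), "unit_id")
    fr <- vapply(units, function(u) {
      i <- match(tp, u$neuron_types)
      if (is.na(i)) 0 else u$fraction[i]
    }, numeric(1))
    edges <- cumsum(fr)
    u <- runif(length(rows))
    pick <- findInterval(u, c(0, edges), left.open = TRUE)
    assigned <- ifelse(pick >= 1 & pick <= length(ids) & u <= edges[length(edges)],
                       ids[pmin(pick, length(ids))], 0L)
    nn$unit[rows] <- as.integer(assigned)
  }
  placement$neurons <- nn
  placement
}
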