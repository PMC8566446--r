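# Shared test fixtures, all generated in code.

# the twenty printed ladder distances (micrometres)
ladder_distances_um <- c(56, 65, 86, 95, 116, 125, 146, 155, 176, 185,
                         206, 215, 236, 245, 266, 275, 296, 305, 326, 335)

# axis-aligned unit-cube OBJ (12 triangles), optionally scaled/shifted
write_cube_obj <- function(path, lo = c(0, 0, 0), side = 1) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  v <- sweep(v * side, 2, lo, "+")
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  writeLines(c(paste("v", v[, 1], v[, 2], v[, 3]),
               paste("f", f[, 1], f[, 2], f[, 3])), path)
  path
}

# watertight UV-sphere triangle mesh built directly (no file)
make_sphere_mesh <- function(r = 1, nth = 24, nph = 12) {
  th <- seq(0, 2 * pi, length.out = nth + 1)[-1]
  ph <- seq(0, pi, length.out = nph + 1)
  verts <- rbind(c(0, 0, r))
  for (p in ph[-c(1, length(ph))]) for (t in th)
    verts <- rbind(verts, r * c(sin(p) * cos(t), sin(p) * sin(t), cos(p)))
  verts <- rbind(verts, c(0, 0, -r))
  idx <- function(i, j) 1 + (i - 1) * nth + ((j - 1) %% nth) + 1
  faces <- list()
  for (j in 1:nth) faces[[length(faces) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
  for (i in 1:(nph - 2)) for (j in 1:nth) {
    faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  last <- nrow(verts)
  for (j in 1:nth)
    faces[[length(faces) + 1]] <- c(last, idx(nph - 1, j + 1), idx(nph - 1, j))
  list(vertices = verts, faces = do.call(rbind, faces))
}

# exact length of a segment clipped to a voxel box (slab method); used to
# classify corner-sliver voxels in the rasterization oracle test
segment_in_voxel_length <- function(p0, p1, voxel, voxel_size) {
  lo <- voxel * voxel_size
  hi <- lo + voxel_size
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-18) {
      if (p0[ax] < lo[ax] || p0[ax] > hi[ax]) return(0)
    } else {
      ta <- (lo[ax] - p0[ax]) / d[ax]
      tb <- (hi[ax] - p0[ax]) / d[ax]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(0)
  (t1 - t0) * sqrt(sum(d^2))
}

expect_valid_morphology <- function(m) {
  expect_silent(validate_morphology(m))
}
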