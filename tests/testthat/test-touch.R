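# touch_detection: rasterization, voxel co-occupancy, hypervoxels

vox <- 3e-6

test_that("segment rasterization matches simple counts and handles ties", {
  g <- voxel_grid(vox)
  # axis-aligned 9 um segment starting at a voxel centre: 4 voxels
  g <- rasterize_segment(g, c(1.5, 1.5, 1.5) * 1e-6,
                         c(10.5, 1.5, 1.5) * 1e-6, 1L, "axon")
  expect_equal(nrow(g$axon), 4L)
  expect_equal(g$axon$vx, 0:3)
  # zero-length segment: one voxel
  g2 <- rasterize_segment(voxel_grid(vox), c(4e-6, 4e-6, 4e-6),
                          c(4e-6, 4e-6, 4e-6), 1L, "dend")
  expect_equal(nrow(g2$dend), 1L)
  expect_equal(unlist(g2$dend[1, c("vx", "vy", "vz")]), rep(1L, 3),
               ignore_attr = TRUE)
})

test_that("rasterization equals fine stepping up to corner slivers", {
  set.seed(9)
  for (i in 1:100) {
    p0 <- runif(3, -2e-5, 2e-5)
    p1 <- runif(3, -2e-5, 2e-5)
    sv <- touchnet:::segment_voxels(p0, p1, vox)
    n_step <- ceiling(sqrt(sum((p1 - p0)^2)) / (vox / 50)) + 2
    tt <- seq(0, 1, length.out = n_step)
    pts <- outer(tt, p1 - p0) + rep(p0, each = length(tt))
    oracle <- unique(floor(pts / vox))
    k_sc <- paste(sv$vx, sv$vy, sv$vz)
    k_or <- paste(oracle[, 1], oracle[, 2], oracle[, 3])
    # every sampled voxel is marked
    expect_true(all(k_or %in% k_sc))
    # any extra marked voxel is a genuine sliver shorter than the step
    extra <- setdiff(k_sc, k_or)
    for (e in extra) {
      vxl <- as.numeric(strsplit(e, " ")[[1]])
      len <- segment_in_voxel_length(p0, p1, vxl, vox)
      expect_gt(len, 0)
      expect_lt(len, vox / 50 * sqrt(3) * 1.01)
    }
  }
})

test_that("soma rasterization marks voxels by centre-in-sphere", {
  g <- rasterize_soma(voxel_grid(vox), c(1.5, 1.5, 1.5) * 1e-6, 1e-6, 1L)
  expect_equal(nrow(g$dend), 1L)
  # radius 5.9 um (off the voxel-centre tie surface): brute-force centre test
  ctr <- c(4.5, 1.5, -7.5) * 1e-6
  r <- 5.9e-6
  g2 <- rasterize_soma(voxel_grid(vox), ctr, r, 2L)
  gg <- expand.grid(vx = -10:10, vy = -10:10, vz = -10:10)
  cc <- (as.matrix(gg) + 0.5) * vox
  brute <- sum((cc[, 1] - ctr[1])^2 + (cc[, 2] - ctr[2])^2 +
                 (cc[, 3] - ctr[3])^2 <= r^2)
  expect_equal(nrow(g2$dend), brute)
  # tiny off-centre soma: its containing voxel
  g3 <- rasterize_soma(voxel_grid(vox), c(2.9, 0.2, 0.2) * 1e-6, 1e-7, 3L)
  expect_equal(unlist(g3$dend[1, c("vx", "vy", "vz")]), c(0L, 0L, 0L),
               ignore_attr = TRUE)
})

test_that("detect_touches pairs axon with dendrite under type rules", {
  g <- voxel_grid(vox)
  g <- rasterize_segment(g, c(0, 1.5, 1.5) * 1e-6, c(20, 1.5, 1.5) * 1e-6,
                         0L, "dend")
  g <- rasterize_segment(g, c(4.5, -6, 1.5) * 1e-6, c(4.5, 9, 1.5) * 1e-6,
                         1L, "axon")
  types <- c("0" = "A", "1" = "B")
  syn <- detect_touches(g, types, data.frame(pre = "B", post = "A"))
  expect_equal(nrow(syn), 1L)
  expect_equal(syn$pre, 1L)
  expect_equal(syn$post, 0L)
  expect_equal(syn$x, 4.5e-6)  # voxel centre
  # disallowed pair: nothing
  expect_equal(nrow(detect_touches(g, types,
                                   data.frame(pre = "A", post = "B"))), 0L)
  # parallel neurites 10 um apart never co-occupy a voxel
  g2 <- voxel_grid(vox)
  g2 <- rasterize_segment(g2, c(0, 1.5, 1.5) * 1e-6, c(30, 1.5, 1.5) * 1e-6,
                          0L, "dend")
  g2 <- rasterize_segment(g2, c(0, 11.5, 1.5) * 1e-6,
                          c(30, 11.5, 1.5) * 1e-6, 1L, "axon")
  expect_equal(nrow(detect_touches(g2, types,
                                   data.frame(pre = "B", post = "A"))), 0L)
  # self-touches excluded
  g3 <- voxel_grid(vox)
  g3 <- rasterize_segment(g3, c(0, 1.5, 1.5) * 1e-6, c(9, 1.5, 1.5) * 1e-6,
                          0L, "dend")
  g3 <- rasterize_segment(g3, c(0, 1.5, 1.5) * 1e-6, c(9, 1.5, 1.5) * 1e-6,
                          0L, "axon")
  expect_equal(nrow(detect_touches(g3, c("0" = "A"), NULL)), 0L)
})

test_that("gap junctions are unordered, deduplicated dendrite contacts", {
  g <- voxel_grid(vox)
  g <- rasterize_segment(g, c(0, 1.5, 1.5) * 1e-6, c(20, 1.5, 1.5) * 1e-6,
                         3L, "dend")
  g <- rasterize_segment(g, c(7.5, -6, 1.5) * 1e-6, c(7.5, 9, 1.5) * 1e-6,
                         1L, "dend")
  types <- c("1" = "FS", "3" = "FS")
  gj <- detect_gap_junctions(g, types, data.frame(pre = "FS", post = "FS"))
  expect_equal(nrow(gj), 1L)
  expect_lt(gj$a, gj$b)
  # brute force: co-occupied voxel count over distinct neuron pairs
  dd <- merge(g$dend, g$dend, by = c("vx", "vy", "vz"))
  brute <- sum(dd$neuron.x < dd$neuron.y)
  expect_equal(nrow(gj), brute)
})

test_that("grid fixture detection: exact counts, translation invariance", {
  fx <- make_grid_fixture(10, 4)
  det <- detect_network(fx$placement, fx$morphologies, fx$allowed_pairs)
  expect_equal(nrow(det$synapses), 40L)
  expect_true(all(table(paste(det$synapses$pre, det$synapses$post)) == 4L))
  expect_setequal(unique(det$synapses$pre), fx$expected$pre)
  # translating the whole scene by whole voxels leaves counts unchanged
  fx$placement$neurons$x <- fx$placement$neurons$x + 5 * vox
  fx$placement$neurons$z <- fx$placement$neurons$z - 3 * vox
  det2 <- detect_network(fx$placement, fx$morphologies, fx$allowed_pairs)
  expect_equal(nrow(det2$synapses), 40L)
  expect_true(all(table(paste(det2$synapses$pre, det2$synapses$post)) == 4L))
})

test_that("hypervoxel bookkeeping: membership, ordering, independence", {
  fx <- make_grid_fixture(6, 4)
  hv <- assign_neurons_to_hypervoxels(fx$placement, fx$morphologies,
                                      hv_voxels = 16L)
  # pair slabs are 20 voxels apart, so every neuron spans >= 1 hypervoxel
  # and neurons from different slabs never share one
  expect_true(all(lengths(hv) >= 1))
  ord <- order_hypervoxels(hv)
  cnt <- vapply(hv, length, integer(1))[ord]
  expect_true(all(diff(cnt) <= 0))
  expect_identical(order_hypervoxels(list()), character(0))
  # equal counts tie-break lexicographically by lattice coordinates
  fake <- list("2_0_0" = 1L, "0_0_0" = 1L, "1_0_0" = 2:3)
  expect_identical(order_hypervoxels(fake), c("1_0_0", "0_0_0", "2_0_0"))
  # decomposition yields the identical synapse multiset
  one <- detect_network(fx$placement, fx$morphologies, fx$allowed_pairs)
  dec <- detect_network(fx$placement, fx$morphologies, fx$allowed_pairs,
                        by_hypervoxel = TRUE, hv_voxels = 16L)
  expect_equal(one$synapses, dec$synapses, ignore_attr = TRUE)
  expect_gt(length(dec$hv_order), 1L)
})

test_that("relabelling neurons permutes but preserves the synapse multiset", {
  fx <- make_grid_fixture(5, 3)
  base <- detect_network(fx$placement, fx$morphologies, fx$allowed_pairs)
  perm <- rev(seq_len(nrow(fx$placement$neurons))) - 1L
  fx$placement$neurons$id <- perm
  rel <- detect_network(fx$placement, fx$morphologies, fx$allowed_pairs)
  expect_equal(nrow(rel$synapses), nrow(base$synapses))
  remap <- function(ids) perm[ids + 1L]
  expect_setequal(paste(remap(base$synapses$pre), remap(base$synapses$post),
                        base$synapses$vx, base$synapses$vy, base$synapses$vz),
                  paste(rel$synapses$pre, rel$synapses$post,
                        rel$synapses$vx, rel$synapses$vy, rel$synapses$vz))
})

test_that("axonal density clouds draw synapses where the density lives", {
  fx <- make_grid_fixture(1, 4)
  nn <- fx$placement$neurons
  g <- voxel_grid(vox)
  post_row <- which(nn$prototype == "bas_post")
  g <- rasterize_morphology(g, fx$morphologies$bas_post, nn$id[post_row],
                            c(nn$x[post_row], nn$y[post_row], nn$z[post_row]))
  pre <- data.frame(id = 99L, type = "bas", x = 0, y = 0, z = 0)
  types <- c("0" = "bas", "99" = "bas")
  ap <- data.frame(pre = "bas", post = "bas")
  # zero density: nothing
  syn0 <- axon_density_touch(pre, function(p) rep(0, nrow(p)), g, types, ap, 1)
  expect_equal(nrow(syn0), 0L)
  # saturating density: every dendrite-occupied voxel of the post neuron
  dd <- touchnet:::.collapse_occupancy(data.table::copy(g$dend))
  satur <- axon_density_touch(pre, function(p) rep(1e30, nrow(p)), g, types,
                              ap, 1)
  expect_equal(nrow(satur), nrow(dd))
  # uniform density: Binomial(V, d * vox^3) within 3 sigma over repeats
  d_per_m3 <- 0.5 / vox^3
  counts <- vapply(1:40, function(s)
    nrow(axon_density_touch(pre, function(p) rep(d_per_m3, nrow(p)), g,
                            types, ap, s)), numeric(1))
  expV <- nrow(dd) * 0.5
  expect_lt(abs(mean(counts) - expV),
            3 * sqrt(nrow(dd) * 0.25 / 40))
  expect_error(
    axon_density_touch(pre, function(p) rep(-1, nrow(p)), g, types, ap, 1),
    "negative")
})
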