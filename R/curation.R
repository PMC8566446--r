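## Repair and augmentation of SWC reconstructions: z-jump correction
## (align / split / tilt / join), grafting of cut neurites, shrinkage
## correction, unravelling, and length-preserving random variability
## (jitter / twist / rotate) plus random 3D scaling.

# ---- structural helpers ----------------------------------------------------

# number of children per row
.child_counts <- function(m) {
  prow <- match(m$nodes$parent, m$nodes$id)
  tabulate(prow[!is.na(prow)], nbins = nrow(m$nodes))
}

# centrifugal (branch) order per row: number of branch points (>= 2
# children, excluding the soma root) on the path from the root, exclusive
# of the node itself.
centrifugal_order <- function(m) {
  n <- m$nodes
  prow <- match(n$parent, n$id)
  nch <- .child_counts(m)
  isbranch <- nch >= 2 & n$type != SWC_SOMA
  ord <- integer(nrow(n))
  for (i in seq_len(nrow(n))) {
    if (is.na(prow[i])) next
    ord[i] <- ord[prow[i]] + as.integer(isbranch[prow[i]])
  }
  ord
}

# decompose into unbranched sections; returns list of integer row vectors,
# each starting at a child of a branch point (or of the root) and running to
# the next branch point or leaf, in root-outward order.
morph_sections <- function(m, types = NULL) {
  n <- m$nodes
  prow <- match(n$parent, n$id)
  nch <- .child_counts(m)
  kids <- morph_children(m)
  # a section starts at every child of the root, of a branch point, of the
  # soma, or at a compartment-type boundary
  starts <- which(!is.na(prow) &
                    (is.na(prow[prow]) | nch[prow] >= 2 |
                       n$type[prow] == SWC_SOMA | n$type[prow] != n$type))
  secs <- list()
  for (s in starts) {
    run <- s
    cur <- s
    while (nch[cur] == 1) {
      nxt <- kids[[cur]]
      if (n$type[nxt] != n$type[cur]) break
      run <- c(run, nxt)
      cur <- nxt
    }
    secs[[length(secs) + 1L]] <- run
  }
  if (!is.null(types))
    secs <- Filter(function(r) n$type[r[1]] %in% types, secs)
  secs
}

# rebuild ids as 1..n from a node table whose ROWS are in parent-before-
# child order, with `parent` holding ROW indices (NA for root).
.renumber_rows <- function(rows_df, parent_rows) {
  rows_df$id <- seq_len(nrow(rows_df))
  rows_df$parent <- ifelse(is.na(parent_rows), -1L, parent_rows)
  rows_df
}

# ---- z-jumps ---------------------------------------------------------------

#' Detect z-jump reconstruction artefacts
#'
#' A z-jump is a parent-to-child step whose vertical offset dominates:
#' `|dz| > dz_threshold` and lateral step `sqrt(dx^2 + dy^2) < |dz|`.
#'
#' @param m a [morphology].
#' @param dz_threshold detection threshold, metres (> 0; 3 um is typical).
#' @return data.frame with `node_id` (the child at the discontinuity) and
#'   `dz` (signed offset, metres); zero rows if none.
#' @export
detect_zjumps <- function(m, dz_threshold = 3e-6) {
  stopifnot(dz_threshold > 0)
  n <- m$nodes
  prow <- match(n$parent, n$id)
  ok <- !is.na(prow) & n$type != SWC_SOMA
  dz <- n$z - n$z[prow]
  lat <- sqrt((n$x - n$x[prow])^2 + (n$y - n$y[prow])^2)
  hit <- ok & abs(dz) > dz_threshold & lat < abs(dz)
  data.frame(node_id = n$id[which(hit)], dz = dz[which(hit)])
}

#' Repair one z-jump
#'
#' Methods:
#' * `align`: subtract `dz` from the whole downstream subtree (rigid shift).
#' * `split`: absorb `-dz` linearly in path length over the remainder of the
#'   jump node's unbranched section (full correction at the jump node,
#'   tapering to zero at the section end).
#' * `tilt`: rigid rotation of the subtree about the jump's parent so the
#'   jump node lands at the parent's z level (an isometry).
#' * `join`: keep the subtree in place and subdivide only the jump segment
#'   into steps small enough that no step exceeds `dz_threshold` (node ids
#'   are renumbered; the repaired node's new id is in attribute
#'   `repaired_node`).
#'
#' @param m a [morphology].
#' @param jump one row of [detect_zjumps()] output (or a list with
#'   `node_id`, `dz`).
#' @param method `"align"`, `"split"`, `"tilt"` or `"join"`.
#' @param dz_threshold threshold used for the `join` subdivision, metres.
#' @return the repaired [morphology]; no z-jump remains at the repaired node
#'   at the same threshold.
#' @export
repair_zjump <- function(m, jump, method = c("align", "split", "tilt", "join"),
                         dz_threshold = 3e-6) {
  method <- match.arg(method)
  node_id <- jump$node_id[1]
  dz <- jump$dz[1]
  n <- m$nodes
  row <- match(node_id, n$id)
  if (is.na(row)) stop("jump node ", node_id, " not in morphology")
  prow <- match(n$parent, n$id)

  if (method == "align") {
    rows <- subtree_rows(m, node_id)
    m$nodes$z[rows] <- m$nodes$z[rows] - dz
    attr(m, "repaired_node") <- node_id
    return(m)
  }
  if (method == "split") {
    kids <- morph_children(m)
    nch <- .child_counts(m)
    chain <- row
    cur <- row
    while (nch[cur] == 1 && n$type[kids[[cur]]] == n$type[cur]) {
      cur <- kids[[cur]]
      chain <- c(chain, cur)
    }
    if (length(chain) == 1) {
      m$nodes$z[subtree_rows(m, node_id)] <-
        m$nodes$z[subtree_rows(m, node_id)] - dz
    } else {
      seg <- segment_lengths(m)
      L <- cumsum(c(0, seg[chain[-1]]))
      Ltot <- L[length(L)]
      w <- if (Ltot > 0) 1 - L / Ltot else seq(1, 0, length.out = length(chain))
      m$nodes$z[chain] <- m$nodes$z[chain] - dz * w
    }
    attr(m, "repaired_node") <- node_id
    return(m)
  }
  if (method == "tilt") {
    piv_row <- prow[row]
    piv <- c(n$x[piv_row], n$y[piv_row], n$z[piv_row])
    v <- c(n$x[row], n$y[row], n$z[row]) - piv
    h <- c(v[1], v[2], 0)
    if (sqrt(sum(h^2)) < 1e-15) h <- c(1, 0, 0)  # purely vertical jump
    R <- rotation_between(v, h)
    rows <- subtree_rows(m, node_id)
    xyz <- t(R %*% (t(as.matrix(m$nodes[rows, c("x", "y", "z")])) - piv)) +
      rep(piv, each = length(rows))
    m$nodes$x[rows] <- xyz[, 1]
    m$nodes$y[rows] <- xyz[, 2]
    m$nodes$z[rows] <- xyz[, 3]
    attr(m, "repaired_node") <- node_id
    return(m)
  }
  # join: subdivide the jump segment; renumber ids afterwards
  steps <- max(2L, ceiling(abs(dz) / (0.9 * dz_threshold)))
  p_row <- prow[row]
  p <- c(n$x[p_row], n$y[p_row], n$z[p_row])
  q <- c(n$x[row], n$y[row], n$z[row])
  tt <- seq_len(steps - 1) / steps
  mid <- data.frame(
    id = NA_integer_, type = n$type[row],
    x = p[1] + tt * (q[1] - p[1]), y = p[2] + tt * (q[2] - p[2]),
    z = p[3] + tt * (q[3] - p[3]),
    radius = n$radius[p_row] + tt * (n$radius[row] - n$radius[p_row]),
    parent = NA_integer_)
  # rebuild row list with the new nodes spliced in just before `row`
  k <- steps - 1L
  all_rows <- rbind(n[seq_len(row - 1), ], mid, n[row:nrow(n), ])
  old_to_new <- c(seq_len(row - 1), seq(row + k, nrow(n) + k))
  parent_rows <- rep(NA_integer_, nrow(n) + k)
  for (r in seq_len(nrow(n)))  # parents precede children, so indices map 1:1
    if (!is.na(prow[r])) parent_rows[old_to_new[r]] <- old_to_new[prow[r]]
  parent_rows[row] <- p_row                      # first inserted node
  if (k > 1) parent_rows[(row + 1):(row + k - 1)] <- row:(row + k - 2)
  parent_rows[row + k] <- row + k - 1L           # jump node follows the chain
  out <- .renumber_rows(all_rows, parent_rows)
  m2 <- morphology(out, name = m$name)
  attr(m2, "repaired_node") <- old_to_new[row]
  m2
}

# ---- cut neurites ----------------------------------------------------------

#' Detect neurite cut points at a slice face
#'
#' Flags leaves lying within `z_tolerance` of the extreme z planes of the
#' reconstruction. A face only qualifies when at least `min_leaves` leaves
#' are coincident with it: a slice cut clips several neurites at one plane,
#' whereas a single extreme leaf is just the neuron's natural extent.
#'
#' @param m a [morphology] with at least one leaf.
#' @param z_tolerance distance to the face, metres (>= 0).
#' @param min_leaves minimum coincident leaves for a face (default 2).
#' @return data.frame with `node_id` and `face` (`"+z"` / `"-z"`).
#' @export
detect_cut_points <- function(m, z_tolerance = 1e-6, min_leaves = 2L) {
  n <- m$nodes
  nch <- .child_counts(m)
  leaves <- which(nch == 0 & n$type != SWC_SOMA)
  if (!length(leaves)) stop("morphology has no leaves")
  zmax <- max(n$z); zmin <- min(n$z)
  top <- leaves[n$z[leaves] >= zmax - z_tolerance]
  bot <- leaves[n$z[leaves] <= zmin + z_tolerance]
  res <- rbind(
    if (length(top) >= min_leaves)
      data.frame(node_id = n$id[top], face = "+z") else NULL,
    if (length(bot) >= min_leaves)
      data.frame(node_id = n$id[bot], face = "-z") else NULL)
  if (is.null(res)) data.frame(node_id = integer(), face = character())
  else res
}

#' Graft donor branches onto cut neurites
#'
#' Each cut leaf is extended with a copy of a randomly chosen intact donor
#' sub-branch of the same centrifugal order, rotated to continue the cut
#' branch direction and mirrored across the cut face (so the graft grows
#' back into the slice). Grafted nodes get fresh ids.
#'
#' @param m a [morphology].
#' @param cuts data.frame from [detect_cut_points()].
#' @param rng_seed integer seed (donor choice).
#' @return the repaired [morphology].
#' @export
repair_cut <- function(m, cuts, rng_seed = 1L) {
  if (is.null(cuts) || nrow(cuts) == 0) return(m)
  set.seed(rng_seed)
  n <- m$nodes
  ords <- centrifugal_order(m)
  secs <- morph_sections(m, types = SWC_DEND)
  cut_rows <- match(cuts$node_id, n$id)
  # a donor section is intact if no cut leaf lies in its downstream subtree
  sec_ok <- vapply(secs, function(r) {
    sub <- subtree_rows(m, n$id[r[1]])
    !any(cut_rows %in% sub)
  }, logical(1))
  for (ci in seq_len(nrow(cuts))) {
    n <- m$nodes  # refresh (ids are append-only, rows stable)
    prow <- match(n$parent, n$id)
    leaf_row <- match(cuts$node_id[ci], n$id)
    o <- ords[cut_rows[ci]]
    donors <- which(sec_ok & vapply(secs, function(r)
      centrifugal_order(m)[r[1]], integer(1)) == o)
    donors <- donors[vapply(secs[donors], function(r)
      r[1] != leaf_row, logical(1))]
    if (!length(donors))
      stop("no intact donor branch of centrifugal order ", o,
           " for cut node ", cuts$node_id[ci])
    don <- secs[[donors[sample.int(length(donors), 1)]]]
    don_start <- don[1]
    sub <- subtree_rows(m, n$id[don_start])
    att_row <- prow[don_start]
    att <- c(n$x[att_row], n$y[att_row], n$z[att_row])
    u <- c(n$x[don_start], n$y[don_start], n$z[don_start]) - att
    leaf <- c(n$x[leaf_row], n$y[leaf_row], n$z[leaf_row])
    cdir <- leaf - c(n$x[prow[leaf_row]], n$y[prow[leaf_row]],
                     n$z[prow[leaf_row]])
    if (sqrt(sum(cdir^2)) < 1e-15) cdir <- c(0, 0, 1)
    cdir[3] <- -cdir[3]  # mirror across the cut face
    R <- rotation_between(u, cdir)
    rel <- t(R %*% (t(as.matrix(n[sub, c("x", "y", "z")])) - att))
    newid0 <- max(n$id)
    graft <- data.frame(
      id = newid0 + seq_along(sub), type = n$type[sub],
      x = leaf[1] + rel[, 1], y = leaf[2] + rel[, 2], z = leaf[3] + rel[, 3],
      radius = n$radius[sub], parent = NA_integer_)
    # donor rows are id-sorted, so parents precede children within `sub`
    graft$parent <- ifelse(match(prow[sub], sub, nomatch = 0L) > 0,
                           newid0 + match(prow[sub], sub),
                           n$id[leaf_row])
    m$nodes <- rbind(n, graft)
  }
  validate_morphology(m)
  m
}

# ---- shrinkage and unravelling --------------------------------------------

#' Shrinkage correction
#'
#' Scales the entire reconstruction in the (x, y) plane and expands it along
#' z; radii unchanged.
#'
#' @param m a [morphology].
#' @param xy_scale,z_scale positive scale factors.
#' @return the scaled [morphology].
#' @export
shrinkage_correct <- function(m, xy_scale = 1, z_scale = 1) {
  if (xy_scale <= 0 || z_scale <= 0) stop("scale factors must be positive")
  m$nodes$x <- m$nodes$x * xy_scale
  m$nodes$y <- m$nodes$y * xy_scale
  m$nodes$z <- m$nodes$z * z_scale
  m
}

#' Unravel contracted neurites
#'
#' Re-lays each dendritic section's points along local principal axes
#' computed in a sliding window, preserving every segment length exactly and
#' straightening tortuosity (end-to-end distance does not decrease for
#' contracted sections). Downstream subtrees follow their attachment points
#' rigidly.
#'
#' @param m a [morphology].
#' @param window window size in nodes (>= 2).
#' @return the unravelled [morphology].
#' @export
unravel <- function(m, window = 5L) {
  stopifnot(window >= 2)
  n <- m$nodes
  prow <- match(n$parent, n$id)
  secs <- morph_sections(m, types = SWC_DEND)
  newpos <- as.matrix(n[, c("x", "y", "z")])
  # process root-outward; morph_sections already emits sections in id order
  for (r in secs) {
    att <- prow[r[1]]
    pts <- as.matrix(n[c(att, r), c("x", "y", "z")])  # original geometry
    k <- nrow(pts)
    q <- matrix(0, k, 3)
    q[1, ] <- newpos[att, ]
    ee <- pts[k, ] - pts[1, ]
    prev_u <- NULL
    for (i in 2:k) {
      lo <- max(1, i - window); hi <- min(k, lo + window)
      w <- pts[lo:hi, , drop = FALSE]
      cv <- stats::cov(w)
      u <- eigen(cv, symmetric = TRUE)$vectors[, 1]
      if (sum(u * ee) < 0) u <- -u
      if (!is.null(prev_u) && sum(u * prev_u) < 0) u <- -u
      if (all(abs(u) < 1e-12)) u <- ee / sqrt(sum(ee^2))
      L <- sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
      q[i, ] <- q[i - 1, ] + L * u
      prev_u <- u
    }
    shift_rows <- setdiff(subtree_rows(m, n$id[r[length(r)]]), r)
    dlt <- q[k, ] - newpos[r[length(r)], ]  # how far the section end moved
    newpos[r, ] <- q[-1, , drop = FALSE]
    if (length(shift_rows))
      newpos[shift_rows, ] <- sweep(newpos[shift_rows, , drop = FALSE], 2,
                                    dlt, "+")
  }
  m$nodes$x <- newpos[, 1]; m$nodes$y <- newpos[, 2]; m$nodes$z <- newpos[, 3]
  m
}

# ---- random variability ----------------------------------------------------

#' Randomise a morphology (length-preserving variants and 3D scaling)
#'
#' * `twist`: at every dendritic bifurcation, rotate each child subtree by a
#'   random angle in `[-amplitude, amplitude]` (radians) about the parent
#'   branch axis.
#' * `rotate`: as `twist` but about a random axis per subtree.
#' * `jitter`: Gaussian displacement (sd = `amplitude`, metres) of every
#'   neurite node followed by per-segment length restoration.
#' * `scale3d`: uniform scaling about the soma by a factor drawn from
#'   `[1 - amplitude, 1 + amplitude]` (coordinates and radii).
#'
#' `twist` and `rotate` are exact isometries of each subtree; `jitter`
#' preserves each segment length to float precision.
#'
#' @param m a [morphology].
#' @param method `"jitter"`, `"twist"`, `"rotate"` or `"scale3d"`.
#' @param amplitude method-specific amplitude (radians / metres / fraction).
#' @param rng_seed integer seed; same seed, same output.
#' @return the randomised [morphology].
#' @export
randomize <- function(m, method = c("jitter", "twist", "rotate", "scale3d"),
                      amplitude, rng_seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.numeric(amplitude), amplitude >= 0)
  if (method == "scale3d" && amplitude >= 1)
    stop("scale3d amplitude must be < 1")
  with_seed(rng_seed, {
    n <- m$nodes
    prow <- match(n$parent, n$id)
    if (method %in% c("twist", "rotate")) {
      nch <- .child_counts(m)
      kids <- morph_children(m)
      branch <- which(nch >= 2 & n$type %in% SWC_DEND & !is.na(prow))
      for (b in branch) {
        piv <- as.numeric(m$nodes[b, c("x", "y", "z")])
        axis_parent <- piv - as.numeric(m$nodes[prow[b], c("x", "y", "z")])
        for (ch in kids[[b]]) {
          ang <- runif(1, -amplitude, amplitude)
          axis <- if (method == "twist") axis_parent else {
            v <- rnorm(3); v / sqrt(sum(v^2))
          }
          if (sqrt(sum(axis^2)) < 1e-15) axis <- c(0, 0, 1)
          R <- rotation_about_axis(axis, ang)
          rows <- subtree_rows(m, m$nodes$id[ch])
          xyz <- t(R %*% (t(as.matrix(m$nodes[rows, c("x", "y", "z")])) -
                            piv)) + rep(piv, each = length(rows))
          m$nodes$x[rows] <- xyz[, 1]
          m$nodes$y[rows] <- xyz[, 2]
          m$nodes$z[rows] <- xyz[, 3]
        }
      }
    } else if (method == "jitter") {
      pos <- as.matrix(n[, c("x", "y", "z")])
      newpos <- pos
      for (i in seq_len(nrow(n))) {
        if (is.na(prow[i]) || n$type[i] == SWC_SOMA) next
        L <- sqrt(sum((pos[i, ] - pos[prow[i], ])^2))
        tgt <- pos[i, ] + rnorm(3, 0, amplitude) - newpos[prow[i], ]
        nt <- sqrt(sum(tgt^2))
        if (nt < 1e-15 || L == 0) { newpos[i, ] <- newpos[prow[i], ]; next }
        newpos[i, ] <- newpos[prow[i], ] + L * tgt / nt
      }
      m$nodes$x <- newpos[, 1]; m$nodes$y <- newpos[, 2]
      m$nodes$z <- newpos[, 3]
    } else {  # scale3d
      s <- runif(1, 1 - amplitude, 1 + amplitude)
      ctr <- soma_sphere(m)$centre
      m$nodes$x <- ctr[1] + (n$x - ctr[1]) * s
      m$nodes$y <- ctr[2] + (n$y - ctr[2]) * s
      m$nodes$z <- ctr[3] + (n$z - ctr[3]) * s
      m$nodes$radius <- n$radius * s
    }
    m
  })
}
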