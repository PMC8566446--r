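## Multi-stage stochastic synapse pruning.
##
## The probability of keeping a putative synapse is the product of the
## individual stages, P_keep = f1 * P_mu * P_SM * a3 * P_dist, applied in
## the order DP -> f1 -> SM -> mu2 -> a3:
##   DP  per synapse, keep with probability P(d), d = path distance to soma
##   f1  per synapse, keep with probability f1
##   SM  per pair, keep each synapse with probability
##       P_SM = 2*softMax / ((1 + exp(-(n - softMax)/5)) * n), n = count
##       entering the stage (a soft cap on per-pair synapse numbers)
##   mu2 per pair, keep ALL synapses with probability
##       P_mu = 1 / (1 + exp(-8/mu2 * (n - mu2))), else remove all
##   a3  per pair, keep all with probability a3, else remove all
## expected_kept() computes the exact expectation through the cascade and
## serves as the independent analytic oracle for the Monte-Carlo path.

#' Per-pair sigmoid keep probability (mu2 rule)
#'
#' `P_mu = 1 / (1 + exp(-8/mu2 * (n - mu2)))`: increasing in `n`, equal to
#' 1/2 at `n = mu2`. Used to remove (all synapses of) weakly connected
#' pairs.
#'
#' @param n synapse count(s) of the pair, >= 1.
#' @param mu2 sigmoid midpoint, > 0.
#' @return keep probability in (0, 1).
#' @export
p_mu <- function(n, mu2) {
  if (!is.numeric(mu2) || length(mu2) != 1 || mu2 <= 0)
    stop("mu2 must be a positive scalar")
  stopifnot(all(n >= 1))
  1 / (1 + exp(-8 / mu2 * (n - mu2)))
}

#' Per-synapse soft-max keep probability
#'
#' `P_SM = 2*softMax / ((1 + exp(-(n - softMax)/5)) * n)`, clamped to 1,
#' where `n` is the pair's synapse count entering the stage. The expected
#' kept count `n * P_SM` is bounded by `2 * softMax` for all `n`.
#'
#' @param n synapse count(s) entering the stage, >= 1.
#' @param soft_max soft cap parameter, > 0.
#' @return keep probability in (0, 1].
#' @export
p_softmax <- function(n, soft_max) {
  if (!is.numeric(soft_max) || length(soft_max) != 1 || soft_max <= 0)
    stop("softMax must be a positive scalar")
  stopifnot(all(n >= 1))
  pmin(1, 2 * soft_max / ((1 + exp(-(n - soft_max) / 5)) * n))
}

#' Pruning parameter set
#'
#' Any parameter may be `NULL`, disabling that stage. `dist_pruning` is a
#' function of `d` or a text expression in `d` (path distance in
#' micrometres) evaluating into `[0, 1]`.
#'
#' @param f1 per-synapse keep fraction in `[0, 1]` or `NULL`.
#' @param soft_max soft cap, > 0 or `NULL`.
#' @param mu2 sigmoid midpoint, > 0 or `NULL`.
#' @param a3 per-pair keep fraction in `[0, 1]` or `NULL`.
#' @param dist_pruning distance-dependence `P(d)`, see
#'   [parse_distance_expression()], or `NULL`.
#' @return a `pruning_parameters` object.
#' @export
pruning_parameters <- function(f1 = NULL, soft_max = NULL, mu2 = NULL,
                               a3 = NULL, dist_pruning = NULL) {
  chk01 <- function(v, nm) if (!is.null(v) &&
      (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1))
    stop(nm, " must be in [0, 1] or NULL")
  chkpos <- function(v, nm) if (!is.null(v) &&
      (!is.numeric(v) || length(v) != 1 || v <= 0))
    stop(nm, " must be positive or NULL")
  chk01(f1, "f1"); chk01(a3, "a3")
  chkpos(soft_max, "softMax"); chkpos(mu2, "mu2")
  structure(list(f1 = f1, soft_max = soft_max, mu2 = mu2, a3 = a3,
                 dist_pruning = parse_distance_expression(dist_pruning)),
            class = "pruning_parameters")
}

#' Connection specification
#'
#' Pairs a pre/post type with synapse model metadata and pruning parameter
#' sets. `pruning` applies within a population unit, `pruning_other` between
#' different units (falling back to `pruning` when absent).
#'
#' @param pre_type,post_type neuron type labels.
#' @param conductance length-2 numeric `(mean, sd)` in siemens; mean > 0,
#'   sd >= 0.
#' @param channel_parameters opaque list passed through (e.g. tau1, tau2,
#'   failRate).
#' @param parameter_file,mod_file opaque references.
#' @param pruning a [pruning_parameters()].
#' @param pruning_other optional [pruning_parameters()] for cross-unit pairs.
#' @return a `connection_spec`.
#' @export
connection_spec <- function(pre_type, post_type, conductance = c(1e-9, 0),
                            channel_parameters = list(),
                            parameter_file = NULL, mod_file = NULL,
                            pruning = pruning_parameters(),
                            pruning_other = NULL) {
  stopifnot(length(conductance) == 2, conductance[1] > 0, conductance[2] >= 0)
  stopifnot(inherits(pruning, "pruning_parameters"))
  if (!is.null(pruning_other))
    stopifnot(inherits(pruning_other, "pruning_parameters"))
  structure(list(pre_type = pre_type, post_type = post_type,
                 conductance = conductance,
                 channel_parameters = channel_parameters,
                 parameter_file = parameter_file, mod_file = mod_file,
                 pruning = pruning, pruning_other = pruning_other),
            class = "connection_spec")
}

#' Select the pruning parameter set for a neuron pair
#'
#' Same (non-zero) population unit on both sides uses `pruning`; different
#' units, or either side in unit 0, use `pruning_other` when present.
#'
#' @param spec a [connection_spec()].
#' @param pre_unit,post_unit population unit ids (0 = none).
#' @return a `pruning_parameters` object.
#' @export
select_params <- function(spec, pre_unit, post_unit) {
  same <- pre_unit == post_unit && pre_unit != 0L
  if (same || is.null(spec$pruning_other)) spec$pruning else spec$pruning_other
}

#' Prune a putative synapse table
#'
#' Applies the stage cascade DP -> f1 -> SM -> mu2 -> a3 to a synapse table
#' (as produced by [detect_touches()]; only `pre`, `post` and, if DP is
#' active, `dist_to_soma` are required). The table is first brought into
#' canonical (pre, post, voxel/distance) order, so the result is independent
#' of input row order and deterministic given the seed.
#'
#' @param synapses data.frame of putative synapses.
#' @param params a [pruning_parameters()].
#' @param rng_seed integer seed.
#' @param keep_connected if `TRUE`, the SM stage retains one synapse (chosen
#'   at random) for any pair it would otherwise disconnect. Off by default:
#'   the plain per-synapse reading is what the analytic expectations assume.
#' @return the pruned subset of `synapses` (row order canonical).
#' @export
prune <- function(synapses, params, rng_seed, keep_connected = FALSE) {
  stopifnot(inherits(params, "pruning_parameters"))
  s <- as.data.frame(synapses)
  if (!nrow(s)) return(s)
  ord <- do.call(order, lapply(intersect(c("pre", "post", "vx", "vy", "vz",
                                           "dist_to_soma", "section"),
                                         names(s)), function(cn) s[[cn]]))
  s <- s[ord, , drop = FALSE]
  rownames(s) <- NULL
  set.seed(rng_seed)

  if (!is.null(params$dist_pruning)) {
    if (is.null(s$dist_to_soma) || anyNA(s$dist_to_soma))
      stop("distance-dependent pruning requires dist_to_soma on every synapse")
    pd <- params$dist_pruning(s$dist_to_soma)
    if (any(pd < 0 | pd > 1)) stop("dist_pruning must evaluate into [0, 1]")
    s <- s[runif(nrow(s)) < pd, , drop = FALSE]
  }
  if (!is.null(params$f1) && nrow(s))
    s <- s[runif(nrow(s)) < params$f1, , drop = FALSE]

  pair_of <- function(df) paste(df$pre, df$post, sep = "_")
  if (!is.null(params$soft_max) && nrow(s)) {
    pid <- pair_of(s)
    n_pair <- table(pid)
    p <- p_softmax(as.numeric(n_pair[pid]), params$soft_max)
    keep <- runif(nrow(s)) < p
    if (keep_connected) {
      lost <- setdiff(names(n_pair), unique(pid[keep]))
      for (lp in lost) {
        rows <- which(pid == lp)
        keep[rows[sample.int(length(rows), 1)]] <- TRUE
      }
    }
    s <- s[keep, , drop = FALSE]
  }
  if (!is.null(params$mu2) && nrow(s)) {
    pid <- pair_of(s)
    pairs <- unique(pid)
    n_pair <- table(pid)[pairs]
    keep_pair <- runif(length(pairs)) < p_mu(as.numeric(n_pair), params$mu2)
    s <- s[pid %in% pairs[keep_pair], , drop = FALSE]
  }
  if (!is.null(params$a3) && nrow(s)) {
    pid <- pair_of(s)
    pairs <- unique(pid)
    keep_pair <- runif(length(pairs)) < params$a3
    s <- s[pid %in% pairs[keep_pair], , drop = FALSE]
  }
  rownames(s) <- NULL
  s
}

#' Exact expected synapse count through the pruning cascade
#'
#' Analytic propagation of each pair's synapse-count distribution through
#' the stage cascade: per-synapse stages (DP, f1) via (Poisson-)binomial
#' convolution, SM via a count-conditional binomial, mu2 and a3 as per-pair
#' all-or-none mixtures. Serves as the independent oracle for the
#' Monte-Carlo [prune()] path.
#'
#' @param pair_counts integer vector: initial synapse count per pair (one
#'   entry per pair), or a named histogram (names = n, values = number of
#'   pairs with that n).
#' @param params a [pruning_parameters()].
#' @param distances optional list (one numeric vector per pair, metres) of
#'   per-synapse path distances, required when `dist_pruning` is active.
#' @param keep_connected match the `keep_connected` flag of [prune()].
#' @return expected total number of synapses kept (numeric scalar).
#' @export
expected_kept <- function(pair_counts, params, distances = NULL,
                          keep_connected = FALSE) {
  stopifnot(inherits(params, "pruning_parameters"))
  if (!is.null(names(pair_counts)) && all(names(pair_counts) != "")) {
    pair_counts <- rep(as.integer(names(pair_counts)),
                       times = as.integer(pair_counts))
  }
  if (!length(pair_counts)) return(0)
  stopifnot(all(pair_counts >= 1))
  if (!is.null(params$dist_pruning) && is.null(distances))
    stop("expected_kept with dist_pruning needs per-pair distances")

  f1 <- if (is.null(params$f1)) 1 else params$f1
  total <- 0
  for (k in seq_along(pair_counts)) {
    n0 <- pair_counts[k]
    # per-synapse survival probabilities through DP and f1
    psurv <- rep(f1, n0)
    if (!is.null(params$dist_pruning)) {
      dk <- distances[[k]]
      stopifnot(length(dk) == n0)
      psurv <- psurv * params$dist_pruning(dk)
    }
    # Poisson-binomial distribution of the surviving count, q[n+1] = P(n)
    q <- 1
    for (p in psurv) q <- c(q * (1 - p), 0) + c(0, q * p)
    if (!is.null(params$soft_max)) {
      q2 <- numeric(n0 + 1)
      q2[1] <- q[1]
      for (n in seq_len(n0)) {
        if (q[n + 1] == 0) next
        psm <- p_softmax(n, params$soft_max)
        kept <- dbinom(0:n, n, psm)
        if (keep_connected) {  # mass at 0 moves to 1
          kept[2] <- kept[2] + kept[1]
          kept[1] <- 0
        }
        q2[1:(n + 1)] <- q2[1:(n + 1)] + q[n + 1] * kept
      }
      q <- q2
    }
    if (!is.null(params$mu2)) {
      pm <- c(0, p_mu(seq_len(n0), params$mu2))
      q <- q * pm
      # removed-pair mass collapses to zero synapses; only E matters
    }
    a3 <- if (is.null(params$a3)) 1 else params$a3
    total <- total + a3 * sum(seq(0, n0) * q)
  }
  unname(total)
}

#' Draw per-synapse conductances
#'
#' Normal draws truncated at zero (negative draws resampled); `sd = 0`
#' returns the mean exactly.
#'
#' @param spec a [connection_spec()] (uses its `conductance`).
#' @param n number of draws.
#' @param rng_seed integer seed.
#' @return numeric vector of conductances, siemens, all > 0.
#' @export
assign_conductance <- function(spec, n, rng_seed) {
  mu <- spec$conductance[1]; sdv <- spec$conductance[2]
  if (sdv < 0) stop("conductance sd must be >= 0")
  if (sdv == 0) return(rep(mu, n))
  set.seed(rng_seed)
  g <- rnorm(n, mu, sdv)
  while (any(g <= 0)) g[g <= 0] <- rnorm(sum(g <= 0), mu, sdv)
  g
}
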