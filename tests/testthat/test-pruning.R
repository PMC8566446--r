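# synapse_pruning: stage formulas, cascade, analytic expectation oracle

test_that("p_mu matches the printed sigmoid values and is monotone", {
  expect_equal(round(100 * p_mu(4, 3), 1), 93.5)
  expect_equal(round(100 * p_mu(3, 3), 1), 50.0)
  expect_equal(round(100 * p_mu(2, 3), 1), 6.5)
  expect_equal(round(100 * p_mu(1, 3), 1), 0.5)
  expect_equal(p_mu(3, 3), 0.5)        # midpoint identity n = mu2
  v <- p_mu(1:100, 7)
  expect_true(all(diff(v) >= 0))       # saturates to 1 in float for large n
  expect_true(all(diff(p_mu(1:20, 7)) > 0))
  expect_true(all(v > 0 & v <= 1))
  expect_error(p_mu(4, 0), "positive")
})

test_that("p_softmax matches printed values and caps expected counts", {
  expect_equal(round(100 * p_softmax(4, 3), 1), 82.5)
  expect_equal(p_softmax(3, 3), 1)     # n = softMax -> 2s/((1+e^0)s) = 1
  expect_equal(round(400 * p_softmax(4, 2)), 239)
  expect_equal(round(400 * p_softmax(4, 1)), 129)
  for (sm in c(0.5, 1, 2, 3, 8)) {
    n <- 1:100
    expect_true(all(n * p_softmax(n, sm) <= 2 * sm + 1e-9))
    expect_true(all(p_softmax(n, sm) <= 1))
  }
  expect_error(p_softmax(4, -1), "positive")
})

test_that("pruning parameter validation rejects out-of-range values", {
  expect_error(pruning_parameters(f1 = 1.2), "f1")
  expect_error(pruning_parameters(a3 = -0.1), "a3")
  expect_error(pruning_parameters(mu2 = 0), "mu2")
  expect_error(pruning_parameters(soft_max = 0), "softMax")
  expect_s3_class(pruning_parameters(), "pruning_parameters")
})

make_pair_table <- function(pairs = 100, k = 4) {
  data.frame(pre = rep(seq_len(pairs), each = k),
             post = rep(seq_len(pairs), each = k) + 10000L,
             vx = rep(seq_len(k), pairs), vy = 0L, vz = 0L,
             dist_to_soma = rep(seq_len(k), pairs) * 1e-5)
}

test_that("prune with no parameters is the identity; subset otherwise", {
  syn <- make_pair_table(10, 4)
  out <- prune(syn, pruning_parameters(), 1)
  expect_equal(nrow(out), 40L)
  out2 <- prune(syn, pruning_parameters(f1 = 0.5, mu2 = 3), 1)
  keys <- function(s) paste(s$pre, s$post, s$vx)
  expect_true(all(keys(out2) %in% keys(syn)))
})

test_that("prune is deterministic by seed and independent of row order", {
  syn <- make_pair_table(50, 4)
  pp <- pruning_parameters(f1 = 0.6, soft_max = 2, mu2 = 2, a3 = 0.8)
  a <- prune(syn, pp, 99)
  b <- prune(syn, pp, 99)
  expect_identical(a, b)
  shuffled <- syn[sample(nrow(syn)), ]
  c3 <- prune(shuffled, pp, 99)
  expect_identical(a, c3)
  d <- prune(syn, pp, 100)
  expect_false(identical(a, d))
})

test_that("distance-dependent stage keeps only where P(d) allows", {
  syn <- make_pair_table(20, 4)  # distances 10..40 um
  pp <- pruning_parameters(dist_pruning = "ifelse(d > 25, 1, 0)")
  out <- prune(syn, pp, 1)
  expect_true(all(out$dist_to_soma > 25e-6))
  expect_equal(nrow(out), 20 * 2)
  syn$dist_to_soma <- NULL
  expect_error(prune(syn, pp, 1), "dist_to_soma")
  bad <- pruning_parameters(dist_pruning = function(d) d * 0 + 2)
  expect_error(prune(make_pair_table(2, 2), bad, 1), "\\[0, 1\\]")
})

test_that("Monte-Carlo means match the analytic oracle across the grid", {
  fx_counts <- rep(4L, 100)
  syn <- make_pair_table(100, 4)
  cases <- list(
    list(pp = pruning_parameters(f1 = 0.5)),
    list(pp = pruning_parameters(mu2 = 3)),
    list(pp = pruning_parameters(f1 = 0.5, mu2 = 3)),
    list(pp = pruning_parameters(soft_max = 1)),
    list(pp = pruning_parameters(soft_max = 2, a3 = 0.8)),
    list(pp = pruning_parameters(f1 = 0.7, soft_max = 2, mu2 = 2, a3 = 0.5)))
  for (cs in cases) {
    kept <- vapply(1:400, function(s) nrow(prune(syn, cs$pp, s)), numeric(1))
    expec <- expected_kept(fx_counts, cs$pp)
    se <- stats::sd(kept) / sqrt(length(kept))
    expect_lt(abs(mean(kept) - expec), 3 * se + 1e-9)
  }
})

test_that("expected_kept reproduces the worked pruning expectations", {
  pc <- rep(4L, 100)
  expect_equal(expected_kept(pc, pruning_parameters(f1 = 0.5)), 200)
  expect_equal(expected_kept(pc, pruning_parameters(f1 = 0.25)), 100)
  expect_equal(round(expected_kept(pc, pruning_parameters(mu2 = 3))), 374)
  expect_equal(round(expected_kept(pc, pruning_parameters(f1 = 0.5,
                                                          mu2 = 3)), 1), 65.9)
  expect_equal(round(expected_kept(pc, pruning_parameters(f1 = 0.25,
                                                          mu2 = 3)), 1), 11.4)
  expect_equal(round(expected_kept(pc, pruning_parameters(soft_max = 3))), 330)
  expect_equal(round(expected_kept(pc, pruning_parameters(soft_max = 2))), 239)
  expect_equal(round(expected_kept(pc, pruning_parameters(soft_max = 1))), 129)
  expect_equal(expected_kept(pc, pruning_parameters(a3 = 0.5)), 200)
  expect_equal(expected_kept(pc, pruning_parameters(a3 = 0.25)), 100)
  # histogram form agrees with the per-pair form
  expect_equal(expected_kept(c("4" = 100), pruning_parameters(mu2 = 3)),
               expected_kept(pc, pruning_parameters(mu2 = 3)))
})

test_that("distance-dependent expectation is 20 * sum P(d_k) on the ladder", {
  dists <- ladder_distances_um * 1e-6
  pfun <- function(d) 1 / (1 + exp((d - 200) / 50))  # d in um
  pp <- pruning_parameters(dist_pruning = pfun)
  e <- expected_kept(rep(20L, 20), pp,
                     distances = lapply(dists, function(d) rep(d, 20)))
  expect_equal(e, 20 * sum(pfun(dists * 1e6)), tolerance = 1e-12)
  # constant P(d) = 0.5 -> half of the 400 synapses
  pp5 <- pruning_parameters(dist_pruning = "d * 0 + 0.5")
  e5 <- expected_kept(rep(20L, 20), pp5,
                      distances = lapply(dists, function(d) rep(d, 20)))
  expect_equal(e5, 200)
})

test_that("stage order matters: the declared cascade is DP-f1-SM-mu2-a3", {
  # mu2 before SM differs from SM before mu2 in expectation; regression-test
  # the declared order via expected_kept against a hand-rolled computation
  pc <- rep(4L, 50)
  pp <- pruning_parameters(soft_max = 2, mu2 = 3)
  # declared order: SM first (per-synapse on n = 4), then mu2 on the
  # post-SM count distribution
  psm <- p_softmax(4, 2)
  q <- dbinom(0:4, 4, psm)
  expec_hand <- 50 * sum((0:4) * q * c(0, p_mu(1:4, 3)))
  expect_equal(expected_kept(pc, pp), expec_hand, tolerance = 1e-12)
  # the reversed order would give a different number
  q_rev <- 50 * p_mu(4, 3) * 4 * psm
  expect_false(isTRUE(all.equal(expected_kept(pc, pp), q_rev)))
})

test_that("keep_connected SM variant never disconnects a pair", {
  syn <- make_pair_table(40, 4)
  pp <- pruning_parameters(soft_max = 0.5)
  for (s in 1:20) {
    out <- prune(syn, pp, s, keep_connected = TRUE)
    expect_equal(length(unique(paste(out$pre, out$post))), 40L)
  }
  # and its expectation oracle follows
  kept <- vapply(1:400, function(s)
    nrow(prune(syn, pp, s, keep_connected = TRUE)), numeric(1))
  expec <- expected_kept(rep(4L, 40), pp, keep_connected = TRUE)
  expect_lt(abs(mean(kept) - expec), 3 * stats::sd(kept) / sqrt(400))
})

test_that("select_params honours population-unit membership", {
  spec <- connection_spec("iSPN", "dSPN",
                          pruning = pruning_parameters(f1 = 0.9),
                          pruning_other = pruning_parameters(f1 = 0.1))
  expect_equal(select_params(spec, 1L, 1L)$f1, 0.9)
  expect_equal(select_params(spec, 1L, 2L)$f1, 0.1)
  expect_equal(select_params(spec, 0L, 0L)$f1, 0.1)  # unit 0 is "no unit"
  spec2 <- connection_spec("iSPN", "dSPN",
                           pruning = pruning_parameters(f1 = 0.9))
  expect_equal(select_params(spec2, 1L, 2L)$f1, 0.9)  # fallback
})

test_that("conductances are truncated-normal draws, exact at sd = 0", {
  spec <- connection_spec("a", "b", conductance = c(5e-10, 0))
  expect_equal(assign_conductance(spec, 5, 1), rep(5e-10, 5))
  spec2 <- connection_spec("a", "b", conductance = c(5e-10, 2e-10))
  g <- assign_conductance(spec2, 1e4, 2)
  expect_true(all(g > 0))
  expect_lt(abs(mean(g) - 5e-10), 3 * 2e-10 / sqrt(1e4) + 2e-12)
  expect_identical(assign_conductance(spec2, 100, 3),
                   assign_conductance(spec2, 100, 3))
})
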