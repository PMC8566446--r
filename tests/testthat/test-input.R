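# input_generation: Poisson trains, correlation, placement, CSV, virtual

test_that("rate profiles validate their vectors", {
  expect_s3_class(rate_profile(c(2, 5), c(3, 7), c(4, 2)), "rate_profile")
  expect_error(rate_profile(1, 0.5, 1), "start")
  expect_error(rate_profile(c(0, 1), c(2, 3), c(1, 1)), "overlap")
  expect_error(rate_profile(0, 1, -2), "frequency")
  expect_error(rate_profile(c(0, 1), 2, 1), "length")
})

test_that("poisson trains follow the piecewise rate profile", {
  expect_length(poisson_train(rate_profile(0, 10, 0), 10, 1), 0)
  n <- length(poisson_train(rate_profile(0, 1000, 1), 1000, 2))
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
  # the printed example: 4 Hz at 2-3 s, 2 Hz at 5-7 s
  pr <- rate_profile(c(2, 5), c(3, 7), c(4, 2))
  counts1 <- counts2 <- outside <- numeric(50)
  for (s in 1:50) {
    sp <- poisson_train(pr, 10, s)
    expect_false(is.unsorted(sp))
    counts1[s] <- sum(sp >= 2 & sp <= 3)
    counts2[s] <- sum(sp >= 5 & sp <= 7)
    outside[s] <- sum(sp < 2 | (sp > 3 & sp < 5) | sp > 7)
  }
  expect_equal(sum(outside), 0)
  expect_lt(abs(mean(counts1) - 4), 3 * sqrt(4 / 50))
  expect_lt(abs(mean(counts2) - 4), 3 * sqrt(4 / 50))
  # trains are clipped to the duration
  expect_true(all(poisson_train(pr, 2.5, 3) <= 2.5))
})

test_that("correlated trains hit the target correlation at equal rate", {
  pr <- rate_profile(0, 500, 2)
  # C = 1: all trains equal the mother; C = 0: independent
  tr1 <- correlated_trains(10, pr, 1, 500, 5)
  expect_true(all(vapply(tr1, identical, logical(1), tr1[[1]])))
  tr0 <- correlated_trains(50, pr, 0, 500, 6)
  c0 <- train_count_correlation(tr0, 500)
  expect_lt(abs(c0), 0.05)
  for (C in c(0.04, 0.25, 0.64)) {
    tr <- correlated_trains(60, pr, C, 500, 7)
    expect_lt(abs(train_count_correlation(tr, 500) - C), 0.05)
    # marginal rate is C-independent; trains share the mother, so the
    # variance of the mean count carries the pairwise correlation term
    rate <- mean(lengths(tr)) / 500
    se_rate <- sqrt(2 * (1 + 59 * C) / (500 * 60))
    expect_lt(abs(rate - 2), 3 * se_rate + 0.01)
  }
  expect_error(correlated_trains(5, pr, 1.2, 10, 1), "\\[0, 1\\]")
})

test_that("target-block resolution picks the most specific match", {
  blk <- function(tag) list(list(name = tag))
  config <- list(dSPN = blk("type"), dSPN_0 = blk("morph"), "5" = blk("id"))
  expect_equal(resolve_target_block(config, 5L, "dSPN_0", "dSPN")[[1]]$name,
               "id")
  expect_equal(resolve_target_block(config, 7L, "dSPN_0", "dSPN")[[1]]$name,
               "morph")
  expect_equal(resolve_target_block(config, 7L, "dSPN_1", "dSPN")[[1]]$name,
               "type")
  expect_length(resolve_target_block(config, 7L, "iSPN_0", "iSPN"), 0)
  expect_length(resolve_target_block(list(), 1L, "m", "t"), 0)
  # adding a more specific block never changes less specific neurons
  config2 <- c(config, list("7" = blk("id7")))
  expect_equal(resolve_target_block(config2, 8L, "dSPN_1", "dSPN")[[1]]$name,
               "type")
})

test_that("input synapse placement follows the density along the cable", {
  m <- make_ball_and_stick(n_dend = 50, step = 10e-6)  # 500 um of cable
  pl <- place_input_synapses(m, n_inputs = 200, rng_seed = 1)
  expect_equal(nrow(pl), 200L)
  # uniform density: flat path-distance histogram (chi-squared test)
  h <- table(cut(pl$dist_to_soma * 1e6, breaks = seq(0, 510, by = 102)))
  expect_gt(stats::chisq.test(h)$p.value, 1e-4)
  # step density: no proximal inputs
  pl2 <- place_input_synapses(m, n_inputs = 100,
                              density = "ifelse(d > 100, 1, 0)", rng_seed = 2)
  expect_true(all(pl2$dist_to_soma > 100e-6))
  expect_equal(nrow(place_input_synapses(m, n_inputs = 0, rng_seed = 3)), 0L)
  # density only: Poisson count, mean = integral(density dl)
  # constant 1e5 inputs per metre of cable over 500 um -> mean 50
  counts <- vapply(1:60, function(s)
    nrow(place_input_synapses(m, density = function(d) rep(1e5, length(d)),
                              rng_seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / 60))
})

test_that("scale_inputs multiplies channel counts", {
  ts <- list("3" = as.list(1:100))
  expect_identical(scale_inputs(ts, 3, 1), ts)
  expect_length(scale_inputs(ts, 3, 0)[["3"]], 0)
  expect_length(scale_inputs(ts, 3, 2, rng_seed = 1)[["3"]], 200)
  expect_length(scale_inputs(ts, 3, 0.25, rng_seed = 1)[["3"]], 25)
  expect_error(scale_inputs(ts, 3, -1), ">= 0")
})

test_that("CSV spike files read one sorted train per row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.5, 0.1, 0.9", "", "1.0 2.0"), f)
  tr <- read_csv_spikes(f)
  expect_length(tr, 3)
  expect_equal(tr[[1]], c(0.1, 0.5, 0.9))
  expect_length(tr[[2]], 0)
  expect_equal(tr[[3]], c(1, 2))
  writeLines(c("0.1, oops"), f)
  expect_error(read_csv_spikes(f), "row 1")
})

test_that("virtual neuron spike attachment validates the prototype", {
  vol <- volume_spec("cube", "cube", d_min = 0, side = 1e-4)
  pl <- place_neurons(vol, c(ctx = 3L), 1, rotation_mode = "none")
  proto <- neuron_prototype("ctx", "ctxAxon", "x.swc", is_virtual = TRUE)
  act <- virtual_neuron_spikes(pl, proto, list(c(0.2, 0.1)))
  expect_length(act, 3)
  expect_equal(act[[1]], c(0.1, 0.2))
  real <- neuron_prototype("ctx", "ctxAxon", "x.swc", is_virtual = FALSE)
  expect_error(virtual_neuron_spikes(pl, real, list(1)), "virtual")
  expect_error(virtual_neuron_spikes(pl, proto, list(1, 2)), "3 trains")
})

test_that("generate_input wires channels onto resolved targets", {
  fx <- make_grid_fixture(2, 1)
  cfg <- list(bas = list(input_block_spec(
    "Ctx", "poisson", rate_profile(0, 1, 5), correlation = 0.25,
    n_inputs = 8)))
  # only post neurons have dendrites; pre neurons would fail placement, so
  # target the post prototype via the morphology key
  cfg <- list(bas_post = cfg$bas)
  ts <- generate_input(fx$placement, fx$morphologies, cfg, 1, 42)
  expect_length(ts, 2)  # the two post neurons
  ch <- ts[[1]][["Ctx"]]
  expect_equal(nrow(ch$placements), 8L)
  expect_length(ch$spikes, 8L)
  # regenerating with the same master seed is identical
  ts2 <- generate_input(fx$placement, fx$morphologies, cfg, 1, 42)
  expect_identical(ts, ts2)
})
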