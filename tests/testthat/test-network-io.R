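# network_io: configuration schema, container round trip, CLI pipeline

write_min_config <- function(path, extra_conn = NULL) {
  cfg <- list(
    RandomSeed = list(masterseed = 11, place = 1, detect = 2, prune = 3,
                      input = 4),
    Volume = list(Cube = list(type = "cube", dMin = 5e-6, side = 1e-4,
                              centre = c(0, 0, 0))),
    PopulationUnits = list(),
    Connectivity = list("iSPN,dSPN" = c(list(
      conductance = c(2.4e-10, 1e-10),
      channelParameters = list(tau1 = 1.3e-3, tau2 = 12e-3, failRate = 0.7),
      modFile = "tmGabaA",
      pruning = list(f1 = 0.27, softMax = 8, mu2 = 2, a3 = 0.63),
      pruningOther = list(f1 = 0.05, a3 = 0.3)), extra_conn)),
    Neurons = list(
      iSPN = list(morphology = "ispn.swc", num = 2, volumeID = "Cube",
                  type = "iSPN", neuronType = "neuron"),
      dSPN = list(morphology = "dspn.swc", num = 2, volumeID = "Cube",
                  type = "dSPN", neuronType = "neuron")))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17))
  path
}

test_that("parse_config reads the schema, pruning blocks included", {
  f <- withr::local_tempfile(fileext = ".json")
  write_min_config(f)
  cfg <- parse_config(f)
  expect_s3_class(cfg, "network_config")
  spec <- cfg$connectivity[["iSPN,dSPN"]]
  expect_equal(spec$pre_type, "iSPN")
  expect_equal(spec$pruning$f1, 0.27)
  expect_equal(spec$pruning$soft_max, 8)
  expect_equal(spec$pruning_other$f1, 0.05)
  expect_null(spec$pruning_other$mu2)
  expect_equal(spec$channel_parameters$failRate, 0.7)
  expect_equal(cfg$volumes$Cube$side, 1e-4)
})

test_that("schema violations error with a JSON path; unknown keys warn", {
  f <- withr::local_tempfile(fileext = ".json")
  write_min_config(f)
  js <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  js$Connectivity[["iSPN,dSPN"]]$pruning$f1 <- 1.2
  jsonlite::write_json(js, f, auto_unbox = TRUE)
  expect_error(parse_config(f), "/Connectivity/iSPN,dSPN/pruning/f1")
  js$Connectivity[["iSPN,dSPN"]]$pruning$f1 <- 0.5
  js$Connectivity[["iSPN,dSPN"]]$pruning$frobnicate <- 1
  jsonlite::write_json(js, f, auto_unbox = TRUE)
  expect_warning(parse_config(f), "frobnicate")
  # undeclared neuron type in a connectivity key
  js$Connectivity[["iSPN,dSPN"]]$pruning$frobnicate <- NULL
  js$Connectivity[["LTS,dSPN"]] <- js$Connectivity[["iSPN,dSPN"]]
  jsonlite::write_json(js, f, auto_unbox = TRUE)
  expect_error(parse_config(f), "undeclared neuron type")
})

test_that("empty connectivity is valid and yields no synapses downstream", {
  f <- withr::local_tempfile(fileext = ".json")
  js <- jsonlite::fromJSON(write_min_config(f), simplifyVector = FALSE)
  js$Connectivity <- NULL
  jsonlite::write_json(js, f, auto_unbox = TRUE)
  cfg <- parse_config(f)
  expect_length(cfg$connectivity, 0)
})

test_that("init_config is deterministic and sizes the cube to the density", {
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  init_config(d1, 10, 77)
  init_config(d2, 10, 77)
  expect_identical(readLines(file.path(d1, "network.json")),
                   readLines(file.path(d2, "network.json")))
  cfg <- parse_config(file.path(d1, "network.json"), data_dir = d1)
  expect_equal(sum(vapply(cfg$neurons, `[[`, integer(1), "num")), 10L)
  expect_error(init_config(d1, 10, 77), "exists")
  # the reference striatal density puts 10,062 neurons in a 0.5 mm cube
  d3 <- file.path(withr::local_tempdir(), "c")
  init_config(d3, 10062, 1)
  cfg3 <- parse_config(file.path(d3, "network.json"), data_dir = d3)
  expect_equal(cfg3$volumes$Cube$side, 5e-4, tolerance = 1e-4)
})

test_that("network container round trips losslessly and checks integrity", {
  dir <- withr::local_tempdir()
  vol <- volume_spec("cube", "cube", d_min = 5e-6, side = 1e-4)
  pl <- place_neurons(vol, c(bas = 5L), 3)
  fx <- make_grid_fixture(3, 2)
  det <- detect_network(fx$placement, fx$morphologies, fx$allowed_pairs)
  cont <- list(placement = fx$placement, putative = det$synapses,
               synapses = det$synapses[1:3, ],
               provenance = list(config_hash = "abc",
                                 seeds = list(place = 1, detect = 2)))
  p <- file.path(dir, "net")
  write_network(cont, p)
  back <- read_network(p)
  expect_equal(back$placement$neurons, cont$placement$neurons)
  expect_equal(back$putative, det$synapses, ignore_attr = TRUE)
  expect_equal(back$synapses, det$synapses[1:3, ], ignore_attr = TRUE)
  expect_equal(back$provenance$config_hash, "abc")
  expect_equal(back$provenance$seeds$detect, 2)
  # empty network is a valid container
  p2 <- file.path(dir, "empty")
  write_network(list(), p2)
  expect_silent(read_network(p2))
  # version mismatch
  meta <- jsonlite::fromJSON(file.path(p, "meta.json"),
                             simplifyVector = TRUE)
  meta$version <- 999
  jsonlite::write_json(meta, file.path(p, "meta.json"), auto_unbox = TRUE)
  expect_error(read_network(p), "version mismatch")
  expect_error(read_network(file.path(dir, "nothing")), "not a network")
})

test_that("the CLI runs the full verb sequence on a small fixture", {
  td <- file.path(withr::local_tempdir(), "sim")
  expect_equal(cli(c("init", td, "--size", "10", "--seed", "42")), 0L)
  expect_equal(cli(c("place", td)), 0L)
  expect_equal(cli(c("detect", td)), 0L)
  expect_equal(cli(c("prune", td)), 0L)
  ic <- list(bas = list(Ctx = list(
    generator = "poisson", start = 0, end = 1, frequency = 5,
    populationCorrelation = 0.25, nInputs = 5, type = "AMPA_NMDA",
    conductance = c(5e-10, 0), modFile = "tmGlut")))
  jsonlite::write_json(ic, file.path(td, "input.json"), auto_unbox = TRUE)
  expect_equal(cli(c("input", td, "--time", "1")), 0L)
  net <- read_network(file.path(td, "network"))
  expect_equal(nrow(net$placement$neurons), 10L)
  expect_true(!is.null(net$putative))
  expect_true(!is.null(net$synapses))
  expect_length(net$input, 10L)
  # repeated prune with the same seed: byte-identical synapse table
  before <- net$synapses
  expect_equal(cli(c("prune", td)), 0L)
  expect_identical(read_network(file.path(td, "network"))$synapses, before)
  # out-of-order invocation names the missing product
  td2 <- file.path(withr::local_tempdir(), "sim2")
  cli(c("init", td2, "--size", "5"))
  expect_equal(cli(c("detect", td2)), 1L)
  expect_equal(cli(c("prune", td2)), 1L)
  expect_equal(cli(c("nonsense")), 1L)
})

test_that("input config files parse into block specs", {
  f <- withr::local_tempfile(fileext = ".json")
  cfg <- list(dSPN = list(
    Ctx = list(generator = "poisson", start = c(2, 5), end = c(3, 7),
               frequency = c(4, 2), populationCorrelation = 0.25,
               nInputs = 20, type = "AMPA_NMDA", modFile = "tmGlut"),
    Thalamic = list(generator = "poisson", start = 0, end = 1,
                    frequency = 1, nInputs = 5)))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE)
  ic <- read_input_config(f)
  expect_length(ic$dSPN, 2)
  expect_equal(ic$dSPN[[1]]$profile$frequency, c(4, 2))
  expect_equal(ic$dSPN[[1]]$correlation, 0.25)
  expect_equal(ic$dSPN[[2]]$n_inputs, 5)
})
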