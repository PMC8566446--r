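## JSON network configuration, the on-disk network container and the CLI.
##
## The container is a directory of plain-text tables (TSV, 17 significant
## digits for floats) plus JSON metadata: lossless round trip, integer and
## float synapse matrices stored separately, provenance (config hash and all
## stage seeds) preserved. The layout is this package's own contract.

CONTAINER_VERSION <- 1L

# ---- configuration ---------------------------------------------------------

.known_keys <- list(
  top = c("RandomSeed", "Volume", "PopulationUnits", "Connectivity",
          "Neurons"),
  volume = c("type", "dMin", "side", "centre", "meshFile", "meshBinWidth"),
  conn = c("conductance", "channelParameters", "parameterFile", "modFile",
           "pruning", "pruningOther", "connectionType"),
  pruning = c("f1", "softMax", "mu2", "a3", "distPruning"),
  neuron = c("morphology", "parameters", "mechanisms", "modulation", "num",
             "volumeID", "rotationMode", "neuronType", "type", "hoc"))

.warn_unknown <- function(block, known, where) {
  extra <- setdiff(names(block), known)
  if (length(extra))
    warning("unknown configuration keys at ", where, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
}

.parse_pruning_block <- function(pb, where) {
  if (is.null(pb)) return(NULL)
  .warn_unknown(pb, .known_keys$pruning, where)
  bad <- function(key, cond) if (cond)
    stop("schema error at ", where, "/", key, call. = FALSE)
  if (!is.null(pb$f1)) bad("f1", pb$f1 < 0 || pb$f1 > 1)
  if (!is.null(pb$a3)) bad("a3", pb$a3 < 0 || pb$a3 > 1)
  if (!is.null(pb$softMax)) bad("softMax", pb$softMax <= 0)
  if (!is.null(pb$mu2)) bad("mu2", pb$mu2 <= 0)
  pruning_parameters(f1 = pb$f1, soft_max = pb$softMax, mu2 = pb$mu2,
                     a3 = pb$a3, dist_pruning = pb$distPruning)
}

#' Parse and validate a JSON network configuration
#'
#' Blocks: `RandomSeed` (per-stage seeds), `Volume`, `PopulationUnits`,
#' `Connectivity` (keys `"preType,postType"`), `Neurons`. All values in SI
#' units. A `"$DATA"` path prefix is substituted by `data_dir`. Unknown keys
#' warn; missing required keys or out-of-range values raise a schema error
#' naming the JSON path.
#'
#' @param path JSON file.
#' @param data_dir substitution for `"$DATA"` (default: the package's
#'   `extdata` directory).
#' @return a `network_config` object.
#' @export
parse_config <- function(path, data_dir = NULL) {
  if (!file.exists(path)) stop("config not found: ", path)
  if (is.null(data_dir))
    data_dir <- system.file("extdata", package = "touchnet")
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  .warn_unknown(cfg, .known_keys$top, "/")
  subst <- function(p) if (is.character(p)) sub("^\\$DATA", data_dir, p) else p
  seeds <- cfg$RandomSeed
  if (is.null(seeds)) stop("schema error at /RandomSeed: block required")
  for (st in c("place", "detect", "prune", "input"))
    if (is.null(seeds[[st]]))
      seeds[[st]] <- derive_seed(seeds$masterseed %||% 0, st)
  volumes <- list()
  for (vn in names(cfg$Volume)) {
    vb <- cfg$Volume[[vn]]
    .warn_unknown(vb, .known_keys$volume, paste0("/Volume/", vn))
    if (is.null(vb$type)) stop("schema error at /Volume/", vn, "/type")
    volumes[[vn]] <- if (vb$type == "cube") {
      volume_spec(vn, "cube", d_min = vb$dMin %||% 0, side = vb$side,
                  centre = vb$centre %||% c(0, 0, 0))
    } else {
      volume_spec(vn, "mesh", d_min = vb$dMin %||% 0,
                  mesh_file = subst(vb$meshFile),
                  mesh_bin_width = vb$meshBinWidth)
    }
  }
  units <- lapply(cfg$PopulationUnits, function(u)
    population_unit_spec(u$unitID, u$volume %||% names(volumes)[1],
                         u$neuronTypes, u$fraction))
  conns <- list()
  for (key in names(cfg$Connectivity)) {
    cb <- cfg$Connectivity[[key]]
    .warn_unknown(cb, .known_keys$conn, paste0("/Connectivity/", key))
    tp <- trimws(strsplit(key, ",")[[1]])
    if (length(tp) != 2)
      stop("schema error at /Connectivity/", key, ": key must be 'pre,post'")
    conns[[key]] <- connection_spec(
      pre_type = tp[1], post_type = tp[2],
      conductance = unlist(cb$conductance) %||% c(1e-9, 0),
      channel_parameters = cb$channelParameters %||% list(),
      parameter_file = subst(cb$parameterFile), mod_file = cb$modFile,
      pruning = .parse_pruning_block(cb$pruning,
                                     paste0("/Connectivity/", key, "/pruning"))
        %||% pruning_parameters(),
      pruning_other = .parse_pruning_block(
        cb$pruningOther, paste0("/Connectivity/", key, "/pruningOther")))
    conns[[key]]$connection_type <- cb$connectionType %||% "synapse"
  }
  neurons <- list()
  for (nm in names(cfg$Neurons)) {
    nb <- cfg$Neurons[[nm]]
    .warn_unknown(nb, .known_keys$neuron, paste0("/Neurons/", nm))
    if (is.null(nb$morphology))
      stop("schema error at /Neurons/", nm, "/morphology: required")
    if (is.null(nb$num) || nb$num < 0)
      stop("schema error at /Neurons/", nm, "/num")
    vol <- nb$volumeID %||% names(volumes)[1]
    if (!vol %in% names(volumes))
      stop("schema error at /Neurons/", nm, "/volumeID: undeclared volume '",
           vol, "'")
    neurons[[nm]] <- list(
      name = nm, morphology = subst(nb$morphology),
      num = as.integer(nb$num), volume = vol,
      rotation_mode = nb$rotationMode %||% "random",
      type = nb$type %||% nm,
      is_virtual = identical(nb$neuronType, "virtualNeuron"))
  }
  types <- vapply(neurons, `[[`, "", "type")
  for (key in names(conns)) {
    tp <- c(conns[[key]]$pre_type, conns[[key]]$post_type)
    if (!all(tp %in% types))
      stop("schema error at /Connectivity/", key,
           ": references undeclared neuron type")
  }
  structure(list(seeds = seeds, volumes = volumes, units = units,
                 connectivity = conns, neurons = neurons,
                 path = normalizePath(path)),
            class = "network_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialise a network directory with a generated configuration
#'
#' Writes `network.json` for a cube volume sized to hold `size` neurons at
#' the reference density, together with a ball-and-stick morphology. Stage
#' seeds are derived from the master seed, so two runs with the same seed
#' produce identical files.
#'
#' @param out_dir target directory.
#' @param size total neuron count (> 0).
#' @param rng_seed master seed.
#' @param overwrite allow an existing directory (default `FALSE`: refuse).
#' @param d_min minimum soma separation, metres.
#' @param reference_density neurons per m^3 (default 80,496 per mm^3, the
#'   striatal value that puts 10,062 neurons in a 0.5 mm cube).
#' @return the config file path, invisibly.
#' @export
init_config <- function(out_dir, size, rng_seed, overwrite = FALSE,
                        d_min = 15e-6, reference_density = 8.0496e13) {
  stopifnot(size > 0)
  if (dir.exists(out_dir) && !overwrite)
    stop("directory exists: ", out_dir, " (use overwrite = TRUE)")
  dir.create(file.path(out_dir, "morphology"), recursive = TRUE,
             showWarnings = FALSE)
  side <- (size / reference_density)^(1 / 3)
  swc_path <- file.path(out_dir, "morphology", "ball_and_stick.swc")
  write_swc(make_ball_and_stick(), swc_path)
  cfg <- list(
    RandomSeed = list(masterseed = rng_seed,
                      place = derive_seed(rng_seed, "place"),
                      detect = derive_seed(rng_seed, "detect"),
                      prune = derive_seed(rng_seed, "prune"),
                      input = derive_seed(rng_seed, "input")),
    Volume = list(Cube = list(type = "cube", dMin = d_min, side = side,
                              centre = c(0, 0, 0))),
    PopulationUnits = list(),
    Connectivity = list(
      "bas,bas" = list(conductance = c(5e-10, 1e-10), modFile = "tmGabaA",
                       pruning = list(f1 = 0.5, mu2 = 3, a3 = 1.0))),
    Neurons = list(bas = list(morphology = "morphology/ball_and_stick.swc",
                              num = size, volumeID = "Cube",
                              rotationMode = "random", neuronType = "neuron",
                              type = "bas")))
  path <- file.path(out_dir, "network.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = I(17))
  invisible(path)
}

# ---- container -------------------------------------------------------------

.fmt_num <- function(x) sprintf("%.17g", x)

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path, classes) {
  if (!file.exists(path)) stop("container integrity error: missing ", path)
  utils::read.table(path, sep = "\t", header = TRUE, colClasses = classes,
                    stringsAsFactors = FALSE)
}

#' Write a network container
#'
#' @param container list with any of: `placement` (a `placement_result`),
#'   `putative` and `synapses` (synapse tables), `gap_junctions`, `input`
#'   (a `spike_train_set`), and `provenance` (list; `config_hash` and
#'   `seeds` preserved verbatim).
#' @param path container directory (created).
#' @return `path`, invisibly.
#' @export
write_network <- function(container, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(version = CONTAINER_VERSION,
               provenance = container$provenance %||% list(),
               has = list(
                 placement = !is.null(container$placement),
                 putative = !is.null(container$putative),
                 synapses = !is.null(container$synapses),
                 gap_junctions = !is.null(container$gap_junctions),
                 input = !is.null(container$input)))
  if (!is.null(container$placement)) {
    pl <- container$placement
    .write_tsv(pl$neurons, file.path(path, "neurons.tsv"))
    rot <- data.frame(id = pl$neurons$id,
                      do.call(rbind, lapply(pl$rotations, as.vector)))
    names(rot) <- c("id", paste0("r", 1:9))
    .write_tsv(rot, file.path(path, "rotations.tsv"))
    pad <- as.data.frame(pl$padding)
    if (ncol(pad) == 3) names(pad) <- c("x", "y", "z")
    .write_tsv(pad, file.path(path, "padding.tsv"))
    meta$placement <- list(d_min = pl$d_min, volume = pl$volume)
  }
  wr_syn <- function(tb, stem) {
    .write_tsv(tb[c("pre", "post", "vx", "vy", "vz", "section")],
               file.path(path, paste0(stem, "_int.tsv")))
    .write_tsv(tb[c("x", "y", "z", "offset", "dist_to_soma")],
               file.path(path, paste0(stem, "_float.tsv")))
    writeLines(tb$type_pair, file.path(path, paste0(stem, "_types.txt")))
  }
  if (!is.null(container$putative)) wr_syn(container$putative, "putative")
  if (!is.null(container$synapses)) wr_syn(container$synapses, "synapses")
  if (!is.null(container$gap_junctions))
    .write_tsv(container$gap_junctions, file.path(path, "gap_junctions.tsv"))
  if (!is.null(container$input))
    jsonlite::write_json(
      list(duration = attr(container$input, "duration"),
           trains = unclass(container$input)),
      file.path(path, "input.json"), auto_unbox = TRUE, digits = I(17),
      dataframe = "columns")
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read a network container
#'
#' @param path container directory written by [write_network()].
#' @return the container list; stops on version mismatch or inconsistent
#'   tables.
#' @export
read_network <- function(path) {
  metaf <- file.path(path, "meta.json")
  if (!file.exists(metaf)) stop("not a network container: ", path)
  meta <- jsonlite::fromJSON(metaf, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(meta$version) || meta$version != CONTAINER_VERSION)
    stop("container version mismatch: found ", meta$version %||% "none",
         ", expected ", CONTAINER_VERSION, " (migration required)")
  out <- list(provenance = meta$provenance)
  icls <- c(pre = "integer", post = "integer", vx = "integer",
            vy = "integer", vz = "integer", section = "integer")
  fcls <- c(x = "numeric", y = "numeric", z = "numeric", offset = "numeric",
            dist_to_soma = "numeric")
  rd_syn <- function(stem) {
    tb <- cbind(.read_tsv(file.path(path, paste0(stem, "_int.tsv")), icls),
                .read_tsv(file.path(path, paste0(stem, "_float.tsv")), fcls))
    tb$type_pair <- readLines(file.path(path, paste0(stem, "_types.txt")))
    tb[c("pre", "post", "vx", "vy", "vz", "x", "y", "z", "section",
         "offset", "dist_to_soma", "type_pair")]
  }
  if (isTRUE(meta$has$placement)) {
    nn <- .read_tsv(file.path(path, "neurons.tsv"),
                    c(id = "integer", prototype = "character",
                      type = "character", x = "numeric", y = "numeric",
                      z = "numeric", volume = "character", unit = "integer"))
    rot <- .read_tsv(file.path(path, "rotations.tsv"), NA)
    pad <- tryCatch(as.matrix(.read_tsv(file.path(path, "padding.tsv"), NA)),
                    error = function(e) matrix(numeric(0), 0, 3))
    if (!is.numeric(pad)) pad <- matrix(numeric(0), 0, 3)
    out$placement <- structure(
      list(neurons = nn,
           rotations = lapply(seq_len(nrow(rot)), function(i)
             matrix(as.numeric(rot[i, -1]), 3, 3)),
           padding = pad, d_min = meta$placement$d_min %||% 0,
           volume = meta$placement$volume %||% ""),
      class = "placement_result")
  }
  if (isTRUE(meta$has$putative)) out$putative <- rd_syn("putative")
  if (isTRUE(meta$has$synapses)) out$synapses <- rd_syn("synapses")
  if (isTRUE(meta$has$gap_junctions))
    out$gap_junctions <- .read_tsv(file.path(path, "gap_junctions.tsv"), NA)
  inf <- file.path(path, "input.json")
  if (isTRUE(meta$has$input) && file.exists(inf)) {
    ij <- jsonlite::fromJSON(inf, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
    out$input <- structure(ij$trains, class = "spike_train_set",
                           duration = ij$duration)
  }
  # cross-consistency
  if (!is.null(out$placement)) {
    nmax <- max(out$placement$neurons$id)
    for (tb in list(out$putative, out$synapses))
      if (!is.null(tb) && nrow(tb) && max(tb$pre, tb$post) > nmax)
        stop("container integrity error: synapse references neuron id ",
             max(tb$pre, tb$post), " > ", nmax)
  }
  out
}

# ---- pipeline stages -------------------------------------------------------

# prune a putative table per connection spec and population units
prune_network <- function(putative, placement, config, rng_seed) {
  if (!nrow(putative)) return(putative)
  nn <- placement$neurons
  unit_of <- stats::setNames(nn$unit, as.character(nn$id))
  kept <- list()
  for (key in names(config$connectivity)) {
    spec <- config$connectivity[[key]]
    if (!is.null(spec$connection_type) && spec$connection_type != "synapse")
      next
    rows <- putative[putative$type_pair == paste(spec$pre_type,
                                                 spec$post_type, sep = ","), ,
                     drop = FALSE]
    if (!nrow(rows)) next
    same <- unit_of[as.character(rows$pre)] ==
      unit_of[as.character(rows$post)] &
      unit_of[as.character(rows$pre)] != 0L
    for (grp in c(TRUE, FALSE)) {
      part <- rows[same == grp, , drop = FALSE]
      if (!nrow(part)) next
      params <- if (grp) spec$pruning else
        (spec$pruning_other %||% spec$pruning)
      kept[[paste(key, grp)]] <-
        prune(part, params, derive_seed(rng_seed, paste0(key, "_", grp)))
    }
  }
  if (!length(kept)) return(putative[0, , drop = FALSE])
  out <- do.call(rbind, kept)
  out <- out[order(out$pre, out$post, out$vx, out$vy, out$vz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pipeline command-line interface
#'
#' Verbs mirroring the build pipeline: `init <dir> --size N [--seed S]
#' [--overwrite]`, `place <dir>`, `detect <dir>`, `prune <dir>`,
#' `input <dir> --input <input.json> --time T`. Stages are idempotent given
#' unchanged inputs and seeds; running a stage before its dependency fails
#' with a dependency error naming the missing product.
#'
#' @param argv character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status (0 on success), invisibly.
#' @export
cli <- function(argv) {
  res <- tryCatch({
    .cli_run(argv)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}

.cli_opt <- function(argv, flag, default = NULL) {
  i <- which(argv == flag)
  if (!length(i)) return(default)
  if (i[1] == length(argv)) stop("missing value for ", flag)
  argv[i[1] + 1]
}

.cli_run <- function(argv) {
  if (!length(argv)) stop("usage: init|place|detect|prune|input <dir> [...]")
  verb <- argv[1]
  if (!verb %in% c("init", "place", "detect", "prune", "input"))
    stop("unknown verb '", verb, "'")
  dir <- if (length(argv) >= 2 && !startsWith(argv[2], "--")) argv[2] else
    stop("missing network directory")
  seed_opt <- .cli_opt(argv, "--seed")
  cdir <- file.path(dir, "network")
  if (verb == "init") {
    size <- as.integer(.cli_opt(argv, "--size", stop("init needs --size")))
    init_config(dir, size, as.integer(seed_opt %||% 1234),
                overwrite = "--overwrite" %in% argv)
    return(invisible(NULL))
  }
  cfgf <- file.path(dir, "network.json")
  if (!file.exists(cfgf))
    stop("dependency error: ", cfgf, " missing (run 'init' first)")
  config <- parse_config(cfgf, data_dir = dir)
  # morphology paths in generated configs are relative to the network dir
  for (nm in names(config$neurons)) {
    p <- config$neurons[[nm]]$morphology
    if (!file.exists(p) && file.exists(file.path(dir, p)))
      config$neurons[[nm]]$morphology <- file.path(dir, p)
  }
  hash <- unname(tools::md5sum(cfgf))
  if (verb == "place") {
    vol <- config$volumes[[1]]
    counts <- vapply(config$neurons, `[[`, integer(1), "num")
    types <- vapply(config$neurons, `[[`, "", "type")
    seed <- as.integer(seed_opt %||% config$seeds$place)
    pl <- place_neurons(vol, counts, seed, types = types)
    if (length(config$units))
      pl <- assign_population_units(pl, config$units,
                                    derive_seed(seed, "units"))
    write_network(list(placement = pl,
                       provenance = list(config_hash = hash,
                                         seeds = config$seeds)), cdir)
    return(invisible(NULL))
  }
  if (!dir.exists(cdir))
    stop("dependency error: no network container (run 'place' first)")
  net <- read_network(cdir)
  if (verb == "detect") {
    if (is.null(net$placement))
      stop("dependency error: placement missing (run 'place' first)")
    morphs <- lapply(config$neurons, function(nb) read_swc(nb$morphology))
    allowed <- do.call(rbind, lapply(config$connectivity, function(s)
      data.frame(pre = s$pre_type, post = s$post_type)))
    det <- detect_network(net$placement, morphs, allowed)
    net$putative <- det$synapses
    write_network(net, cdir)
    return(invisible(NULL))
  }
  if (verb == "prune") {
    if (is.null(net$putative))
      stop("dependency error: putative synapses missing (run 'detect' first)")
    seed <- as.integer(seed_opt %||% config$seeds$prune)
    net$synapses <- prune_network(net$putative, net$placement, config, seed)
    write_network(net, cdir)
    return(invisible(NULL))
  }
  # input
  if (is.null(net$placement))
    stop("dependency error: placement missing (run 'place' first)")
  duration <- as.numeric(.cli_opt(argv, "--time",
                                  stop("input needs --time")))
  inpf <- .cli_opt(argv, "--input", file.path(dir, "input.json"))
  if (!file.exists(inpf)) stop("input configuration not found: ", inpf)
  input_config <- read_input_config(inpf)
  morphs <- lapply(config$neurons, function(nb) read_swc(nb$morphology))
  seed <- as.integer(seed_opt %||% config$seeds$input)
  net$input <- generate_input(net$placement, morphs, input_config, duration,
                              seed)
  write_network(net, cdir)
  invisible(NULL)
}

#' Read an input configuration file
#'
#' JSON: target blocks keyed by neuron id, morphology key or type, each a
#' map of channel name -> fields `generator`, `start`, `end`, `frequency`,
#' `populationCorrelation`, `nInputs`, `synapseDensity`, `type`,
#' `conductance`, `modFile`, `parameterFile`, `csvFile`.
#'
#' @param path JSON file.
#' @return named list of target blocks of [input_block_spec()] lists.
#' @export
read_input_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  lapply(cfg, function(block)
    lapply(names(block), function(chname) {
      ch <- block[[chname]]
      gen <- ch$generator %||% "poisson"
      input_block_spec(
        name = chname, generator = gen,
        profile = if (gen == "poisson")
          rate_profile(unlist(ch$start), unlist(ch$end),
                       unlist(ch$frequency)) else NULL,
        correlation = ch$populationCorrelation %||% 0,
        n_inputs = ch$nInputs, synapse_density = ch$synapseDensity,
        type = ch$type %||% "AMPA_NMDA",
        conductance = unlist(ch$conductance) %||% c(5e-10, 0),
        mod_file = ch$modFile, parameter_file = ch$parameterFile,
        csv_file = ch$csvFile)
    }))
}
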