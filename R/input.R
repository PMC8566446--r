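## External synaptic input: piecewise-rate Poisson trains, correlated train
## ensembles via a thinned mother process, target-block resolution,
## dendritic placement, CSV spikes and virtual neurons.

#' Piecewise-constant rate profile
#'
#' @param start,end,frequency equal-length vectors: interval starts/ends in
#'   seconds and rates in Hz. Intervals must be non-overlapping with
#'   `start < end` and `frequency >= 0`. Rate is zero outside all intervals.
#' @return a `rate_profile`.
#' @export
rate_profile <- function(start, end, frequency) {
  stopifnot(length(start) == length(end), length(end) == length(frequency))
  if (length(start)) {
    if (any(start >= end)) stop("rate profile: start must be < end")
    if (any(frequency < 0)) stop("rate profile: frequency must be >= 0")
    o <- order(start)
    start <- start[o]; end <- end[o]; frequency <- frequency[o]
    if (length(start) > 1 && any(start[-1] < end[-length(end)] - 1e-12))
      stop("rate profile: intervals overlap")
  }
  structure(list(start = start, end = end, frequency = frequency),
            class = "rate_profile")
}

#' Generate a piecewise-homogeneous Poisson spike train
#'
#' Within each `[start, end)` interval of the profile (clipped to
#' `[0, duration]`) spikes are Poisson with the interval's rate; no spikes
#' elsewhere.
#'
#' @param profile a [rate_profile()].
#' @param duration simulation length, seconds (> 0).
#' @param rng_seed optional integer seed; `NULL` uses the current stream.
#' @return sorted numeric vector of spike times, seconds.
#' @export
poisson_train <- function(profile, duration, rng_seed = NULL) {
  stopifnot(inherits(profile, "rate_profile"), duration > 0)
  gen <- function() {
    spikes <- numeric(0)
    for (i in seq_along(profile$start)) {
      a <- max(0, profile$start[i]); b <- min(duration, profile$end[i])
      if (b <= a || profile$frequency[i] == 0) next
      n <- rpois(1, profile$frequency[i] * (b - a))
      if (n > 0) spikes <- c(spikes, a + sort(runif(n)) * (b - a))
    }
    sort(spikes)
  }
  if (is.null(rng_seed)) gen() else with_seed(rng_seed, gen())
}

#' Generate correlated Poisson spike trains
#'
#' A shared mother process at the target rate is thinned independently per
#' train with probability `P = sqrt(C)` and merged with an independent
#' Poisson process at rate `(1 - P) * f(t)`, so every train keeps the
#' marginal rate profile while pairwise spike-count correlation (in
#' moderate bins) is `P^2 = C`.
#'
#' @param k number of trains (>= 1).
#' @param profile a [rate_profile()].
#' @param C population correlation in `[0, 1]`.
#' @param duration seconds.
#' @param rng_seed integer seed.
#' @return list of `k` sorted spike-time vectors.
#' @export
correlated_trains <- function(k, profile, C, duration, rng_seed) {
  stopifnot(k >= 1)
  if (!is.numeric(C) || length(C) != 1 || C < 0 || C > 1)
    stop("populationCorrelation C must be in [0, 1]")
  P <- sqrt(C)
  child_profile <- rate_profile(profile$start, profile$end,
                                profile$frequency * (1 - P))
  with_seed(rng_seed, {
    mother <- poisson_train(profile, duration)
    lapply(seq_len(k), function(i) {
      kept <- if (P == 1) mother else mother[runif(length(mother)) < P]
      sort(c(kept, poisson_train(child_profile, duration)))
    })
  })
}

#' Pairwise spike-count correlation of a train ensemble
#'
#' Mean off-diagonal Pearson correlation of binned spike counts; the
#' empirical counterpart of the `populationCorrelation` parameter.
#'
#' @param trains list of spike-time vectors, seconds.
#' @param duration seconds.
#' @param bin bin width, seconds (default 0.1).
#' @return scalar correlation.
#' @export
train_count_correlation <- function(trains, duration, bin = 0.1) {
  edges <- seq(0, duration, by = bin)
  counts <- vapply(trains, function(tt)
    tabulate(findInterval(tt, edges, left.open = FALSE,
                          rightmost.closed = TRUE),
             nbins = length(edges) - 1), numeric(length(edges) - 1))
  cm <- suppressWarnings(cor(counts))
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}

#' Input block specification
#'
#' One external-input channel for a target block: a named generator with a
#' rate profile, correlation, placement rule and synapse metadata.
#'
#' @param name channel name (e.g. `"Ctx"`).
#' @param generator `"poisson"` or `"csv"`.
#' @param profile a [rate_profile()] (poisson generator).
#' @param correlation population correlation `C` in `[0, 1]`.
#' @param n_inputs exact input count, or `NULL`.
#' @param synapse_density density expression in `d` (micrometres; see
#'   [parse_distance_expression()]) or `NULL`.
#' @param type synapse type tag (e.g. `"AMPA_NMDA"`).
#' @param conductance length-2 `(mean, sd)`, siemens.
#' @param mod_file,parameter_file opaque metadata.
#' @param csv_file path for the csv generator.
#' @return an `input_block_spec`.
#' @export
input_block_spec <- function(name, generator = c("poisson", "csv"),
                             profile = NULL, correlation = 0,
                             n_inputs = NULL, synapse_density = NULL,
                             type = "AMPA_NMDA", conductance = c(5e-10, 0),
                             mod_file = NULL, parameter_file = NULL,
                             csv_file = NULL) {
  generator <- match.arg(generator)
  if (correlation < 0 || correlation > 1)
    stop("populationCorrelation must be in [0, 1]")
  if (generator == "poisson") stopifnot(inherits(profile, "rate_profile"))
  if (generator == "csv") stopifnot(!is.null(csv_file))
  structure(list(name = name, generator = generator, profile = profile,
                 correlation = correlation, n_inputs = n_inputs,
                 synapse_density = synapse_density, type = type,
                 conductance = conductance, mod_file = mod_file,
                 parameter_file = parameter_file, csv_file = csv_file),
            class = "input_block_spec")
}

#' Resolve the input target block for a neuron
#'
#' Exactly one target block applies per neuron, the most specific match:
#' neuron id beats morphology key beats neuron type. All channels inside the
#' chosen block apply. No match means no input (empty list), not an error.
#'
#' @param config named list: block name -> list of [input_block_spec()].
#'   Names are neuron ids (digits), morphology keys or type labels.
#' @param neuron_id integer id.
#' @param morphology_key morphology label (e.g. `"dSPN_0"`).
#' @param neuron_type type label (e.g. `"dSPN"`).
#' @return the matched block's channel list (possibly empty).
#' @export
resolve_target_block <- function(config, neuron_id, morphology_key,
                                 neuron_type) {
  nm <- names(config)
  if (is.null(nm)) return(list())
  if (as.character(neuron_id) %in% nm) return(config[[as.character(neuron_id)]])
  if (!is.null(morphology_key) && morphology_key %in% nm)
    return(config[[morphology_key]])
  if (!is.null(neuron_type) && neuron_type %in% nm)
    return(config[[neuron_type]])
  list()
}

#' Place input synapses along the dendrites
#'
#' Locations are sampled along the dendritic cable with linear density
#' proportional to `density(d)` (uniform if `NULL`). With `n_inputs` given
#' the count is exact (density-weighted sampling, the density acting as a
#' shape); with a density only, the count is Poisson with mean
#' `integral(density dl)`.
#'
#' @param m a [morphology] with dendrite.
#' @param n_inputs exact number of inputs, or `NULL`.
#' @param density density expression/function in `d` (micrometres on entry,
#'   see [parse_distance_expression()]); interpreted as inputs per metre of
#'   cable when `n_inputs` is `NULL`.
#' @param rng_seed integer seed.
#' @return data.frame: `section` (node id), `offset` in `[0, 1]`,
#'   `dist_to_soma` (metres).
#' @export
place_input_synapses <- function(m, n_inputs = NULL, density = NULL,
                                 rng_seed = 1L) {
  n <- m$nodes
  prow <- match(n$parent, n$id)
  seg <- segment_lengths(m)
  dists <- node_path_distances(m)
  rows <- which(!is.na(prow) & n$type %in% SWC_DEND)
  if (!length(rows) || sum(seg[rows]) <= 0) stop("no dendritic cable")
  dfun <- parse_distance_expression(density)
  mid <- (dists[prow[rows]] + dists[rows]) / 2
  w <- if (is.null(dfun)) rep(1, length(rows)) else dfun(mid)
  if (any(w < 0)) stop("synapseDensity evaluated negative")
  lin <- w * seg[rows]  # expected inputs per segment (up to scale)
  if (sum(lin) == 0) stop("synapseDensity is zero over the whole dendrite")
  set.seed(rng_seed)
  count <- if (!is.null(n_inputs)) n_inputs else rpois(1, sum(lin))
  if (count == 0)
    return(data.frame(section = integer(), offset = numeric(),
                      dist_to_soma = numeric()))
  pick <- sample(seq_along(rows), count, replace = TRUE, prob = lin)
  off <- runif(count)
  data.frame(section = n$id[rows[pick]], offset = off,
             dist_to_soma = dists[prow[rows[pick]]] + off * seg[rows[pick]])
}

#' Scale the number of input channels of one neuron
#'
#' Excitability scaling: multiplies the channel count by `factor`
#' (rounded). Shrinking keeps a seeded random subset; growing duplicates
#' seeded random choices of existing channels.
#'
#' @param train_set a `spike_train_set` (see [generate_input()]).
#' @param neuron_id target neuron id.
#' @param factor non-negative scale factor.
#' @param rng_seed integer seed.
#' @return the modified train set.
#' @export
scale_inputs <- function(train_set, neuron_id, factor, rng_seed = 1L) {
  if (factor < 0) stop("scale factor must be >= 0")
  key <- as.character(neuron_id)
  ch <- train_set[[key]]
  if (is.null(ch)) return(train_set)
  n_new <- round(length(ch) * factor)
  set.seed(rng_seed)
  train_set[[key]] <-
    if (n_new <= length(ch)) ch[sort(sample.int(length(ch), n_new))]
    else c(ch, ch[sample.int(length(ch), n_new - length(ch), replace = TRUE)])
  train_set
}

#' Read spike trains from a CSV file
#'
#' One train per row (comma- or whitespace-separated times in seconds);
#' empty rows give empty trains; output is sorted.
#'
#' @param path CSV file.
#' @return list of sorted numeric vectors.
#' @export
read_csv_spikes <- function(path) {
  if (!file.exists(path)) stop("CSV spike file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) return(numeric(0))
    v <- suppressWarnings(as.numeric(toks))
    if (anyNA(v)) stop("CSV spike format error at row ", i,
                       ": non-numeric token")
    sort(v)
  })
}

#' Attach prescribed spike trains to virtual neurons
#'
#' Virtual neurons are not simulated; their activity is a given spike train
#' and their detected synapses act as feed-forward input.
#'
#' @param placement a `placement_result`.
#' @param prototype a [neuron_prototype()] with `is_virtual = TRUE`.
#' @param trains list of spike-time vectors, one per placed neuron of the
#'   prototype (recycled if length 1).
#' @return named list: neuron id -> spike times.
#' @export
virtual_neuron_spikes <- function(placement, prototype, trains) {
  if (!isTRUE(prototype$is_virtual))
    stop("spike trains can only drive virtual neurons; '", prototype$name,
         "' is not virtual")
  ids <- placement$neurons$id[placement$neurons$prototype == prototype$name]
  if (!length(ids)) return(list())
  if (length(trains) == 1) trains <- rep(trains, length(ids))
  if (length(trains) != length(ids))
    stop("need ", length(ids), " trains for prototype '", prototype$name,
         "', got ", length(trains))
  stats::setNames(lapply(trains, sort), as.character(ids))
}

#' Generate external input for a placed network
#'
#' For each neuron, resolves the most specific target block, places the
#' requested input synapses on the dendrites and draws one (correlated)
#' spike train per placed input. Per-neuron, per-channel seeds are derived
#' from the master seed, so regenerating one neuron never perturbs others.
#'
#' @param placement a `placement_result`.
#' @param morphologies named list of [morphology] keyed by prototype.
#' @param input_config named list of target blocks (see
#'   [resolve_target_block()]).
#' @param duration seconds of input to generate.
#' @param rng_seed master integer seed.
#' @return a `spike_train_set`: named list (neuron id) of channels, each a
#'   list with `name`, `type`, `spikes` (list per input synapse),
#'   `placements` (from [place_input_synapses()]), `conductance`, metadata.
#' @export
generate_input <- function(placement, morphologies, input_config, duration,
                           rng_seed) {
  nn <- placement$neurons
  out <- list()
  for (i in seq_len(nrow(nn))) {
    blocks <- resolve_target_block(input_config, nn$id[i], nn$prototype[i],
                                   nn$type[i])
    if (!length(blocks)) next
    chans <- list()
    for (b in blocks) {
      seed_i <- derive_seed(rng_seed, paste0("input_", nn$id[i], "_", b$name))
      if (b$generator == "csv") {
        trains <- read_csv_spikes(b$csv_file)
        placements <- place_input_synapses(
          morphologies[[nn$prototype[i]]], n_inputs = length(trains),
          density = b$synapse_density, rng_seed = seed_i)
      } else {
        k <- if (!is.null(b$n_inputs)) b$n_inputs else NULL
        placements <- place_input_synapses(
          morphologies[[nn$prototype[i]]], n_inputs = k,
          density = b$synapse_density, rng_seed = seed_i)
        trains <- if (nrow(placements) == 0) list() else
          correlated_trains(nrow(placements), b$profile, b$correlation,
                            duration, seed_i + 1L)
      }
      chans[[b$name]] <- list(name = b$name, type = b$type, spikes = trains,
                              placements = placements,
                              conductance = b$conductance,
                              mod_file = b$mod_file,
                              parameter_file = b$parameter_file)
    }
    if (length(chans)) out[[as.character(nn$id[i])]] <- chans
  }
  structure(out, class = "spike_train_set", duration = duration)
}
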