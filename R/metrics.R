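## Connectivity statistics for comparing generated networks against
## experimental summaries: distance-resolved connection probability,
## synapses-per-pair and connected-neighbour histograms, synapse density.

#' Connection probability as a function of soma-soma distance
#'
#' All directed (pre, post) pairs of the requested types are binned by 3D
#' soma-centre distance; a pair is connected if it has at least one synapse.
#'
#' @param placement a `placement_result`.
#' @param synapses synapse table (columns `pre`, `post`).
#' @param pre_type,post_type neuron type labels (`NULL` = any).
#' @param bin_width distance bin, metres (default 10 um).
#' @return data.frame: `bin_lo`, `bin_hi` (metres), `connected`, `total`,
#'   `probability`.
#' @export
connection_probability_vs_distance <- function(placement, synapses,
                                               pre_type = NULL,
                                               post_type = NULL,
                                               bin_width = 10e-6) {
  stopifnot(bin_width > 0)
  nn <- placement$neurons
  pre_ids <- nn$id[if (is.null(pre_type)) TRUE else nn$type == pre_type]
  post_ids <- nn$id[if (is.null(post_type)) TRUE else nn$type == post_type]
  if (!length(pre_ids) || !length(post_ids))
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      connected = integer(), total = integer(),
                      probability = numeric()))
  g <- expand.grid(pre = pre_ids, post = post_ids)
  g <- g[g$pre != g$post, ]
  pi_ <- match(g$pre, nn$id); po <- match(g$post, nn$id)
  d <- sqrt((nn$x[pi_] - nn$x[po])^2 + (nn$y[pi_] - nn$y[po])^2 +
              (nn$z[pi_] - nn$z[po])^2)
  conn_key <- unique(paste(synapses$pre, synapses$post, sep = "_"))
  is_conn <- paste(g$pre, g$post, sep = "_") %in% conn_key
  nb <- max(1L, ceiling(max(d) / bin_width + 1e-12))
  idx <- pmin(pmax(ceiling(d / bin_width), 1L), nb)
  total <- tabulate(idx, nbins = nb)
  connected <- tabulate(idx[is_conn], nbins = nb)
  data.frame(bin_lo = (seq_len(nb) - 1) * bin_width,
             bin_hi = seq_len(nb) * bin_width,
             connected = connected, total = total,
             probability = ifelse(total > 0, connected / total, NA_real_))
}

#' Histogram of synapse counts between connected pairs
#'
#' @param synapses synapse table (columns `pre`, `post`).
#' @return table: synapse count (connected pairs only) -> number of pairs.
#' @export
synapses_per_pair_histogram <- function(synapses) {
  if (!nrow(synapses)) return(table(integer(0)))
  table(table(paste(synapses$pre, synapses$post, sep = "_")))
}

#' Histogram of connected presynaptic neighbours per postsynaptic neuron
#'
#' Counts distinct presynaptic partners for every neuron of the target type
#' (isolated neurons count at 0); histogram totals equal the number of
#' postsynaptic neurons.
#'
#' @param placement a `placement_result`.
#' @param synapses synapse table.
#' @param post_type type label (`NULL` = all neurons).
#' @return table: in-degree -> neuron count.
#' @export
connected_neighbours_histogram <- function(placement, synapses,
                                           post_type = NULL) {
  nn <- placement$neurons
  ids <- nn$id[if (is.null(post_type)) TRUE else nn$type == post_type]
  deg <- vapply(ids, function(i)
    length(unique(synapses$pre[synapses$post == i])), integer(1))
  table(factor(deg, levels = sort(unique(deg))))
}

#' Synapse density
#'
#' @param synapses synapse table or a synapse count.
#' @param volume_mm3 volume in cubic millimetres (> 0).
#' @return synapses per mm^3.
#' @export
synapse_density <- function(synapses, volume_mm3) {
  stopifnot(volume_mm3 > 0)
  n <- if (is.data.frame(synapses)) nrow(synapses) else as.numeric(synapses)
  n / volume_mm3
}
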