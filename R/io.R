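#' Read an experiment configuration file
#'
#' Loads a YAML (or JSON) configuration and builds the corresponding
#' [network_config()] and [ga_config()] objects.  Recognized top-level
#' blocks: `network` (fields of [network_config()] except the cell list),
#' `synapse` (fields of [synapse_params()]), `izhikevich` (fields of
#' [izhikevich_params()]) and `ga` (fields of [ga_config()]).  Missing
#' fields keep their defaults.
#'
#' @param path file path.
#' @return List with `network` and `ga` configuration objects.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  syn <- do.call(synapse_params, as.list(raw$synapse))
  izh <- do.call(izhikevich_params, as.list(raw$izhikevich))
  net_args <- as.list(raw$network)
  net_args$synapse <- syn
  net_args$izh <- izh
  net <- do.call(network_config, net_args)
  ga <- do.call(ga_config, as.list(raw$ga))
  list(network = net, ga = ga)
}

#' Write a voltage trace as CSV
#'
#' Two columns: `time_ms`, `Vm_mV`.
#'
#' @param trace a `voltage_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_voltage_csv <- function(trace, path) {
  write.csv(data.frame(time_ms = trace$t_ms, Vm_mV = trace$Vm_mV),
            path, row.names = FALSE)
  invisible(path)
}

#' Write network rasters as CSV
#'
#' Long format: one row per spike with `layer` (0 = input), `neuron_id`
#' (within layer) and `spike_time_ms`.
#'
#' @param response a `network_response`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(response, path) {
  rows <- list()
  add <- function(layer, trains) {
    for (j in seq_along(trains))
      if (length(trains[[j]]))
        rows[[length(rows) + 1]] <<- data.frame(layer = layer,
                                                neuron_id = j,
                                                spike_time_ms = trains[[j]])
  }
  add(0L, response$input_trains)
  for (l in seq_along(response$rasters)) add(l, response$rasters[[l]])
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(layer = integer(0), neuron_id = integer(0),
                        spike_time_ms = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a binary output pattern as CSV
#'
#' Dense `k x m` 0/1 matrix, one row per time bin.
#'
#' @param pattern binary matrix as returned in a `network_response`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pattern_csv <- function(pattern, path) {
  utils::write.table(pattern, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Export a fitness history as CSV
#'
#' @param result a `gust_evolution` object from [evolve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(result, path) {
  write.csv(data.frame(generation = seq_along(result$history) - 1,
                       best_fitness = result$history),
            path, row.names = FALSE)
  invisible(path)
}

#' Export the best genome as JSON
#'
#' @param result a `gust_evolution` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_json <- function(result, path) {
  g <- as_genome(result$best_network$W)
  jsonlite::write_json(list(n_total = g$n_total, phos = g$phos), path,
                       digits = NA)
  invisible(path)
}
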