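#' Serialize a network to a directory
#'
#' Writes `neurons.csv` (id, pop, x, y, z, microcomplex), `synapses.csv`
#' (columnar pre, post, row, weight, delay, tau_alpha, erev, sign) and
#' `meta.json` (counts, volumes, placement parameters, seeds).
#'
#' @param network An `ocsnn_network`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(network$neurons, file.path(dir, "neurons.csv"))
  data.table::fwrite(network$synapses, file.path(dir, "synapses.csv"))
  meta <- list(counts = as.list(network$counts),
               volumes = lapply(network$volumes, function(v) {
                 list(origin = v$origin, extent = v$extent)
               }),
               placement = network$placement,
               seeds = network$seeds)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  data.table::fwrite(network$table, file.path(dir, "connection_table.csv"))
  invisible(dir)
}

#' Load a serialized network
#' @param dir Directory written by [write_network()].
#' @return An `ocsnn_network`.
#' @export
read_network <- function(dir) {
  neurons <- as.data.frame(data.table::fread(file.path(dir, "neurons.csv")))
  synapses <- data.table::fread(file.path(dir, "synapses.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  vols <- lapply(names(meta$volumes), function(nm) {
    volume_spec(nm, meta$volumes[[nm]]$origin, meta$volumes[[nm]]$extent)
  })
  names(vols) <- names(meta$volumes)
  tab <- as.data.frame(data.table::fread(file.path(dir,
                                                   "connection_table.csv")))
  counts <- unlist(meta$counts)
  structure(list(neurons = neurons, synapses = synapses,
                 counts = counts[POP_ORDER], volumes = vols, table = tab,
                 placement = meta$placement, seeds = meta$seeds),
            class = "ocsnn_network")
}

#' Write a spike record to CSV
#'
#' Columnar `neuron_id, time_ms, population, microcomplex`; one file, or one
#' file per population when `per_population` is set.
#'
#' @param spikes Spike data.table from [run_simulation()].
#' @param path File path (or directory when `per_population`).
#' @param per_population Split by population.
#' @return Written path(s), invisibly.
#' @export
write_spikes <- function(spikes, path, per_population = FALSE) {
  out <- data.table::data.table(neuron_id = spikes$id, time_ms = spikes$time,
                                population = spikes$pop,
                                microcomplex = spikes$microcomplex)
  if (!per_population) {
    data.table::fwrite(out, path)
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(POP_ORDER, function(p) {
    f <- file.path(path, paste0("spikes_", p, ".csv"))
    data.table::fwrite(out[out$population == p, ], f)
    f
  }, "")
  invisible(files)
}

#' Read a spike record written by [write_spikes()]
#' @param path CSV path.
#' @return Spike data.table with `id`, `time`, `pop`, `microcomplex`.
#' @export
read_spikes <- function(path) {
  d <- data.table::fread(path)
  data.table::data.table(id = d$neuron_id, time = d$time_ms,
                         pop = d$population, microcomplex = d$microcomplex)
}
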