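#' Default run configuration
#'
#' A fully populated, serializable configuration carrying the default census,
#' layer volumes, connection table, stimulation protocol, analysis settings,
#' and the four independent seed streams (placement, connectivity,
#' initialization, simulation — so structural and dynamical stochasticity stay
#' separable).
#'
#' @param model "eglif" or "lif".
#' @return A `run_config` list.
#' @export
default_config <- function(model = "eglif") {
  vols <- default_volumes()
  structure(list(
    network = list(
      counts = as.list(default_counts()),
      volumes = lapply(vols, function(v) {
        list(origin = v$origin, extent = v$extent)
      }),
      placement = placement_params(),
      connection_table = connection_table()
    ),
    neurons = list(model = model, params_file = NULL),
    protocol = list(baseline_rate = 4, cs_rate = 40, us_rate = 500,
                    baseline_end = 1000, cs_end = 1260, us_duration = 10,
                    post = 500,
                    bundle = list(center = c(200, 200), radius = 150,
                                  height = 150),
                    us_microcomplex = 1L),
    analysis = list(psth_bin = 5, sigma_pc = 5, sigma_dcnp = 10,
                    cf_onset = 1250,
                    decoder = list(update = 1.0, tau_decay = 10,
                                   ma_window = 50, mode = "sum")),
    seeds = list(placement = 1L, connectivity = 2L, initialization = 3L,
                 simulation = 4L)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks population counts, volume extents, that every connection-table row
#' appears exactly once, the model switch, and seed integrality, before any
#' computation starts.
#'
#' @param config A `run_config`.
#' @return The config, invisibly; errors describe the violated field.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  cts <- unlist(config$network$counts)
  if (!setequal(names(cts), POP_ORDER)) {
    stop("config counts must name exactly the populations ",
         paste(POP_ORDER, collapse = ", "))
  }
  if (any(cts < 0)) stop("population counts must be >= 0")
  for (v in config$network$volumes) {
    if (any(unlist(v$extent) <= 0)) stop("volume extents must be positive")
  }
  tab <- config$network$connection_table
  ref <- connection_table()$name
  if (any(duplicated(tab$name))) stop("duplicated connection-table rows")
  if (!setequal(tab$name, ref)) {
    stop("connection table must contain every connection row exactly once; ",
         "missing/extra: ",
         paste(c(setdiff(ref, tab$name), setdiff(tab$name, ref)),
               collapse = ", "))
  }
  if (any(tab$weight <= 0) || any(tab$tau_alpha <= 0)) {
    stop("connection weights and tau_alpha must be positive")
  }
  if (!config$neurons$model %in% c("eglif", "lif")) {
    stop("neurons$model must be 'eglif' or 'lif'")
  }
  sds <- unlist(config$seeds)
  if (length(sds) != 4 || any(sds != round(sds))) {
    stop("seeds must be four integers (placement, connectivity, ",
         "initialization, simulation)")
  }
  invisible(config)
}

#' Write / read a configuration as YAML
#'
#' The connection table is stored as a list of row records; round-tripping
#' preserves semantics exactly.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `write_config` returns the path invisibly; `read_config` the parsed
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  tab <- cfg$network$connection_table
  cfg$network$connection_table <- lapply(seq_len(nrow(tab)), function(i) {
    as.list(tab[i, ])
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rows <- lapply(cfg$network$connection_table, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  cfg$network$connection_table <- do.call(rbind, rows)
  cfg$seeds <- lapply(cfg$seeds, as.integer)
  cfg$network$counts <- lapply(cfg$network$counts, as.integer)
  validate_config(structure(cfg, class = "run_config"))
  structure(cfg, class = "run_config")
}

config_volumes <- function(config) {
  vs <- config$network$volumes
  out <- lapply(names(vs), function(nm) {
    volume_spec(nm, unlist(vs[[nm]]$origin), unlist(vs[[nm]]$extent))
  })
  names(out) <- names(vs)
  out
}

config_protocol <- function(config) {
  p <- config$protocol
  ebcc_protocol(baseline_rate = p$baseline_rate, cs_rate = p$cs_rate,
                us_rate = p$us_rate, baseline_end = p$baseline_end,
                cs_end = p$cs_end, us_duration = p$us_duration,
                post = p$post,
                bundle = list(center = unlist(p$bundle$center),
                              radius = p$bundle$radius,
                              height = p$bundle$height),
                us_microcomplex = p$us_microcomplex)
}
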