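#' Alpha conductance kernel
#'
#' `g(t) = w (t/tau) exp(1 - t/tau)` for `t >= 0`, else 0: zero at the spike,
#' peak exactly `w` at `t = tau`, total area `w tau e`. Synaptic conductances
#' superpose linearly across spikes.
#'
#' @param t Time since spike delivery, ms (vectorized).
#' @param w Peak conductance, nS.
#' @param tau Kernel time constant, ms.
#' @return Conductance, nS.
#' @export
alpha_kernel <- function(t, w, tau) {
  ifelse(t >= 0, w * (t / tau) * exp(1 - t / tau), 0)
}

#' Simulate the network
#'
#' Clock-driven simulation at resolution `dt`: all neurons advance in lockstep
#' by their exact subthreshold propagator; the synaptic current on each neuron
#' is `sum_receptors g(t) (E_rev - V_m)`; spikes are routed through per-row
#' delay queues (delays rounded to the nearest step, minimum one). One alpha
#' filter is kept per (connection row, postsynaptic neuron), exploiting kernel
#' linearity. Mossy fibers are external spike sources; the unconditioned
#' stimulus is injected by forcing spikes of the targeted inferior-olive
#' neurons so that both climbing-fiber pathways (to Purkinje cells and, with
#' spillover delays, to molecular-layer interneurons) carry it.
#'
#' Everything stochastic (membrane-potential initialization, stimulus spike
#' trains, escape-noise spiking) is drawn from the single RNG stream seeded by
#' `seed`, so identical arguments reproduce an identical spike record.
#'
#' @param network An `ocsnn_network`.
#' @param params Per-population parameter table ([default_neuron_params()]).
#' @param protocol A stimulation protocol ([ebcc_protocol()]).
#' @param model "eglif" or "lif" for all dynamic populations.
#' @param T Duration, ms (defaults to the protocol duration).
#' @param dt Resolution, ms.
#' @param seed Integer seed.
#' @param init_vm Optional explicit initial membrane potentials (global
#'   order); by default drawn uniformly between each population's `E_L` and
#'   `V_th`.
#' @param record_vm Global ids whose membrane trajectory is recorded.
#' @return A data.table of spikes (`id`, `time`, `pop`, `microcomplex`), with
#'   the membrane record (if any) in attribute `vm` and the realized stimulus
#'   in attribute `stimulus`.
#' @export
run_simulation <- function(network, params, protocol, model = "eglif",
                           T = NULL, dt = 1, seed = 1L, init_vm = NULL,
                           record_vm = integer(0)) {
  if (is.null(T)) T <- protocol$duration
  stopifnot(abs(T / dt - round(T / dt)) < 1e-9)
  set.seed(seed)
  stim <- realize_protocol(network, protocol, dt)
  if (is.null(init_vm)) {
    init_vm <- init_membrane_potentials(network, params)
  }
  pidx <- population_index(network)
  pop_of <- match(network$neurons$pop, pidx$pops) - 1L
  pm <- params_matrix(params, model)

  syn <- network$synapses
  if (is.null(syn) || nrow(syn) == 0L) stop("network has no synapses")
  tab <- network$table
  row_id <- match(syn$row, tab$name)
  if (anyNA(row_id)) stop("synapse table references unknown connection rows")
  ord <- order(syn$pre)
  src_ptr <- c(0L, cumsum(tabulate(syn$pre, nbins = nrow(network$neurons))))
  delay_steps <- pmax(1L, as.integer(round(syn$delay / dt)))
  res <- .simulate_network_cpp(
    pop_of, pm, as.integer(pidx$offset), as.integer(pidx$size),
    as.integer(src_ptr),
    as.integer(syn$post[ord] - 1L), as.integer(row_id[ord] - 1L),
    as.numeric(syn$weight[ord]), delay_steps[ord],
    match(tab$post, pidx$pops) - 1L, as.numeric(tab$tau_alpha),
    as.numeric(tab$erev),
    as.integer(stim$ext$id - 1L), as.integer(stim$ext$step),
    as.integer(stim$forced$id - 1L), as.integer(stim$forced$step),
    as.numeric(init_vm), T, dt, as.integer(record_vm - 1L))

  spikes <- data.table::data.table(id = res$id + 1L, time = res$time)
  data.table::setorder(spikes, time, id)
  spikes$pop <- network$neurons$pop[spikes$id]
  spikes$microcomplex <- network$neurons$microcomplex[spikes$id]
  attr(spikes, "vm") <- res$vm
  attr(spikes, "g") <- res$g
  attr(spikes, "stimulus") <- stim
  attr(spikes, "T") <- T
  attr(spikes, "dt") <- dt
  spikes
}
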