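#' Eyeblink-conditioning style stimulation protocol
#'
#' Default schedule: a 1-s baseline phase with 4-Hz Poisson input to all mossy
#' fibers (in vivo background noise); a conditioned stimulus (light) as a
#' 40-Hz Poisson train on a cylindrical mossy-fiber bundle over
#' `[1000, 1260)` ms; an unconditioned stimulus (air puff) as a 500-Hz regular
#' burst over the final 10 ms (`[1250, 1260)`, co-terminating with the
#' conditioned stimulus) forcing the inferior-olive neurons of one
#' microcomplex; then 500 ms of silence to check return to rest. Total
#' 1760 ms.
#'
#' @param baseline_rate,cs_rate Poisson rates, Hz.
#' @param us_rate Burst rate, Hz (regular train).
#' @param baseline_end Baseline duration, ms.
#' @param cs_end End of the conditioned stimulus, ms.
#' @param us_duration Burst length, ms.
#' @param post Silent tail, ms.
#' @param bundle Cylinder of the mossy-fiber bundle: `center` (x, z um),
#'   `radius`, `height` (um).
#' @param us_microcomplex Which microcomplex's IO cells receive the burst.
#' @return A `stimulus_protocol` list with a `phases` data.frame and
#'   `duration`.
#' @export
ebcc_protocol <- function(baseline_rate = 4, cs_rate = 40, us_rate = 500,
                          baseline_end = 1000, cs_end = 1260,
                          us_duration = 10, post = 500,
                          bundle = list(center = c(200, 200), radius = 150,
                                        height = 150),
                          us_microcomplex = 1L) {
  phases <- data.frame(
    t_start = c(0, baseline_end, cs_end - us_duration),
    t_end = c(baseline_end, cs_end, cs_end),
    kind = c("poisson", "poisson", "burst"),
    rate = c(baseline_rate, cs_rate, us_rate),
    target = c("MF_all", "MF_bundle", "IO_us"))
  structure(list(phases = phases, duration = cs_end + post, bundle = bundle,
                 us_microcomplex = as.integer(us_microcomplex)),
            class = "stimulus_protocol")
}

#' Select the mossy-fiber bundle inside a cylinder
#'
#' The cylinder stands on the transversal x-z plane (default: centered, basis
#' radius 150 um) and spans `height` um of the granular layer depth.
#'
#' @param network An `ocsnn_network`.
#' @param center Cylinder center in the x-z plane, um.
#' @param radius Basis radius, um.
#' @param height Cylinder height along the depth axis, um.
#' @return Integer global ids of the selected mossy fibers; the selected
#'   fraction is attached as attribute `fraction`. An empty selection warns.
#' @export
select_mf_bundle <- function(network, center = c(200, 200), radius = 150,
                             height = 150) {
  nn <- network$neurons
  mf <- nn[nn$pop == "MF", ]
  gran <- network$volumes$granular
  in_circle <- (mf$x - center[1])^2 + (mf$z - center[2])^2 <= radius^2
  in_height <- mf$y >= gran$origin[2] & mf$y <= gran$origin[2] + height
  sel <- mf$id[in_circle & in_height]
  if (length(sel) == 0L) warning("empty mossy-fiber bundle selection")
  structure(sel, fraction = length(sel) / max(1L, nrow(mf)))
}

#' Homogeneous Poisson spike train
#'
#' @param rate Rate, Hz (>= 0).
#' @param t0,t1 Window, ms (`t1 > t0`); spikes fall in `[t0, t1)`.
#' @param seed Optional integer seed.
#' @return Sorted spike times, ms.
#' @export
poisson_train <- function(rate, t0, t1, seed = NULL) {
  if (rate < 0) stop("rate must be >= 0")
  stopifnot(t1 > t0)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate * (t1 - t0) / 1000)
  sort(stats::runif(n, t0, t1))
}

#' Regular high-frequency burst
#'
#' Deterministic train at interval `1000/rate` ms starting at `t0`; the last
#' spike falls strictly before `t1`.
#'
#' @param rate Rate, Hz (> 0).
#' @param t0,t1 Window, ms.
#' @param dt Simulation resolution, ms (the interval must not fall below it).
#' @return Spike times, ms.
#' @export
burst_train <- function(rate, t0, t1, dt = 1) {
  stopifnot(rate > 0, t1 > t0)
  interval <- 1000 / rate
  if (interval < dt) {
    stop("burst interval ", interval, " ms below the simulation resolution ",
         dt, " ms")
  }
  n <- ceiling((t1 - t0) / interval - 1e-9)
  t0 + (seq_len(n) - 1) * interval
}

#' Randomized membrane-potential initialization
#'
#' Every dynamic neuron starts at a uniform random potential between its
#' population's resting and threshold potential (identical rule for EGLIF and
#' LIF networks), avoiding artificial spike synchronization at onset.
#'
#' @param network An `ocsnn_network`.
#' @param params Parameter table ([default_neuron_params()]).
#' @param seed Optional integer seed.
#' @return Numeric vector of initial potentials in global order (0 for
#'   external sources).
#' @export
init_membrane_potentials <- function(network, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nn <- network$neurons
  v0 <- numeric(nrow(nn))
  for (p in setdiff(POP_ORDER, "MF")) {
    idx <- which(nn$pop == p)
    if (!length(idx)) next
    r <- params[params$pop == p, ]
    if (r$V_th < r$E_L) stop("population ", p, ": V_th below E_L")
    v0[idx] <- stats::runif(length(idx), r$E_L, r$V_th)
  }
  v0
}

#' Realize a protocol into engine spike trains
#'
#' Draws the Poisson trains per targeted mossy fiber and lays out the forced
#' burst steps for the unconditioned-stimulus IO neurons. Uses the current RNG
#' stream.
#'
#' @param network An `ocsnn_network`.
#' @param protocol A `stimulus_protocol`.
#' @param dt Resolution, ms.
#' @return List with data.tables `ext` (id, step) sorted by step and `forced`
#'   (id, step).
#' @export
realize_protocol <- function(network, protocol, dt = 1) {
  nn <- network$neurons
  mf_all <- nn$id[nn$pop == "MF"]
  io_us <- nn$id[nn$pop == "IO" &
                   nn$microcomplex == protocol$us_microcomplex]
  bundle <- select_mf_bundle(network, center = protocol$bundle$center,
                             radius = protocol$bundle$radius,
                             height = protocol$bundle$height)
  ext <- list()
  forced <- list()
  for (i in seq_len(nrow(protocol$phases))) {
    ph <- protocol$phases[i, ]
    targets <- switch(ph$target,
                      MF_all = mf_all,
                      MF_bundle = as.integer(bundle),
                      IO_us = io_us,
                      stop("unknown protocol target: ", ph$target))
    if (ph$kind == "poisson") {
      # one homogeneous Poisson train per target, drawn in bulk
      n <- stats::rpois(length(targets),
                        ph$rate * (ph$t_end - ph$t_start) / 1000)
      if (sum(n) > 0) {
        tt <- stats::runif(sum(n), ph$t_start, ph$t_end)
        ext[[length(ext) + 1L]] <- data.table::data.table(
          id = rep(targets, n), step = as.integer(floor(tt / dt)))
      }
    } else if (ph$kind == "burst") {
      tt <- burst_train(ph$rate, ph$t_start, ph$t_end, dt)
      for (id in targets) {
        forced[[length(forced) + 1L]] <-
          data.table::data.table(id = id, step = as.integer(round(tt / dt)))
      }
    } else {
      stop("unknown phase kind: ", ph$kind)
    }
  }
  bind <- function(x) {
    if (length(x) == 0L) {
      return(data.table::data.table(id = integer(0), step = integer(0)))
    }
    d <- data.table::rbindlist(x)
    data.table::setorder(d, step, id)
    d
  }
  list(ext = bind(ext), forced = bind(forced))
}
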