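#' Peristimulus time histogram of a population
#'
#' Population rate per bin: spike count / (number of neurons x bin width in
#' seconds).
#'
#' @param spikes Spike data.table from [run_simulation()] (or any data.frame
#'   with `time` and `pop`).
#' @param population Population name.
#' @param n_neurons Number of neurons in the population (inferred from
#'   `network` if given).
#' @param network Optional `ocsnn_network` used to infer `n_neurons` and
#'   microcomplex membership.
#' @param bin Bin width, ms.
#' @param window Two-vector time range, ms (defaults to the spike record's).
#' @param microcomplex Optional microcomplex filter (1 or 2).
#' @return Data.frame with bin start `time` (ms) and population `rate` (Hz).
#' @export
psth <- function(spikes, population, n_neurons = NULL, network = NULL,
                 bin = 5, window = NULL, microcomplex = NULL) {
  stopifnot(bin > 0)
  sel <- spikes$pop == population
  if (!is.null(microcomplex)) sel <- sel & spikes$microcomplex == microcomplex
  if (is.null(n_neurons)) {
    if (is.null(network)) stop("provide n_neurons or network")
    keep <- network$neurons$pop == population
    if (!is.null(microcomplex)) {
      keep <- keep & network$neurons$microcomplex == microcomplex
    }
    n_neurons <- sum(keep)
  }
  if (n_neurons == 0L) stop("empty population: ", population)
  if (is.null(window)) {
    window <- c(0, attr(spikes, "T") %||% max(spikes$time, 0))
  }
  edges <- seq(window[1], window[2], by = bin)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  tt <- spikes$time[sel & spikes$time >= window[1] & spikes$time < window[2]]
  counts <- tabulate(findInterval(tt, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  widths <- diff(edges)
  data.frame(time = edges[-length(edges)],
             rate = counts / (n_neurons * widths / 1000))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian-kernel instantaneous firing rate
#'
#' Convolution of the spike train with a unit-area Gaussian of width `sigma`,
#' evaluated on `grid` and expressed in Hz. Kernels are truncated at four
#' sigma and renormalized by the kernel mass inside the trace support, so the
#' trace integrates to the spike count.
#'
#' @param spike_times Spike times, ms.
#' @param sigma Kernel width, ms (> 0).
#' @param grid Evaluation grid, ms (regular).
#' @return A `rate_trace`: list with `time`, `rate` (Hz), `sigma`.
#' @export
instantaneous_rate <- function(spike_times, sigma, grid) {
  stopifnot(sigma > 0, length(grid) >= 2)
  rate <- numeric(length(grid))
  lo <- grid[1]
  hi <- grid[length(grid)]
  for (s in spike_times) {
    mass <- stats::pnorm(min(hi, s + 4 * sigma), s, sigma) -
      stats::pnorm(max(lo, s - 4 * sigma), s, sigma)
    if (mass <= 0) next
    i <- which(abs(grid - s) <= 4 * sigma)
    rate[i] <- rate[i] + stats::dnorm(grid[i], s, sigma) / mass
  }
  structure(list(time = grid, rate = rate * 1000, sigma = sigma),
            class = "rate_trace")
}

#' Response speed after the climbing-fiber burst
#'
#' Locates the maximum and minimum of a rate trace inside the 100-ms window
#' starting 5 ms after the burst onset and returns
#' `speed = (max_rate - min_rate) / (t_max - t_min)` (Hz/ms). The sign is
#' carried by the order of the extrema: negative when the maximum precedes the
#' minimum (burst-then-pause), positive when the minimum comes first
#' (pause-then-burst). A flat trace gives 0 by convention.
#'
#' @param trace A `rate_trace` (or list with `time` and `rate`).
#' @param cf_onset Burst onset, ms.
#' @param window_offset,window_length Analysis window definition, ms.
#' @return List: `speed` (Hz/ms), `max_rate`, `min_rate`, `t_max`, `t_min`.
#' @export
response_speed <- function(trace, cf_onset, window_offset = 5,
                           window_length = 100) {
  t0 <- cf_onset + window_offset
  t1 <- t0 + window_length
  if (min(trace$time) > t0 || max(trace$time) < t1) {
    stop("trace does not cover the analysis window [", t0, ", ", t1, "] ms")
  }
  i <- which(trace$time >= t0 & trace$time <= t1)
  r <- trace$rate[i]
  tt <- trace$time[i]
  imax <- which.max(r)
  imin <- which.min(r)
  if (r[imax] == r[imin]) {
    return(list(speed = 0, max_rate = r[imax], min_rate = r[imin],
                t_max = tt[imax], t_min = tt[imin]))
  }
  list(speed = (r[imax] - r[imin]) / (tt[imax] - tt[imin]),
       max_rate = r[imax], min_rate = r[imin],
       t_max = tt[imax], t_min = tt[imin])
}

#' Per-neuron response speeds of a population
#'
#' Builds each neuron's Gaussian-kernel rate trace and applies
#' [response_speed()].
#'
#' @param spikes Spike record from [run_simulation()].
#' @param network The network the spikes came from.
#' @param population Population name ("PC" or "DCNp" in the analyses here).
#' @param microcomplex Microcomplex filter (default 1, the one receiving the
#'   burst).
#' @param cf_onset Burst onset, ms.
#' @param sigma Kernel width, ms (5 for Purkinje cells, 10 for nuclear
#'   projection neurons).
#' @param dt Grid resolution, ms.
#' @return Data.frame with one row per neuron: `id`, `speed`, extrema.
#' @export
population_speeds <- function(spikes, network, population,
                              microcomplex = 1L, cf_onset = 1250,
                              sigma = if (population == "PC") 5 else 10,
                              dt = 1) {
  nn <- network$neurons
  ids <- nn$id[nn$pop == population & nn$microcomplex == microcomplex]
  if (length(ids) == 0L) {
    return(data.frame(id = integer(0), speed = numeric(0),
                      max_rate = numeric(0), min_rate = numeric(0),
                      t_max = numeric(0), t_min = numeric(0)))
  }
  grid <- seq(max(0, cf_onset - 100), cf_onset + 120, by = dt)
  out <- lapply(ids, function(i) {
    st <- spikes$time[spikes$id == i]
    tr <- instantaneous_rate(st, sigma, grid)
    sp <- response_speed(tr, cf_onset)
    data.frame(id = i, speed = sp$speed, max_rate = sp$max_rate,
               min_rate = sp$min_rate, t_max = sp$t_max, t_min = sp$t_min)
  })
  do.call(rbind, out)
}

#' Two-sample comparison of response speeds
#'
#' Welch two-sample t-test on per-neuron speeds.
#'
#' @param speeds_a,speeds_b Numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p`, and the two group means. Degenerate
#'   (zero-variance) input is reported via `degenerate = TRUE` with `p = NA`,
#'   not raised.
#' @export
compare_speeds <- function(speeds_a, speeds_b) {
  stopifnot(length(speeds_a) >= 2, length(speeds_b) >= 2)
  if (stats::sd(speeds_a) == 0 && stats::sd(speeds_b) == 0) {
    same <- isTRUE(all.equal(mean(speeds_a), mean(speeds_b)))
    return(list(t = if (same) 0 else Inf, df = NA_real_,
                p = if (same) 1 else NA_real_,
                mean_a = mean(speeds_a), mean_b = mean(speeds_b),
                degenerate = TRUE))
  }
  ht <- stats::t.test(speeds_a, speeds_b)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(speeds_a), mean_b = mean(speeds_b),
       degenerate = FALSE)
}

#' Decode the eyeblink response from nuclear output spikes
#'
#' Each microcomplex's DCNp spike train is decoded with an update-and-decay
#' rule (update constant 1.0 per spike, exponential decay with a 10-ms time
#' constant), smoothed with a 50-sample moving average, and the net response
#' combines the two microcomplexes (default: baseline-subtracted sum;
#' alternatively their difference).
#'
#' @param spike_times List of two numeric vectors: DCNp spike times (ms) of
#'   microcomplex 1 and 2.
#' @param dt Sample interval, ms.
#' @param T Trace duration, ms.
#' @param update Update constant per spike.
#' @param tau_decay Decay time constant, ms.
#' @param ma_window Moving-average window, samples.
#' @param mode "sum" (baseline-subtracted sum) or "diff" (microcomplex 1
#'   minus 2).
#' @param baseline_window Window used for baseline subtraction, ms.
#' @return List: `time`, `decoded` (2-column matrix, pre-smoothing),
#'   `filtered` (2-column matrix), `net`.
#' @export
decode_eyeblink <- function(spike_times, dt = 1, T = NULL, update = 1.0,
                            tau_decay = 10, ma_window = 50,
                            mode = c("sum", "diff"),
                            baseline_window = c(500, 1000)) {
  mode <- match.arg(mode)
  stopifnot(length(spike_times) == 2)
  if (is.null(T)) T <- max(unlist(spike_times), 0) + dt
  n <- as.integer(ceiling(T / dt))
  time <- (seq_len(n) - 1L) * dt
  dec <- matrix(0, n, 2)
  decay <- exp(-dt / tau_decay)
  for (m in 1:2) {
    counts <- tabulate(pmin(n, floor(spike_times[[m]] / dt) + 1L), nbins = n)
    s <- 0
    for (k in seq_len(n)) {
      s <- s * decay + update * counts[k]
      dec[k, m] <- s
    }
  }
  flt <- apply(dec, 2, function(x) {
    as.numeric(stats::filter(x, rep(1 / ma_window, ma_window), sides = 1))
  })
  flt[is.na(flt)] <- 0
  if (mode == "diff") {
    net <- flt[, 1] - flt[, 2]
  } else {
    bw <- time >= baseline_window[1] & time < baseline_window[2]
    base <- if (any(bw)) colMeans(flt[bw, , drop = FALSE]) else c(0, 0)
    net <- (flt[, 1] - base[1]) + (flt[, 2] - base[2])
  }
  list(time = time, decoded = dec, filtered = flt, net = net)
}
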