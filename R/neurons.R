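#' EGLIF parameter set
#'
#' Extended generalized leaky integrate-and-fire point neuron: a leaky
#' membrane coupled to a spike-triggered adaptation current `I_adap`
#' (`dI_adap/dt = k_adap (V - E_L) - k_2 I_adap`, incremented by `A_2` at each
#' spike) and a spike-triggered depolarizing current `I_dep`
#' (`dI_dep/dt = -k_1 I_dep`, set to `A_1` at each spike), with stochastic
#' spike emission from an exponential escape rate
#' `lambda(V) = lambda_0 exp((V - V_th)/delta_V)` (the firing-irregularity
#' parameters). The voltage coupling of `I_adap` yields rebound responses:
#' hyperpolarization drives `I_adap` negative, which depolarizes once
#' inhibition ceases.
#'
#' @param C_m Membrane capacitance, pF.
#' @param tau_m Membrane time constant, ms.
#' @param E_L Resting (leak reversal) potential, mV.
#' @param V_th Spike threshold, mV.
#' @param V_r Reset potential, mV (must be <= `V_th`).
#' @param t_ref Absolute refractory period, ms.
#' @param I_e Endogenous (pacemaking) current, pA.
#' @param k_adap Adaptation voltage coupling, pA/(mV ms).
#' @param k_2 Adaptation decay rate, 1/ms.
#' @param k_1 Depolarizing-current decay rate, 1/ms.
#' @param A_1 Depolarizing current set at each spike, pA.
#' @param A_2 Adaptation increment at each spike, pA.
#' @param lambda_0 Escape rate at threshold, Hz.
#' @param delta_V Escape-noise voltage sensitivity, mV (> 0).
#' @return An `eglif_params` list.
#' @export
eglif_params <- function(C_m, tau_m, E_L, V_th, V_r, t_ref, I_e = 0,
                         k_adap = 0, k_2 = 0, k_1 = 0, A_1 = 0, A_2 = 0,
                         lambda_0 = 1000, delta_V = 1) {
  stopifnot(C_m > 0, tau_m > 0, t_ref > 0, delta_V > 0)
  if (V_r > V_th) stop("V_r must be <= V_th")
  structure(list(C_m = C_m, tau_m = tau_m, E_L = E_L, V_th = V_th, V_r = V_r,
                 t_ref = t_ref, I_e = I_e, k_adap = k_adap, k_2 = k_2,
                 k_1 = k_1, A_1 = A_1, A_2 = A_2, lambda_0 = lambda_0,
                 delta_V = delta_V, model = "eglif"),
            class = c("eglif_params", "neuron_params"))
}

#' LIF parameter set
#'
#' Plain leaky integrate-and-fire with deterministic threshold crossing. The
#' passive fields mirror the corresponding EGLIF population; only the
#' endogenous current is retuned so the isolated neuron reproduces the same
#' tonic rate.
#'
#' @inheritParams eglif_params
#' @return A `lif_params` list.
#' @export
lif_params <- function(C_m, tau_m, E_L, V_th, V_r, t_ref, I_e = 0) {
  stopifnot(C_m > 0, tau_m > 0, t_ref > 0)
  if (V_r > V_th) stop("V_r must be <= V_th")
  structure(list(C_m = C_m, tau_m = tau_m, E_L = E_L, V_th = V_th, V_r = V_r,
                 t_ref = t_ref, I_e = I_e, k_adap = 0, k_2 = 0, k_1 = 0,
                 A_1 = 0, A_2 = 0, lambda_0 = 0, delta_V = 1, model = "lif"),
            class = c("lif_params", "neuron_params"))
}

#' Fresh neuron state
#' @param params A `neuron_params` object.
#' @return List with `V_m`, `I_adap`, `I_dep`, `refractory_remaining`,
#'   `last_spike`.
#' @export
neuron_state <- function(params) {
  list(V_m = params$E_L, I_adap = 0, I_dep = 0, refractory_remaining = 0,
       last_spike = NA_real_)
}

params_vector <- function(params, model = params$model) {
  code <- switch(model, lif = 0, eglif = 1, source = 2,
                 stop("unknown model: ", model))
  c(params$C_m, params$tau_m, params$E_L, params$V_th, params$V_r,
    params$t_ref, params$I_e, params$k_adap, params$k_2, params$k_1,
    params$A_1, params$A_2, params$lambda_0, params$delta_V, code)
}

#' Exact subthreshold propagator
#'
#' The subthreshold EGLIF system is linear in `(V_m, I_adap, I_dep)`; over a
#' step of `dt` with the synaptic current frozen, the exact update is
#' `x <- A x + Q b` where `A = expm(M dt)` and `Q = int_0^dt expm(M s) ds`.
#' Step-size invariant: one step of `dt` equals any number of sub-steps.
#'
#' @param params A `neuron_params` object.
#' @param dt Step, ms.
#' @return List with matrices `A` and `Q`.
#' @export
eglif_propagator <- function(params, dt) {
  .propagator_matrices(params$C_m, params$tau_m, params$k_adap, params$k_2,
                       params$k_1, dt)
}

#' Advance an EGLIF neuron by one step
#'
#' Subthreshold state advances by the exact solution of the linear
#' three-variable system; a spike is then drawn from the escape rate. On a
#' spike: `V_m <- V_r`, `I_dep <- A_1`, `I_adap <- I_adap + A_2`, and the
#' refractory clock is set to `t_ref` (during refractoriness `V_m` is clamped
#' at `V_r` while both currents keep evolving).
#'
#' @param state Neuron state, see [neuron_state()].
#' @param params An `eglif_params` object.
#' @param I_syn Total synaptic current at step start, pA.
#' @param dt Step, ms (> 0).
#' @param prop Propagator from [eglif_propagator()] (recomputed if missing).
#' @param stochastic Set `FALSE` to disable spike generation (subthreshold
#'   flow only).
#' @param t Current time, ms (only used to stamp `last_spike`).
#' @return List with the advanced `state` and logical `spiked`.
#' @export
eglif_step <- function(state, params, I_syn = 0, dt = 1,
                       prop = eglif_propagator(params, dt),
                       stochastic = TRUE, t = 0) {
  stopifnot(dt > 0)
  if (state$refractory_remaining > 0) {
    e2 <- if (params$k_2 > 0) exp(-params$k_2 * dt) else 1
    cad <- if (params$k_2 > 0) {
      params$k_adap * (params$V_r - params$E_L) / params$k_2 * (1 - e2)
    } else params$k_adap * (params$V_r - params$E_L) * dt
    state$I_adap <- state$I_adap * e2 + cad
    state$I_dep <- state$I_dep * exp(-params$k_1 * dt)
    state$V_m <- params$V_r
    state$refractory_remaining <- max(0, state$refractory_remaining - dt)
    return(list(state = state, spiked = FALSE))
  }
  x <- c(state$V_m, state$I_adap, state$I_dep)
  b <- c(params$E_L / params$tau_m + (params$I_e + I_syn) / params$C_m,
         -params$k_adap * params$E_L, 0)
  x <- as.numeric(prop$A %*% x + prop$Q %*% b)
  if (!all(is.finite(x))) stop("non-finite neuron state")
  state$V_m <- x[1]
  state$I_adap <- x[2]
  state$I_dep <- x[3]
  spiked <- FALSE
  if (stochastic) {
    arg <- (state$V_m - params$V_th) / params$delta_V
    p <- if (arg > 30) 1 else -expm1(-params$lambda_0 * exp(arg) * dt / 1000)
    spiked <- stats::runif(1) < p
  }
  if (spiked) {
    state$V_m <- params$V_r
    state$I_dep <- params$A_1
    state$I_adap <- state$I_adap + params$A_2
    state$refractory_remaining <- params$t_ref
    state$last_spike <- t + dt
  }
  list(state = state, spiked = spiked)
}

#' Advance a LIF neuron by one step
#'
#' Exact exponential relaxation toward `E_L + (I_e + I_syn) tau_m / C_m`, with
#' deterministic threshold crossing, reset to `V_r` and refractory period
#' `t_ref`.
#'
#' @inheritParams eglif_step
#' @param params A `lif_params` object.
#' @return List with the advanced `state` and logical `spiked`.
#' @export
lif_step <- function(state, params, I_syn = 0, dt = 1, t = 0) {
  stopifnot(dt > 0)
  if (state$refractory_remaining > 0) {
    state$V_m <- params$V_r
    state$refractory_remaining <- max(0, state$refractory_remaining - dt)
    return(list(state = state, spiked = FALSE))
  }
  vinf <- params$E_L + (params$I_e + I_syn) * params$tau_m / params$C_m
  state$V_m <- vinf + (state$V_m - vinf) * exp(-dt / params$tau_m)
  if (!is.finite(state$V_m)) stop("non-finite neuron state")
  spiked <- state$V_m >= params$V_th
  if (spiked) {
    state$V_m <- params$V_r
    state$refractory_remaining <- params$t_ref
    state$last_spike <- t + dt
  }
  list(state = state, spiked = spiked)
}

#' Simulate one isolated neuron
#'
#' Runs the compiled single-neuron propagator under a constant synaptic
#' current.
#'
#' @param params A `neuron_params` object.
#' @param T Duration, ms.
#' @param dt Step, ms.
#' @param I_syn Constant synaptic current, pA.
#' @param seed Optional integer seed.
#' @param V0 Initial membrane potential (defaults to `E_L`).
#' @param record_vm Record the membrane trajectory.
#' @param model Override the params' own model tag.
#' @return List with `spikes` (times, ms) and optionally `vm`.
#' @export
simulate_neuron <- function(params, T, dt = 1, I_syn = 0, seed = NULL,
                            V0 = NA_real_, record_vm = FALSE,
                            model = params$model) {
  if (!is.null(seed)) set.seed(seed)
  .simulate_neuron_cpp(params_vector(params, model), I_syn, T, dt, V0,
                       record_vm)
}

#' Closed-form tonic rate of a LIF neuron under constant current
#'
#' `1 / (t_ref + tau_m log((V_inf - V_r)/(V_inf - V_th)))` with
#' `V_inf = E_L + I tau_m / C_m`; 0 below rheobase.
#'
#' @param params A `lif_params` object.
#' @param I Total constant current, pA (defaults to `I_e`).
#' @return Firing rate, Hz.
#' @export
lif_rate_closed_form <- function(params, I = params$I_e) {
  vinf <- params$E_L + I * params$tau_m / params$C_m
  if (vinf <= params$V_th) return(0)
  isi <- params$t_ref +
    params$tau_m * log((vinf - params$V_r) / (vinf - params$V_th))
  1000 / isi
}

#' Tune the endogenous current to a target tonic rate
#'
#' Monotone bisection over `I_e`: the isolated neuron is simulated for `T` ms
#' and the bracket is narrowed until the realized rate is within `tolerance`
#' of the target. This is the autorhythm-tuning routine used to generate the
#' bundled placeholder parameter sets.
#'
#' @param params A `neuron_params` object (its `I_e` is ignored).
#' @param target_rate Target tonic rate, Hz (> 0).
#' @param tolerance Acceptable |rate - target|, Hz.
#' @param T Simulation length per evaluation, ms.
#' @param dt Step, ms.
#' @param seed Seed used for every evaluation (so the map I_e -> rate is
#'   deterministic).
#' @param max_iter Bisection iterations.
#' @param model Override the params' model tag.
#' @param lower Lower bracket for `I_e`, pA (negative values allow
#'   compensating an escape-noise-driven rate at rest that already exceeds the
#'   target).
#' @return The tuned `I_e`, pA, with the achieved rate as attribute `rate`.
#' @export
tune_intrinsic_current <- function(params, target_rate, tolerance = 1,
                                   T = 10000, dt = 1, seed = 1234,
                                   max_iter = 60, model = params$model,
                                   lower = 0) {
  stopifnot(target_rate > 0)
  rate_at <- function(I) {
    p <- params
    p$I_e <- I
    st <- simulate_neuron(p, T = T, dt = dt, seed = seed, model = model)$spikes
    length(st) / (T / 1000)
  }
  lo <- lower
  hi <- max(params$C_m / params$tau_m * (params$V_th - params$E_L), 1) * 2
  expand <- 0
  while (rate_at(hi) < target_rate) {
    hi <- hi * 2
    expand <- expand + 1
    if (expand > 12) stop("tuning failure: target rate unreachable within current bounds")
  }
  expand <- 0
  while (rate_at(lo) > target_rate) {
    lo <- lo - max(abs(lo), hi / 4)
    expand <- expand + 1
    if (expand > 12) stop("tuning failure: target rate below reach even with hyperpolarizing current")
  }
  I <- (lo + hi) / 2
  r <- rate_at(I)
  iter <- 0
  while (abs(r - target_rate) > tolerance && iter < max_iter) {
    if (r < target_rate) lo <- I else hi <- I
    I <- (lo + hi) / 2
    r <- rate_at(I)
    iter <- iter + 1
  }
  structure(I, rate = r)
}

#' Tonic-rate and regularity statistics of a spike train
#'
#' @param spike_times Sorted spike times, ms.
#' @param window Two-vector `(t0, t1)`, ms.
#' @return List with `f_tonic` (Hz) and `cv_isi` (NA with fewer than 3
#'   spikes).
#' @export
firing_stats <- function(spike_times, window) {
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  stopifnot(length(window) == 2, window[2] > window[1])
  st <- spike_times[spike_times >= window[1] & spike_times <= window[2]]
  f <- length(st) / ((window[2] - window[1]) / 1000)
  cv <- NA_real_
  if (length(st) >= 3) {
    isi <- diff(st)
    cv <- stats::sd(isi) / mean(isi)
  }
  list(f_tonic = f, cv_isi = cv)
}

#' Bundled placeholder electrophysiology
#'
#' Loads the synthetic per-population parameter table shipped with the
#' package (`inst/extdata/neuron_params_synthetic.csv`). These are NOT
#' published measurements: they are placeholder sets produced by the package's
#' own autorhythm-tuning routine, calibrated so each isolated population hits
#' its documented tonic rate and interspike-interval irregularity and so the
#' network-level phenotypes (Purkinje burst-pause, nuclear rebound burst) can
#' express. A user with a published parameter set can substitute their own
#' file with the same columns.
#'
#' @param file Optional path to an alternative parameter CSV.
#' @return Data.frame with one row per population.
#' @export
default_neuron_params <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "neuron_params_synthetic.csv",
                        package = "ocsnn")
  }
  par <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("pop", "C_m", "tau_m", "E_L", "V_th", "V_r", "t_ref",
            "I_e_eglif", "I_e_lif", "k_adap", "k_2", "k_1", "A_1", "A_2",
            "lambda_0", "delta_V", "f_target", "cv_target")
  miss <- setdiff(need, names(par))
  if (length(miss)) stop("parameter file lacks columns: ",
                         paste(miss, collapse = ", "))
  par
}

#' One `neuron_params` object from a parameter-table row
#' @param par Parameter data.frame from [default_neuron_params()].
#' @param pop Population name.
#' @param model "eglif" or "lif".
#' @return A `neuron_params` object.
#' @export
population_params <- function(par, pop, model = c("eglif", "lif")) {
  model <- match.arg(model)
  r <- par[par$pop == pop, ]
  if (nrow(r) != 1) stop("no parameter row for population ", pop)
  if (model == "eglif") {
    eglif_params(r$C_m, r$tau_m, r$E_L, r$V_th, r$V_r, r$t_ref,
                 I_e = r$I_e_eglif, k_adap = r$k_adap, k_2 = r$k_2,
                 k_1 = r$k_1, A_1 = r$A_1, A_2 = r$A_2,
                 lambda_0 = r$lambda_0, delta_V = r$delta_V)
  } else {
    lif_params(r$C_m, r$tau_m, r$E_L, r$V_th, r$V_r, r$t_ref,
               I_e = r$I_e_lif)
  }
}

#' Per-population parameter matrix for the engine
#' @param par Parameter data.frame.
#' @param model "eglif" or "lif" for the dynamic populations.
#' @return Matrix with one row per population in global order (mossy fibers
#'   are external spike sources).
#' @keywords internal
params_matrix <- function(par, model = "eglif") {
  rows <- lapply(POP_ORDER, function(p) {
    if (p == "MF") {
      c(1, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 2)
    } else {
      params_vector(population_params(par, p, model))
    }
  })
  m <- do.call(rbind, rows)
  rownames(m) <- POP_ORDER
  m
}
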