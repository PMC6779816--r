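test_that("resting neuron with no drive is a fixed point of the propagator", {
  p <- eglif_params(C_m = 100, tau_m = 20, E_L = -65, V_th = -40, V_r = -70,
                    t_ref = 2, I_e = 0, A_1 = 0, A_2 = 0)
  st <- neuron_state(p)
  for (dt in c(0.1, 1, 5, 25)) {
    out <- eglif_step(st, p, I_syn = 0, dt = dt, stochastic = FALSE)
    expect_equal(out$state$V_m, -65, tolerance = 1e-12)
    expect_equal(out$state$I_adap, 0, tolerance = 1e-12)
    expect_equal(out$state$I_dep, 0, tolerance = 1e-12)
  }
})

test_that("subthreshold propagation is step-size invariant and matches an ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(20)
  for (k in 1:5) {
    p <- eglif_params(C_m = runif(1, 3, 600), tau_m = runif(1, 5, 60),
                      E_L = runif(1, -75, -50), V_th = -40,
                      V_r = runif(1, -80, -60), t_ref = 1,
                      I_e = runif(1, 0, 500), k_adap = runif(1, 0, 0.3),
                      k_2 = runif(1, 0.005, 0.2), k_1 = runif(1, 0.05, 0.5),
                      A_1 = runif(1, 0, 300), A_2 = runif(1, 0, 300))
    I_syn <- runif(1, -100, 100)
    st <- neuron_state(p)
    st$V_m <- p$E_L + 5
    st$I_adap <- 30
    st$I_dep <- 80
    one <- eglif_step(st, p, I_syn = I_syn, dt = 2, stochastic = FALSE)$state
    sub <- st
    prop <- eglif_propagator(p, 0.2)
    for (i in 1:10) {
      sub <- eglif_step(sub, p, I_syn = I_syn, dt = 0.2, prop = prop,
                        stochastic = FALSE)$state
    }
    expect_equal(one$V_m, sub$V_m, tolerance = 1e-9)
    expect_equal(one$I_adap, sub$I_adap, tolerance = 1e-9)
    expect_equal(one$I_dep, sub$I_dep, tolerance = 1e-9)
    ode <- deSolve::lsoda(
      y = c(V = st$V_m, A = st$I_adap, D = st$I_dep),
      times = c(0, 2),
      func = function(t, y, parms) {
        list(c(-(y[1] - p$E_L) / p$tau_m +
                 (-y[2] + y[3] + p$I_e + I_syn) / p$C_m,
               p$k_adap * (y[1] - p$E_L) - p$k_2 * y[2],
               -p$k_1 * y[3]))
      }, rtol = 1e-11, atol = 1e-11)
    expect_equal(one$V_m, unname(ode[2, "V"]), tolerance = 1e-7)
    expect_equal(one$I_adap, unname(ode[2, "A"]), tolerance = 1e-7)
  }
})

test_that("compiled single-neuron path agrees with the R stepping reference", {
  p <- lif_params(C_m = 150, tau_m = 30, E_L = -60, V_th = -45, V_r = -70,
                  t_ref = 2, I_e = 120)
  cpp <- simulate_neuron(p, T = 50, dt = 1, I_syn = 40, record_vm = TRUE)
  st <- neuron_state(p)
  vr <- numeric(50)
  for (k in 1:50) {
    vr[k] <- st$V_m
    st <- lif_step(st, p, I_syn = 40, dt = 1)$state
  }
  # both paths integrate identically until the first (deterministic) spike
  n <- min(which(diff(cpp$vm) < -5), 50)
  expect_equal(cpp$vm[1:(n - 1)], vr[1:(n - 1)], tolerance = 1e-9)
})

test_that("LIF tonic rate matches the closed form within 1%", {
  p <- lif_params(C_m = 142, tau_m = 33, E_L = -45, V_th = -36, V_r = -55,
                  t_ref = 1.5, I_e = 120)
  sim <- simulate_neuron(p, T = 20000, dt = 0.1, seed = 1)
  rate <- length(sim$spikes) / 20
  expect_equal(rate, lif_rate_closed_form(p), tolerance = 0.01)
  # at rest, no drive: never spikes
  p0 <- lif_params(C_m = 142, tau_m = 33, E_L = -45, V_th = -36, V_r = -55,
                   t_ref = 1.5, I_e = 0)
  expect_length(simulate_neuron(p0, T = 5000, dt = 1)$spikes, 0L)
})

test_that("no spikes are emitted during the refractory period", {
  p <- eglif_params(C_m = 50, tau_m = 10, E_L = -50, V_th = -40, V_r = -55,
                    t_ref = 3, I_e = 500, lambda_0 = 2000, delta_V = 2)
  st <- simulate_neuron(p, T = 5000, dt = 0.5, seed = 9)$spikes
  expect_gt(length(st), 100)
  expect_true(all(diff(st) >= 3 - 1e-9))
  pl <- lif_params(C_m = 50, tau_m = 10, E_L = -50, V_th = -40, V_r = -55,
                   t_ref = 3, I_e = 500)
  stl <- simulate_neuron(pl, T = 5000, dt = 0.5)$spikes
  expect_true(all(diff(stl) >= 3 - 1e-9))
})

test_that("escape noise converges to deterministic threshold crossing", {
  mk <- function(dv) eglif_params(C_m = 142, tau_m = 33, E_L = -45,
                                  V_th = -36, V_r = -55, t_ref = 1.5,
                                  I_e = 150, lambda_0 = 500, delta_V = dv)
  cv_at <- function(dv) {
    st <- simulate_neuron(mk(dv), T = 20000, dt = 1, seed = 3)$spikes
    firing_stats(st, c(500, 20000))$cv_isi
  }
  expect_lt(cv_at(0.01), 0.03) # deterministic floor: clock-like train
  expect_gt(cv_at(4), 0.25)    # strong noise: irregular train
})

test_that("intrinsic-current tuning inverts the closed-form LIF rate", {
  p <- lif_params(C_m = 142, tau_m = 33, E_L = -45, V_th = -36, V_r = -55,
                  t_ref = 1.5)
  I_true <- 130
  target <- lif_rate_closed_form(lif_params(142, 33, -45, -36, -55, 1.5,
                                            I_e = I_true))
  I_hat <- tune_intrinsic_current(p, target, tolerance = 0.2, T = 20000,
                                  dt = 0.1)
  expect_equal(as.numeric(I_hat), I_true, tolerance = 0.05)
  expect_equal(attr(I_hat, "rate"), target, tolerance = 0.01)
  # infinite tolerance: returns the first bracket midpoint, rate finite
  I_any <- tune_intrinsic_current(p, 65, tolerance = Inf)
  expect_true(is.finite(attr(I_any, "rate")))
  expect_error(tune_intrinsic_current(p, 1e7, tolerance = 1),
               "tuning failure")
})

test_that("firing statistics follow their definitions", {
  reg <- seq(10, 1000, by = 10)
  fs <- firing_stats(reg, c(0, 1000))
  expect_equal(fs$f_tonic, 100)
  expect_equal(fs$cv_isi, 0)
  # homogeneous Poisson: CV near 1
  ps <- poisson_train(50, 0, 100000, seed = 4)
  expect_equal(firing_stats(ps, c(0, 100000))$cv_isi, 1, tolerance = 0.05)
  # fewer than 3 spikes: undefined CV, rate still reported
  fs2 <- firing_stats(c(100, 200), c(0, 1000))
  expect_equal(fs2$f_tonic, 2)
  expect_true(is.na(fs2$cv_isi))
  expect_error(firing_stats(c(5, 3, 8), c(0, 10)), "sorted")
})

test_that("bundled placeholder parameters reproduce their calibration targets", {
  par <- test_params()
  for (pop in c("PC", "DCNp", "GoC")) {
    r <- par[par$pop == pop, ]
    p <- population_params(par, pop, "eglif")
    st <- simulate_neuron(p, T = 20000, dt = 1, seed = 17)$spikes
    fs <- firing_stats(st, c(1000, 20000))
    expect_equal(fs$f_tonic, r$f_target, tolerance = 0.08)
  }
})
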