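test_that("PSTH implements count / (neurons x bin seconds)", {
  spikes <- data.table::data.table(
    id = c(1L, 2L, 3L, 1L), time = c(1, 2, 3, 4), pop = "PC",
    microcomplex = 1L)
  h <- psth(spikes, "PC", n_neurons = 10, bin = 5, window = c(0, 10))
  expect_equal(h$rate[1], 4 / (10 * 0.005)) # 80 Hz
  expect_equal(h$rate[2], 0)
  none <- spikes[0, ]
  h0 <- psth(none, "PC", n_neurons = 10, bin = 5, window = c(0, 20))
  expect_true(all(h0$rate == 0))
  expect_error(psth(spikes, "PC", n_neurons = 0), "empty")
})

test_that("Gaussian rate traces are unit-area and superpose", {
  grid <- seq(0, 400, by = 1)
  tr <- instantaneous_rate(200, sigma = 5, grid = grid)
  expect_equal(max(tr$rate), 1000 / (5 * sqrt(2 * pi)), tolerance = 1e-4)
  expect_equal(tr$time[which.max(tr$rate)], 200)
  # integral equals the spike count (unit-area kernels)
  expect_equal(sum(tr$rate) / 1000, 1, tolerance = 1e-4)
  # edge renormalization keeps unit mass for a spike near the boundary
  fine <- seq(0, 400, by = 0.1)
  tr_edge <- instantaneous_rate(2, sigma = 5, grid = fine)
  expect_equal(sum(tr_edge$rate) * 0.1 / 1000, 1, tolerance = 0.02)
  # two far-separated spikes: two identical peaks, integral 2
  tr2 <- instantaneous_rate(c(100, 300), sigma = 5, grid = grid)
  expect_equal(tr2$rate[101], tr2$rate[301], tolerance = 1e-9)
  expect_equal(sum(tr2$rate) / 1000, 2, tolerance = 1e-4)
  expect_true(all(instantaneous_rate(numeric(0), 5, grid)$rate == 0))
})

test_that("response speed follows the max/min arithmetic and sign convention", {
  grid <- seq(1200, 1400, by = 1)
  rate <- rep(50, length(grid))
  rate[grid == 1255] <- 100 # max first
  rate[grid == 1275] <- 20  # then min
  sp <- response_speed(list(time = grid, rate = rate), cf_onset = 1250)
  expect_equal(sp$speed, (100 - 20) / (1255 - 1275)) # -4 Hz/ms
  expect_equal(sp$t_max, 1255)
  expect_equal(sp$t_min, 1275)
  # burst-then-pause is negative; pause-then-burst positive
  expect_lt(sp$speed, 0)
  rate2 <- rep(50, length(grid))
  rate2[grid == 1260] <- 5
  rate2[grid == 1290] <- 120
  expect_gt(response_speed(list(time = grid, rate = rate2), 1250)$speed, 0)
  # flat trace: 0 by convention
  expect_equal(response_speed(list(time = grid,
                                   rate = rep(7, length(grid))), 1250)$speed,
               0)
  # invariant to adding a constant; linear under rate scaling
  shifted <- response_speed(list(time = grid, rate = rate + 13), 1250)
  expect_equal(shifted$speed, sp$speed)
  scaled <- response_speed(list(time = grid, rate = 3 * rate), 1250)
  expect_equal(scaled$speed, 3 * sp$speed)
  expect_error(response_speed(list(time = grid, rate = rate), 1400),
               "window")
})

test_that("speed comparison agrees with a permutation oracle", {
  set.seed(91)
  a <- rnorm(35, 0, 1)
  b <- rnorm(35, 5, 1) # five-sigma separation
  out <- compare_speeds(a, b)
  expect_lt(out$p, 1e-6)
  # permutation null: no permuted |mean difference| reaches the observed one
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(2000, {
    idx <- sample(70, 35)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  expect_equal(mean(perm >= obs), 0)
  # moderate separation: t-test and permutation p agree
  set.seed(92)
  a2 <- rnorm(30, 0, 1)
  b2 <- rnorm(30, 0.6, 1)
  p_t <- compare_speeds(a2, b2)$p
  pooled2 <- c(a2, b2)
  obs2 <- abs(mean(a2) - mean(b2))
  perm2 <- replicate(20000, {
    idx <- sample(60, 30)
    abs(mean(pooled2[idx]) - mean(pooled2[-idx]))
  })
  expect_equal(p_t, mean(perm2 >= obs2), tolerance = 0.25)
  # identical groups: t = 0, p in the null region
  same <- compare_speeds(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_gt(same$p, 0.99)
  # degenerate variance reported, not raised
  deg <- compare_speeds(c(1, 1), c(1, 1))
  expect_true(deg$degenerate)
})

test_that("eyeblink decoder matches its impulse response and is linear", {
  eb <- decode_eyeblink(list(100, numeric(0)), dt = 1, T = 300)
  k0 <- 101 # sample containing the spike at t = 100
  expect_equal(eb$decoded[k0, 1], 1.0)
  # e-fold decay every 10 ms before smoothing
  expect_equal(eb$decoded[k0 + 10, 1], exp(-1), tolerance = 1e-9)
  expect_equal(eb$decoded[k0 + 30, 1], exp(-3), tolerance = 1e-9)
  expect_true(all(eb$decoded[1:(k0 - 1), 1] == 0))
  expect_true(all(eb$decoded[, 2] == 0))
  # no spikes anywhere: identically zero net response
  eb0 <- decode_eyeblink(list(numeric(0), numeric(0)), dt = 1, T = 100,
                         baseline_window = c(0, 50))
  expect_true(all(eb0$net == 0))
  # linearity in the spike input (before and after the moving average)
  ebA <- decode_eyeblink(list(c(50, 120), numeric(0)), dt = 1, T = 300)
  ebB <- decode_eyeblink(list(c(80), numeric(0)), dt = 1, T = 300)
  ebAB <- decode_eyeblink(list(c(50, 80, 120), numeric(0)), dt = 1, T = 300)
  expect_equal(ebAB$decoded[, 1], ebA$decoded[, 1] + ebB$decoded[, 1],
               tolerance = 1e-9)
  expect_equal(ebAB$filtered[, 1], ebA$filtered[, 1] + ebB$filtered[, 1],
               tolerance = 1e-9)
  # microcomplex-difference mode
  ebd <- decode_eyeblink(list(c(100), c(100)), dt = 1, T = 200, mode = "diff")
  expect_true(all(abs(ebd$net) < 1e-9))
})

test_that("PSTH of a Poisson population recovers the generating rate", {
  set.seed(14)
  n <- 50
  rate <- 20
  spikes <- data.table::rbindlist(lapply(1:n, function(i) {
    tt <- poisson_train(rate, 0, 2000)
    if (!length(tt)) return(NULL)
    data.table::data.table(id = i, time = tt, pop = "GrC", microcomplex = 1L)
  }))
  h <- psth(spikes, "GrC", n_neurons = n, bin = 5, window = c(0, 2000))
  expect_equal(mean(h$rate), rate, tolerance = 0.05)
})
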