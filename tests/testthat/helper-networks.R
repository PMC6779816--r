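# Hand-built micro-networks and cached fixtures shared across test files.

# A network with one external source population (MF) fanning into one target
# neuron through `nsyn` copies of a named connection-table row.
micro_chain <- function(target_pop, row_name, nsyn = 1, weight = NULL,
                        delay = NULL, pre_pop = "MF") {
  tab <- connection_table()
  r <- tab[tab$name == row_name, ]
  counts <- setNames(rep(0L, length(ocsnn:::POP_ORDER)), ocsnn:::POP_ORDER)
  counts[pre_pop] <- 1L
  counts[target_pop] <- counts[target_pop] + 1L
  neurons <- data.frame(id = 1:2, pop = c(pre_pop, target_pop),
                        x = 200, y = c(50, 137), z = 150, microcomplex = 1L)
  syn <- data.table::data.table(
    pre = rep(1L, nsyn), post = 2L, row = row_name,
    weight = if (is.null(weight)) r$weight else weight,
    delay = if (is.null(delay)) r$delay else delay,
    tau_alpha = r$tau_alpha, erev = r$erev, sign = r$sign)
  structure(list(neurons = neurons, synapses = syn, counts = counts,
                 volumes = default_volumes(), table = tab,
                 placement = placement_params(),
                 seeds = list(placement = 1L, connectivity = 1L)),
            class = "ocsnn_network")
}

# protocol with a single forced/poisson phase on all external sources
burst_protocol <- function(t0, t1, rate = 500, target = "MF_all",
                           kind = "burst", duration = 2000) {
  p <- ebcc_protocol()
  p$phases <- data.frame(t_start = t0, t_end = t1, kind = kind, rate = rate,
                         target = target)
  p$duration <- duration
  p
}

silent_protocol <- function(duration = 1000) {
  p <- ebcc_protocol()
  p$phases <- p$phases[0, ]
  p$duration <- duration
  p
}

# cached small scaffold (built once per test run)
.fixtures <- new.env(parent = emptyenv())
toy_net <- function(scale = 0.02, seed = 1L) {
  key <- paste0("toy_", scale, "_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_toy_network(scale, seed = seed)
  }
  .fixtures[[key]]
}

test_params <- function() {
  if (is.null(.fixtures$params)) .fixtures$params <- default_neuron_params()
  .fixtures$params
}

# brute-force equal-size 2-means over all bipartitions (oracle for the
# position-based cluster split)
brute_2means <- function(pos) {
  n <- nrow(pos)
  best <- NULL
  best_ss <- Inf
  for (idx in utils::combn(n, n / 2, simplify = FALSE)) {
    a <- pos[idx, , drop = FALSE]
    b <- pos[-idx, , drop = FALSE]
    ss <- sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- idx
    }
  }
  best
}
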