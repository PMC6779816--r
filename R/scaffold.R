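#' @useDynLib ocsnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

POP_ORDER <- c("MF", "GoC", "GrC", "MLI", "PC", "DCNp", "DCNi", "IO")

#' Placement parameters
#'
#' Soma radii and inferior-olive placement settings. The DCNi satellite
#' distance bounds are derived at placement time: `d1 = r_dcnp + r_dcni`
#' (somata must not overlap) and `d2 = mean_dist/4 - r_dcnp - r_dcni`, with
#' `mean_dist` the mean pairwise distance between placed DCNp somata, so that
#' each interneuron stays a satellite of its own projection neuron. Radii are
#' package defaults (not constrained by data used here) and flagged as
#' assumptions.
#'
#' @param io_density Inferior-olive density, cells/mm^3.
#' @param io_step Random-walk step length, um.
#' @param r_dcnp,r_dcni,r_io Soma radii, um.
#' @return List of placement parameters.
#' @export
placement_params <- function(io_density = 15172, io_step = 10,
                             r_dcnp = 10, r_dcni = 5, r_io = 7.5) {
  list(io_density = io_density, io_step = io_step,
       r_dcnp = r_dcnp, r_dcni = r_dcni, r_io = r_io)
}

#' Place a population uniformly at random inside a layer volume
#'
#' @param count Number of somata (>= 0).
#' @param volume A [volume_spec()].
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return A `count` x 3 matrix of positions (columns x, y, z; um).
#' @export
place_population <- function(count, volume, seed = NULL) {
  if (count < 0) stop("count must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  count <- as.integer(count)
  m <- matrix(stats::runif(3L * count), ncol = 3)
  m <- sweep(m, 2, volume$extent, `*`)
  m <- sweep(m, 2, volume$origin, `+`)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Place inferior-olive somata by a self-avoiding bounded random walk
#'
#' The number of cells is `floor(density x volume)`. The walk starts at a
#' random point, takes fixed-length steps in uniformly random directions,
#' reflects at the volume boundary, and deposits a soma whenever the current
#' point is at least `2 r_soma` away from every deposited soma.
#'
#' @param volume Olivary [volume_spec()].
#' @param density Cells per mm^3 (default 15172).
#' @param step Walk step length, um.
#' @param seed Optional integer seed.
#' @param r_soma Soma radius, um.
#' @param n Optional explicit cell count overriding the density-derived one
#'   (used for reduced test networks).
#' @param max_retries Walk steps allowed per soma before declaring the volume
#'   infeasible.
#' @return An n x 3 position matrix.
#' @export
place_io_cells <- function(volume, density = 15172, step = 10, seed = NULL,
                           r_soma = 7.5, n = NULL, max_retries = 1000) {
  if (density <= 0) stop("density must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- floor(density * volume_um3(volume) / 1e9)
  n <- as.integer(n)
  lo <- volume$origin
  hi <- volume$origin + volume$extent
  reflect <- function(p) {
    for (k in 1:3) {
      while (p[k] < lo[k] || p[k] > hi[k]) {
        if (p[k] < lo[k]) p[k] <- 2 * lo[k] - p[k]
        if (p[k] > hi[k]) p[k] <- 2 * hi[k] - p[k]
      }
    }
    p
  }
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  if (n == 0L) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  pos <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  cur <- lo + stats::runif(3) * volume$extent
  pos[1, ] <- cur
  if (n > 1L) {
    for (i in 2:n) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        cur <- reflect(cur + step * rand_dir())
        d2 <- rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                         matrix(cur, i - 1, 3, byrow = TRUE))^2)
        if (min(d2) >= (2 * r_soma)^2) {
          pos[i, ] <- cur
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("olivary placement infeasible: could not fit soma ", i,
             " of ", n, " with minimum separation ", 2 * r_soma,
             " um after ", max_retries, " walk steps")
      }
    }
  }
  pos
}

#' Place one nuclear interneuron (DCNi) as a satellite of each DCNp
#'
#' Each DCNi is dropped at a uniformly random distance `d` in `[d1, d2]` from
#' its projection neuron, in a uniformly random direction, with
#' `d1 = r_dcnp + r_dcni` and `d2 = mean_dist/4 - r_dcnp - r_dcni`
#' (`mean_dist` = mean pairwise DCNp distance). Proposals are clamped to the
#' nuclear volume and re-drawn until the satellite property holds (the DCNi is
#' closer to its own DCNp than to any other).
#'
#' @param dcnp_pos Matrix of DCNp positions (>= 2 rows).
#' @param r_dcnp,r_dcni Soma radii, um.
#' @param seed Optional integer seed.
#' @param volume Optional nuclear [volume_spec()] used for clamping.
#' @param max_retries Proposal attempts per interneuron.
#' @return Matrix of DCNi positions, one row per DCNp (same order).
#' @export
place_dcni <- function(dcnp_pos, r_dcnp = 10, r_dcni = 5, seed = NULL,
                       volume = NULL, max_retries = 1000) {
  n <- nrow(dcnp_pos)
  if (n < 2) stop("need at least 2 DCNp positions to define mean_dist")
  if (!is.null(seed)) set.seed(seed)
  mean_dist <- mean(stats::dist(dcnp_pos))
  d1 <- r_dcnp + r_dcni
  d2 <- mean_dist / 4 - r_dcnp - r_dcni
  if (d2 <= d1) {
    stop("DCNi placement infeasible: d2 (", signif(d2, 4),
         ") <= d1 (", signif(d1, 4),
         "); requires mean_dist/4 - r_dcnp - r_dcni > r_dcnp + r_dcni")
  }
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      d <- stats::runif(1, d1, d2)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      p <- dcnp_pos[i, ] + d * u
      if (!is.null(volume)) {
        p <- pmin(pmax(p, volume$origin), volume$origin + volume$extent)
      }
      dd <- sqrt(rowSums((dcnp_pos - matrix(p, n, 3, byrow = TRUE))^2))
      if (which.min(dd) == i && dd[i] >= d1 * 0.999) {
        out[i, ] <- p
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place a satellite DCNi for DCNp ", i)
  }
  out
}

#' Label neurons by microzone / microcomplex
#'
#' Cortical neurons (MF, GoC, GrC, MLI, PC) are labeled by the parasagittal
#' split of the cortical slab into two 200-um microzones along z. DCNp and IO
#' are divided into two equal-size position-based clusters (split at the
#' z-median, the midplane of the realized positions); each DCNi inherits the
#' label of its nearest DCNp, which by construction is its parent.
#'
#' @param network An `ocsnn_network`.
#' @param z_split Cortical split coordinate, um.
#' @return The network with a filled `microcomplex` column (1 or 2).
#' @export
assign_microcomplexes <- function(network, z_split = NULL) {
  nn <- network$neurons
  if (is.null(z_split)) {
    cv <- network$volumes$cortex
    z_split <- cv$origin[3] + cv$extent[3] / 2
  }
  cortical <- nn$pop %in% c("MF", "GoC", "GrC", "MLI", "PC")
  nn$microcomplex[cortical] <- ifelse(nn$z[cortical] <= z_split, 1L, 2L)
  split_equal <- function(idx) {
    m <- length(idx)
    if (m %% 2L != 0L) {
      stop("population of size ", m, " cannot be split into two equal clusters")
    }
    lab <- rep(2L, m)
    ord <- order(nn$z[idx], idx) # ties broken by neuron index
    lab[ord[seq_len(m / 2)]] <- 1L
    lab
  }
  for (p in c("DCNp", "IO")) {
    idx <- which(nn$pop == p)
    if (length(idx)) nn$microcomplex[idx] <- split_equal(idx)
  }
  idx_i <- which(nn$pop == "DCNi")
  idx_p <- which(nn$pop == "DCNp")
  if (length(idx_i) && length(idx_p)) {
    pp <- as.matrix(nn[idx_p, c("x", "y", "z")])
    for (k in idx_i) {
      d <- rowSums((pp - matrix(as.numeric(nn[k, c("x", "y", "z")]),
                                nrow(pp), 3, byrow = TRUE))^2)
      nn$microcomplex[k] <- nn$microcomplex[idx_p[which.min(d)]]
    }
  }
  network$neurons <- nn
  network
}

#' Instantiate the synapses of one connection-table row
#'
#' Builds the candidate presynaptic pool according to the row's geometric
#' rule, draws the per-target convergence (fixed, or Gaussian with the printed
#' SD, clipped at 1 and at the pool size for statistical rows), and samples
#' without replacement. Microcomplex-confined rows never cross labels;
#' same-population rows never create self-synapses.
#'
#' @param network An `ocsnn_network` with positions and labels.
#' @param row One row of [connection_table()].
#' @param allow_clip Clip fixed convergences to the pool size instead of
#'   erroring (used by reduced test networks).
#' @param min_delay Smallest admissible delay, ms (the simulation resolution).
#' @return A data.table of synapses: pre, post (global ids), row, weight,
#'   delay, tau_alpha, erev, sign.
#' @export
connect_populations <- function(network, row, allow_clip = FALSE,
                                min_delay = 1) {
  nn <- network$neurons
  pre_idx <- which(nn$pop == row$src)
  post_idx <- which(nn$pop == row$post)
  if (length(pre_idx) == 0L || length(post_idx) == 0L) {
    return(empty_synapses())
  }
  fixed <- row$conv_sd == 0
  pre <- post <- integer(0)

  if (row$rule %in% c("radial_xz", "axis_x")) {
    res <- .connect_geometric_cpp(
      as.matrix(nn[pre_idx, c("x", "z")]),
      as.matrix(nn[post_idx, c("x", "z")]),
      row$reach, ifelse(row$rule == "radial_xz", 0L, 1L),
      row$conv_mean, row$conv_sd, fixed, allow_clip,
      row$src == row$post, row$name)
    pre <- pre_idx[res$pre]
    post <- post_idx[res$post]
  } else if (row$rule == "all") {
    for (j in post_idx) {
      k <- draw_convergence(row, length(pre_idx), fixed, allow_clip)
      sel <- pre_idx[sample.int(length(pre_idx), k)]
      pre <- c(pre, sel)
      post <- c(post, rep(j, k))
    }
  } else if (row$rule == "cluster") {
    for (j in post_idx) {
      pool <- pre_idx[nn$microcomplex[pre_idx] == nn$microcomplex[j]]
      pool <- setdiff(pool, j)
      if (length(pool) == 0L) {
        if (allow_clip) next
        stop("connection '", row$name, "': empty microcomplex pool for target ",
             j)
      }
      k <- draw_convergence(row, length(pool), fixed, allow_clip,
                            clip_statistical = TRUE)
      sel <- pool[sample.int(length(pool), k)]
      pre <- c(pre, sel)
      post <- c(post, rep(j, k))
    }
  } else if (row$rule == "cf_assign") {
    # one climbing fiber per Purkinje cell; balanced over the microcomplex's
    # IO cells so the divergence stays within [4, 8] at default sizes
    for (m in sort(unique(nn$microcomplex[post_idx]))) {
      pcs <- post_idx[nn$microcomplex[post_idx] == m]
      ios <- pre_idx[nn$microcomplex[pre_idx] == m]
      if (length(ios) == 0L) {
        if (allow_clip) next
        stop("connection '", row$name, "': no IO cells in microcomplex ", m)
      }
      pcs <- pcs[sample.int(length(pcs))]
      ios <- ios[sample.int(length(ios))]
      pre <- c(pre, ios[(seq_along(pcs) - 1L) %% length(ios) + 1L])
      post <- c(post, pcs)
    }
  } else {
    stop("unknown connectivity rule: ", row$rule)
  }

  ns <- length(pre)
  if (ns == 0L) return(empty_synapses())
  if (row$delay_sd > 0) {
    delay <- pmax(stats::rnorm(ns, row$delay, row$delay_sd), min_delay)
  } else if (row$name == "MLI-PC") {
    # basket vs stellate inhibition reaches the Purkinje cell with 4 or 5 ms
    delay <- sample(c(4, 5), ns, replace = TRUE)
  } else {
    delay <- rep(max(row$delay, min_delay), ns)
  }
  data.table::data.table(
    pre = as.integer(pre), post = as.integer(post), row = row$name,
    weight = row$weight, delay = delay, tau_alpha = row$tau_alpha,
    erev = row$erev, sign = row$sign)
}

empty_synapses <- function() {
  data.table::data.table(pre = integer(0), post = integer(0),
                         row = character(0), weight = numeric(0),
                         delay = numeric(0), tau_alpha = numeric(0),
                         erev = numeric(0), sign = character(0))
}

draw_convergence <- function(row, pool, fixed, allow_clip,
                             clip_statistical = TRUE) {
  k <- if (fixed) round(row$conv_mean) else
    round(stats::rnorm(1, row$conv_mean, row$conv_sd))
  k <- max(1, k)
  if (k > pool) {
    if (fixed && !allow_clip) {
      stop("connection '", row$name, "': candidate pool (", pool,
           ") smaller than required convergence (", k, ")")
    }
    if (!fixed && !clip_statistical && !allow_clip) {
      stop("connection '", row$name, "': pool exhausted")
    }
    k <- pool
  }
  as.integer(k)
}

#' Build the full olivocerebellar network
#'
#' Places every population, labels microzones/microcomplexes, and instantiates
#' all connection-table rows. Placement and connectivity consume separate seed
#' streams so structural stochasticity is separable.
#'
#' @param counts Named population sizes, see [default_counts()].
#' @param volumes Named layer volumes, see [default_volumes()].
#' @param table Connection table, see [connection_table()].
#' @param placement Placement parameters, see [placement_params()].
#' @param seed_placement,seed_connectivity Integer seeds.
#' @param allow_clip Passed to [connect_populations()] (reduced networks).
#' @return An `ocsnn_network`: `neurons` (id, pop, x, y, z, microcomplex),
#'   `synapses` (data.table), plus the inputs used to build it.
#' @export
build_network <- function(counts = default_counts(),
                          volumes = default_volumes(),
                          table = connection_table(),
                          placement = placement_params(),
                          seed_placement = 1L, seed_connectivity = 2L,
                          allow_clip = FALSE) {
  counts <- counts[POP_ORDER]
  layers <- population_layers()
  set.seed(seed_placement)
  pos <- list()
  for (p in c("MF", "GoC", "GrC", "MLI", "PC")) {
    pos[[p]] <- place_population(counts[[p]], volumes[[layers[[p]]]])
  }
  pos$IO <- place_io_cells(volumes$olive, density = placement$io_density,
                           step = placement$io_step, r_soma = placement$r_io,
                           n = counts[["IO"]])
  # At very small DCNp counts a random draw can leave the satellite bounds
  # d1 < d2 unsatisfiable; redraw the projection neurons a bounded number of
  # times (still within the placement seed stream, so deterministic).
  for (attempt in 1:50) {
    pos$DCNp <- place_population(counts[["DCNp"]], volumes$nuclei)
    dcni <- tryCatch(
      place_dcni(pos$DCNp, r_dcnp = placement$r_dcnp,
                 r_dcni = placement$r_dcni, volume = volumes$nuclei),
      error = function(e) {
        if (grepl("infeasible", conditionMessage(e)) && attempt < 50) NULL
        else stop(e)
      })
    if (!is.null(dcni)) break
  }
  pos$DCNi <- dcni
  if (nrow(pos$DCNi) != counts[["DCNi"]]) {
    stop("DCNi count must equal DCNp count (one satellite per DCNp)")
  }
  neurons <- do.call(rbind, lapply(POP_ORDER, function(p) {
    data.frame(pop = p, pos[[p]])
  }))
  neurons <- data.frame(id = seq_len(nrow(neurons)), neurons,
                        microcomplex = NA_integer_)
  net <- structure(list(neurons = neurons, synapses = NULL, counts = counts,
                        volumes = volumes, table = table,
                        placement = placement,
                        seeds = list(placement = seed_placement,
                                     connectivity = seed_connectivity)),
                   class = "ocsnn_network")
  net <- assign_microcomplexes(net)
  set.seed(seed_connectivity)
  syn <- lapply(seq_len(nrow(table)), function(i) {
    connect_populations(net, table[i, ], allow_clip = allow_clip)
  })
  net$synapses <- data.table::rbindlist(syn)
  net
}

#' Realized convergence/divergence report
#'
#' For every connection type, the realized synapse total and the mean and SD
#' of the in-degree over all neurons of the target population and of the
#' out-degree over all neurons of the source population (zeros included), plus
#' a grand synapse total. The report does not modify the network.
#'
#' @param network A connected `ocsnn_network`.
#' @return A data.frame with one record per connection row and a `TOTAL` row.
#' @export
connectivity_report <- function(network) {
  tab <- network$table
  nn <- network$neurons
  syn <- network$synapses
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    s <- syn[syn$row == r$name, ]
    post_idx <- which(nn$pop == r$post)
    pre_idx <- which(nn$pop == r$src)
    indeg <- tabulate(match(s$post, post_idx), nbins = length(post_idx))
    outdeg <- tabulate(match(s$pre, pre_idx), nbins = length(pre_idx))
    data.frame(row = r$name, n_synapses = nrow(s),
               conv_mean = if (length(indeg)) mean(indeg) else 0,
               conv_sd = if (length(indeg) > 1) stats::sd(indeg) else 0,
               div_mean = if (length(outdeg)) mean(outdeg) else 0,
               div_sd = if (length(outdeg) > 1) stats::sd(outdeg) else 0)
  })
  rep <- do.call(rbind, out)
  rbind(rep, data.frame(row = "TOTAL", n_synapses = sum(rep$n_synapses),
                        conv_mean = NA, conv_sd = NA, div_mean = NA,
                        div_sd = NA))
}

#' Population offsets and sizes in global id order
#' @param network An `ocsnn_network`.
#' @return List with `offset` (0-based first id) and `size` per population.
#' @keywords internal
population_index <- function(network) {
  sizes <- vapply(POP_ORDER, function(p) sum(network$neurons$pop == p), 0L)
  list(offset = c(0L, cumsum(sizes))[seq_along(sizes)], size = sizes,
       pops = POP_ORDER)
}
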