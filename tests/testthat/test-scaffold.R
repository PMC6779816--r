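test_that("uniform placement fills the volume and respects counts and seed", {
  vol <- volume_spec("granular", c(0, 0, 0), c(400, 130, 400))
  p <- place_population(1000, vol, seed = 42)
  expect_equal(dim(p), c(1000L, 3L))
  expect_true(all(p >= 0))
  expect_true(all(sweep(p, 2, vol$extent) <= 0))
  # same seed reproduces, different seed differs
  expect_identical(p, place_population(1000, vol, seed = 42))
  expect_false(identical(p, place_population(1000, vol, seed = 43)))
  # parasagittal split is balanced (binomial CI by direct counting)
  frac <- mean(p[, "z"] <= 200)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 1000))
  expect_equal(nrow(place_population(0, vol)), 0L)
  expect_error(place_population(-1, vol), "count")
})

test_that("volume invariants hold for the default geometry", {
  vols <- default_volumes()
  expect_error(volume_spec("bad", c(0, 0, 0), c(1, -1, 1)), "positive")
  ratio <- volume_um3(vols$cortex) / volume_um3(vols$olive)
  expect_gte(ratio, 66)
  expect_lte(ratio, 68)
  expect_equal(sum(default_counts()), 96767L)
})

test_that("olivary random walk places the density-implied count without overlap", {
  vols <- default_volumes()
  pos <- place_io_cells(vols$olive, density = 15172, seed = 7, r_soma = 5)
  expect_equal(nrow(pos), 12L) # floor(15172 cells/mm^3 x 0.0008 mm^3)
  lo <- vols$olive$origin
  hi <- lo + vols$olive$extent
  expect_true(all(t(pos) >= lo & t(pos) <= hi))
  # exhaustive pairwise self-avoidance scan: all 66 pairs >= 2 r
  d <- as.matrix(dist(pos))
  expect_true(all(d[upper.tri(d)] >= 10))
  expect_identical(pos, place_io_cells(vols$olive, density = 15172, seed = 7,
                                       r_soma = 5))
  # single cell trivially inside
  one <- place_io_cells(vols$olive, density = 1300, seed = 1)
  expect_equal(nrow(one), 1L)
  # a volume too small for non-overlapping somata errors out
  tiny <- volume_spec("tiny", c(0, 0, 0), c(8, 8, 8))
  expect_error(place_io_cells(tiny, density = 1e10, seed = 1, r_soma = 5,
                              max_retries = 50),
               "infeasible")
})

test_that("DCNi satellites respect the distance bounds and nearest-parent rule", {
  # two DCNp 200 um apart -> mean_dist 200, d in [14, 36] with radii 10 and 4
  dcnp <- rbind(c(100, -300, 200), c(300, -300, 200))
  set.seed(5)
  for (k in 1:20) {
    dcni <- place_dcni(dcnp, r_dcnp = 10, r_dcni = 4)
    d <- sqrt(rowSums((dcni - dcnp)^2))
    expect_true(all(d >= 14 - 1e-6 & d <= 36 + 1e-6))
    # brute-force nearest-DCNp search confirms the satellite property
    for (i in 1:2) {
      dd <- sqrt(colSums((t(dcnp) - dcni[i, ])^2))
      expect_equal(which.min(dd), i)
    }
  }
  # vanishing radii: d in [0, mean_dist/4]
  dcni0 <- place_dcni(dcnp, r_dcnp = 0, r_dcni = 0, seed = 1)
  expect_true(all(sqrt(rowSums((dcni0 - dcnp)^2)) <= 50 + 1e-6))
  # violated inequality is a configuration error naming it
  close_pair <- rbind(c(100, -300, 200), c(130, -300, 200))
  expect_error(place_dcni(close_pair, r_dcnp = 10, r_dcni = 4), "d2")
})

test_that("microcomplex labels split cortex by z and cluster DCN/IO equally", {
  net <- toy_net()
  nn <- net$neurons
  cortical <- nn$pop %in% c("MF", "GoC", "GrC", "MLI", "PC")
  expect_true(all(nn$microcomplex[cortical & nn$z <= 200] == 1L))
  expect_true(all(nn$microcomplex[cortical & nn$z > 200] == 2L))
  for (p in c("DCNp", "IO")) {
    tab <- table(nn$microcomplex[nn$pop == p])
    expect_equal(unname(tab["1"]), unname(tab["2"]))
  }
  # DCNi inherits its parent's cluster (satellite = nearest DCNp)
  dcnp <- nn[nn$pop == "DCNp", ]
  for (k in which(nn$pop == "DCNi")) {
    dd <- (dcnp$x - nn$x[k])^2 + (dcnp$y - nn$y[k])^2 + (dcnp$z - nn$z[k])^2
    expect_equal(nn$microcomplex[k], dcnp$microcomplex[which.min(dd)])
  }
})

test_that("position-based cluster split matches exhaustive 2-means on separated groups", {
  # 12 points in two well-separated z-groups, shuffled order
  set.seed(11)
  pos <- rbind(cbind(runif(6, 150, 250), runif(6, -330, -270), runif(6, 110, 160)),
               cbind(runif(6, 150, 250), runif(6, -330, -270), runif(6, 240, 290)))
  pos <- pos[sample(12), ]
  colnames(pos) <- c("x", "y", "z")
  fake <- structure(list(neurons = data.frame(id = 1:12, pop = "DCNp",
                                              x = pos[, 1], y = pos[, 2],
                                              z = pos[, 3],
                                              microcomplex = NA_integer_),
                         volumes = default_volumes()),
                    class = "ocsnn_network")
  fake <- assign_microcomplexes(fake)
  oracle <- brute_2means(pos)
  labs <- fake$neurons$microcomplex
  expect_equal(sort(which(labs == labs[oracle[1]])), sort(oracle))
  # degenerate toy input: everything in slab 1
  all1 <- fake
  all1$neurons$pop <- "GrC"
  all1$neurons$z <- 50
  all1 <- assign_microcomplexes(all1)
  expect_true(all(all1$neurons$microcomplex == 1L))
})

test_that("connectivity sampling meets exact and statistical convergence targets", {
  # toy 4-pre / 2-post with fixed convergence 2: enumerated edge list
  net <- micro_chain("PC", "MLI-PC")
  net$neurons <- data.frame(id = 1:6, pop = c(rep("MLI", 4), "PC", "PC"),
                            x = c(190, 210, 200, 205, 200, 201),
                            y = 250, z = c(149, 151, 150, 152, 150, 151),
                            microcomplex = 1L)
  row <- connection_table()[connection_table()$name == "MLI-PC", ]
  row$conv_mean <- 2
  set.seed(3)
  syn <- connect_populations(net, row)
  expect_equal(nrow(syn), 4L)
  expect_equal(as.vector(table(syn$post)), c(2L, 2L))
  expect_true(all(syn$pre %in% 1:4))
  expect_true(all(!duplicated(syn[, c("pre", "post")])))
  # empty pre-population gives an empty synapse list
  empty <- net
  empty$neurons <- net$neurons[net$neurons$pop == "PC", ]
  expect_equal(nrow(connect_populations(empty, row)), 0L)
  # infeasible fixed convergence errors with the row name
  row$conv_mean <- 10
  expect_error(connect_populations(net, row), "MLI-PC")
})

test_that("toy scaffold respects confinement, self-synapse and degree invariants", {
  net <- toy_net()
  syn <- net$synapses
  lab <- net$neurons$microcomplex
  confined <- net$table$name[net$table$confined]
  expect_equal(sum(syn$row %in% confined & lab[syn$pre] != lab[syn$post]), 0L)
  for (r in c("GoC-GoC", "MLI-MLI")) {
    expect_equal(sum(syn$row == r & syn$pre == syn$post), 0L)
  }
  # each PC has exactly one climbing fiber
  cf <- syn[syn$row == "CF-PC", ]
  pcs <- net$neurons$id[net$neurons$pop == "PC"]
  expect_equal(sort(cf$post), sort(pcs))
  # regenerating with the same seeds is byte-identical; a different seed isn't
  net2 <- make_toy_network(0.02, seed = 1L)
  expect_identical(net$synapses, net2$synapses)
  net3 <- make_toy_network(0.02, seed = 2L)
  expect_false(identical(net$synapses, net3$synapses))
})

test_that("connectivity report is pure and arithmetically consistent", {
  net <- toy_net()
  before <- data.table::copy(net$synapses)
  rep <- connectivity_report(net)
  expect_identical(net$synapses, before)
  expect_equal(rep$n_synapses[rep$row == "TOTAL"],
               sum(rep$n_synapses[rep$row != "TOTAL"]))
  expect_equal(rep$n_synapses[rep$row == "TOTAL"], nrow(net$synapses))
  # per-row totals equal conv_mean x n_post by construction of the means
  for (i in which(rep$row != "TOTAL")) {
    r <- rep[i, ]
    n_post <- sum(net$neurons$pop ==
                    net$table$post[net$table$name == r$row])
    expect_equal(r$n_synapses, r$conv_mean * n_post, tolerance = 1e-9)
  }
})
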