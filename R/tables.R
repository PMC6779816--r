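#' Default neuron counts of the olivocerebellar scaffold
#'
#' Census of the reconstructed volume: mossy fibers (MF), Golgi cells (GoC),
#' granule cells (GrC), molecular-layer interneurons (MLI), Purkinje cells
#' (PC), deep-cerebellar-nuclei projection neurons (DCNp) and interneurons
#' (DCNi), and inferior-olive neurons (IO). The default census totals 96767
#' elements.
#'
#' @return Named integer vector of population sizes.
#' @export
default_counts <- function() {
  c(MF = 7073L, GoC = 219L, GrC = 88164L, MLI = 1206L,
    PC = 69L, DCNp = 12L, DCNi = 12L, IO = 12L)
}

#' Default layer volumes
#'
#' Axis convention: `y` is depth (layering axis); the `x`-`z` plane is
#' transversal, with the parasagittal microzone split at `z = 200` um.
#' The cerebellar cortex spans 400 x 330 x 400 um^3 (granular, Purkinje and
#' molecular sub-layers stacked along y), the nuclei 200 x 600 x 200 um^3
#' underneath, and the inferior olive 100 x 200 x 40 um^3 below that
#' (cortical/olivary volume ratio 66:1).
#'
#' @return Named list of volume specs, each with `origin` and `extent`
#'   (3-vectors, um).
#' @export
default_volumes <- function() {
  list(
    granular  = volume_spec("granular",  c(0, 0, 0),      c(400, 130, 400)),
    purkinje  = volume_spec("purkinje",  c(0, 130, 0),    c(400, 15, 400)),
    molecular = volume_spec("molecular", c(0, 145, 0),    c(400, 185, 400)),
    cortex    = volume_spec("cortex",    c(0, 0, 0),      c(400, 330, 400)),
    nuclei    = volume_spec("nuclei",    c(100, -600, 100), c(200, 600, 200)),
    olive     = volume_spec("olive",     c(150, -740, 180), c(100, 200, 40))
  )
}

#' Construct a volume specification
#'
#' @param name Layer identifier.
#' @param origin Numeric 3-vector, um.
#' @param extent Numeric 3-vector of strictly positive edge lengths, um.
#' @return A `volume_spec` list.
#' @export
volume_spec <- function(name, origin, extent) {
  stopifnot(length(origin) == 3, length(extent) == 3)
  if (any(extent <= 0)) {
    stop("volume '", name, "': all extents must be strictly positive")
  }
  structure(list(name = name, origin = as.numeric(origin),
                 extent = as.numeric(extent)),
            class = "volume_spec")
}

#' Volume of a volume_spec in cubic micrometres
#' @param vol A `volume_spec`.
#' @return Scalar volume, um^3.
#' @export
volume_um3 <- function(vol) prod(vol$extent)

#' Which layer hosts each population
#' @return Named character vector mapping population to layer name.
#' @keywords internal
population_layers <- function() {
  c(MF = "granular", GoC = "granular", GrC = "granular", MLI = "molecular",
    PC = "purkinje", DCNp = "nuclei", DCNi = "nuclei", IO = "olive")
}

#' The olivocerebellar connection table
#'
#' One row per connection type: source and target population (the granule-cell
#' axon is split into its ascending-axon, AA, and parallel-fiber, PF, branches;
#' CF denotes the inferior-olive climbing fiber), convergence and divergence
#' statistics (synapses per target / targets per source; `conv_sd = 0` marks a
#' fixed in-degree), peak synaptic conductance (nS), transmission delay (ms,
#' with a per-synapse SD only for the CF-MLI spillover pathway), alpha-kernel
#' time constant `tau_alpha` (ms), synaptic sign, and microcomplex confinement.
#'
#' Candidate presynaptic pools are geometric: `rule = "radial_xz"` keeps
#' sources within `reach` um of the target in the transversal plane,
#' `"axis_x"` keeps sources within `reach` um along x (parallel fibers run
#' along z, so a PF passes a target whose x is close to the source's),
#' `"cluster"` restricts to the target's microcomplex, `"all"` imposes no
#' geometry, and `"cf_assign"` is the balanced one-climbing-fiber-per-Purkinje
#' assignment with divergence bounded in [4, 8]. Reaches are package defaults
#' chosen so that every candidate pool exceeds the largest convergence draw;
#' they stand in for the axonal/dendritic intersection rules of the precursor
#' scaffold, which are not reproduced here.
#'
#' Gap-junction-like coupling in the GoC-GoC and MLI-MLI subnetworks is
#' approximated by fast chemical synapses with a 1-ms delay.
#'
#' @return A data.frame with one row per connection type.
#' @export
connection_table <- function() {
  tab <- rbind(
    data.frame(name = "MF-GrC",   pre = "MF",   post = "GrC",  src = "MF",
               conv_mean = 4,    conv_sd = 0,  weight = 0.15, delay = 4,
               delay_sd = 0, tau_alpha = 5.8,  sign = "exc", confined = FALSE,
               rule = "radial_xz", reach = 40),
    data.frame(name = "MF-GoC",   pre = "MF",   post = "GoC",  src = "MF",
               conv_mean = 65,   conv_sd = 27, weight = 1.5,  delay = 4,
               delay_sd = 0, tau_alpha = 0.23, sign = "exc", confined = FALSE,
               rule = "radial_xz", reach = 80),
    data.frame(name = "GoC-GrC",  pre = "GoC",  post = "GrC",  src = "GoC",
               conv_mean = 2,    conv_sd = 1,  weight = 0.6,  delay = 2,
               delay_sd = 0, tau_alpha = 13.6, sign = "inh", confined = FALSE,
               rule = "radial_xz", reach = 150),
    data.frame(name = "GoC-GoC",  pre = "GoC",  post = "GoC",  src = "GoC",
               conv_mean = 34,   conv_sd = 8,  weight = 0.3,  delay = 1,
               delay_sd = 0, tau_alpha = 10,   sign = "inh", confined = FALSE,
               rule = "radial_xz", reach = 250),
    data.frame(name = "AA-GoC",   pre = "AA",   post = "GoC",  src = "GrC",
               conv_mean = 360,  conv_sd = 81, weight = 1.2,  delay = 2,
               delay_sd = 0, tau_alpha = 0.5,  sign = "exc", confined = FALSE,
               rule = "radial_xz", reach = 60),
    data.frame(name = "PF-GoC",   pre = "PF",   post = "GoC",  src = "GrC",
               conv_mean = 1600, conv_sd = 0,  weight = 0.05, delay = 5,
               delay_sd = 0, tau_alpha = 0.5,  sign = "exc", confined = FALSE,
               rule = "axis_x", reach = 100),
    data.frame(name = "MLI-MLI",  pre = "MLI",  post = "MLI",  src = "MLI",
               conv_mean = 4,    conv_sd = 2,  weight = 0.2,  delay = 1,
               delay_sd = 0, tau_alpha = 2,    sign = "inh", confined = FALSE,
               rule = "radial_xz", reach = 60),
    data.frame(name = "PF-MLI",   pre = "PF",   post = "MLI",  src = "GrC",
               conv_mean = 1012.5, conv_sd = 221, weight = 0.015, delay = 5,
               delay_sd = 0, tau_alpha = 0.64, sign = "exc", confined = FALSE,
               rule = "axis_x", reach = 100),
    data.frame(name = "MLI-PC",   pre = "MLI",  post = "PC",   src = "MLI",
               conv_mean = 20,   conv_sd = 0,  weight = 0.3,  delay = 4.5,
               delay_sd = 0, tau_alpha = 2.8,  sign = "inh", confined = FALSE,
               rule = "radial_xz", reach = 100),
    data.frame(name = "AA-PC",    pre = "AA",   post = "PC",   src = "GrC",
               conv_mean = 249,  conv_sd = 13, weight = 0.7,  delay = 2,
               delay_sd = 0, tau_alpha = 1.1,  sign = "exc", confined = FALSE,
               rule = "radial_xz", reach = 30),
    data.frame(name = "PF-PC",    pre = "PF",   post = "PC",   src = "GrC",
               conv_mean = 28401, conv_sd = 776, weight = 0.007, delay = 5,
               delay_sd = 0, tau_alpha = 1.1,  sign = "exc", confined = FALSE,
               rule = "axis_x", reach = 150),
    data.frame(name = "PC-DCNp",  pre = "PC",   post = "DCNp", src = "PC",
               conv_mean = 26,   conv_sd = 2,  weight = 0.4,  delay = 4,
               delay_sd = 0, tau_alpha = 0.7,  sign = "inh", confined = TRUE,
               rule = "cluster", reach = NA),
    data.frame(name = "PC-DCNi",  pre = "PC",   post = "DCNi", src = "PC",
               conv_mean = 26,   conv_sd = 4,  weight = 0.12, delay = 4,
               delay_sd = 0, tau_alpha = 1.14, sign = "inh", confined = TRUE,
               rule = "cluster", reach = NA),
    data.frame(name = "MF-DCNp",  pre = "MF",   post = "DCNp", src = "MF",
               conv_mean = 147,  conv_sd = 0,  weight = 0.05, delay = 4,
               delay_sd = 0, tau_alpha = 1,    sign = "exc", confined = FALSE,
               rule = "all", reach = NA),
    data.frame(name = "CF-PC",    pre = "CF",   post = "PC",   src = "IO",
               conv_mean = 1,    conv_sd = 0,  weight = 350,  delay = 4,
               delay_sd = 0, tau_alpha = 0.4,  sign = "exc", confined = TRUE,
               rule = "cf_assign", reach = NA),
    data.frame(name = "CF-MLI",   pre = "CF",   post = "MLI",  src = "IO",
               conv_mean = 3,    conv_sd = 1,  weight = 1,    delay = 70,
               delay_sd = 10, tau_alpha = 1.2, sign = "exc", confined = TRUE,
               rule = "cluster", reach = NA),
    data.frame(name = "IO-DCNp",  pre = "IO",   post = "DCNp", src = "IO",
               conv_mean = 6,    conv_sd = 0,  weight = 0.1,  delay = 4,
               delay_sd = 0, tau_alpha = 1,    sign = "exc", confined = TRUE,
               rule = "cluster", reach = NA),
    data.frame(name = "IO-DCNi",  pre = "IO",   post = "DCNi", src = "IO",
               conv_mean = 6,    conv_sd = 0,  weight = 0.2,  delay = 5,
               delay_sd = 0, tau_alpha = 3.64, sign = "exc", confined = TRUE,
               rule = "cluster", reach = NA),
    data.frame(name = "DCNi-IO",  pre = "DCNi", post = "IO",   src = "DCNi",
               conv_mean = 6,    conv_sd = 0,  weight = 3,    delay = 20,
               delay_sd = 0, tau_alpha = 60,   sign = "inh", confined = TRUE,
               rule = "cluster", reach = NA)
  )
  tab$erev <- ifelse(tab$sign == "exc", 0, -80)
  tab
}

#' Reversal potentials by synaptic sign
#' @return Named numeric vector (mV): excitatory 0, inhibitory -80.
#' @export
reversal_potentials <- function() c(exc = 0, inh = -80)
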