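---
title: "Modeling olivocerebellar response dynamics with ocsnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling olivocerebellar response dynamics with ocsnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`ocsnn` builds and simulates a spiking model of two adjacent olivocerebellar
*microcomplexes*: paired cortical microzones (mossy fibers, granule and Golgi
cells, molecular-layer interneurons, Purkinje cells) with their target deep
cerebellar nuclei (projection neurons DCNp and GABAergic interneurons DCNi)
and the inferior-olive cluster that sends each microzone its climbing fibers.
The purpose of the package is to ask how much of the circuit's stereotyped
response dynamics — the Purkinje-cell *burst-pause* after a climbing-fiber
volley and the nuclear *pause-burst* that follows — depends on non-linear
single-neuron dynamics, by simulating the identical circuit twice: once with
extended generalized leaky integrate-and-fire (EGLIF) point neurons and once
with plain LIF neurons that share all passive parameters, synapses, delays
and weights.

## Geometry and connectivity

The cortical slab spans 400 x 330 x 400 um (x, depth y, transversal z), the
nuclear volume 200 x 600 x 200 um beneath it, and the olivary volume
100 x 200 x 40 um (cortical/olivary volume ratio 66:1, inside the
physiological 66-68 range). The census is fixed at 7073 mossy fibers, 219
Golgi cells, 88164 granule cells, 1206 molecular-layer interneurons, 69
Purkinje cells, 12 DCNp, 12 DCNi and 12 inferior-olive neurons — 96767
elements in total. Cortical somata are placed uniformly at random within
their sub-layer; olivary neurons by a self-avoiding bounded random walk
(step 10 um, reflecting boundaries, minimum separation two soma radii), with
the count implied by the olivary density of 15172 cells/mm^3; each DCNi is
dropped as a satellite of its DCNp at a distance between
`d1 = r_DCNp + r_DCNi` and `d2 = mean_dist/4 - r_DCNp - r_DCNi`. The slab is
split at z = 200 um into two microzones; deep-nuclei and olivary populations
are divided into two equal position-based clusters (median split along z,
ties by index; DCNi inherit their parent's cluster).

Connectivity is generated per connection type from convergence/divergence
statistics: a geometric candidate pool (radial reach in the transversal
plane, an x-aligned band for parallel fibers, the microcomplex for the
confined nucleo-olivary rows), then sampling without replacement to a fixed
or Gaussian-drawn in-degree. Reach defaults are package parameters chosen so
every pool exceeds the largest convergence draw; they stand in for the
axonal/dendritic intersection rules of the precursor scaffold pipeline,
which this package deliberately does not reproduce. Purkinje-to-nuclei,
olivo-nuclear, nucleo-olivary and climbing-fiber rows never cross
microcomplex labels; climbing fibers are assigned one per Purkinje cell with
divergence balanced into [4, 8]. The default build realizes ~4.20 M synapses
against the reference 4 151 182 (+1.3%), within the documented 2% band —
exact equality is not expected because the tabulated convergence means are
rounded and the precursor's geometric rules are replaced by reach-based
pools. One internal tension in the connection table is worth noting: the
tabulated CF-MLI divergence (115 ± 23) is inconsistent with its own
convergence (3 ± 1) given 1206 interneurons and 12 olivary cells; the
package enforces convergence and merely reports realized divergence (~300).
The basket/stellate sub-variants of the molecular-layer rows are folded into
a single MLI population: parallel-fiber convergence uses the mean of the two
tabulated means, and interneuron-to-Purkinje delays are drawn per synapse from
{4, 5} ms in equal proportion.

## Neuron models

Subthreshold EGLIF dynamics are linear in `(V_m, I_adap, I_dep)`:

- `C_m dV/dt = -C_m/tau_m (V - E_L) - I_adap + I_dep + I_e + I_syn(t)`
- `dI_adap/dt = k_adap (V - E_L) - k_2 I_adap` (voltage-coupled adaptation;
  incremented by `A_2` at each spike)
- `dI_dep/dt = -k_1 I_dep` (depolarizing spike-triggered current; set to
  `A_1` at each spike)

with stochastic spiking from an exponential escape rate
`lambda(V) = lambda_0 exp((V - V_th)/delta_V)`. Because the system is
linear, the per-step update uses the exact matrix exponential (computed once
per population from the augmented 6 x 6 exponential), making subthreshold
propagation step-size invariant. The LIF variant zeroes the two currents and
replaces escape noise with a deterministic threshold; passive parameters are
shared between the two models and only the endogenous current is retuned so
isolated tonic rates match.

Voltage-coupled adaptation is what carries the biphasic responses: a strong
conductance volley drives a spike burst whose accumulated `A_2` increments
silence the cell afterwards (burst-pause), while hyperpolarization drives
`I_adap` negative so that the release of inhibition overshoots (rebound),
amplified by the fast depolarizing current `A_1` during the restart
(pause-burst). None of these mechanisms exist in the LIF variant, which is
the point of the comparison.

## Synapses and the engine

Transmission uses alpha-shaped conductance-based synapses,
`g(t) = w (t/tau_alpha) exp(1 - t/tau_alpha)`, peaking at exactly `w` nS at
`t = tau_alpha`, with reversal potentials 0 mV (excitatory) and -80 mV
(inhibitory). The engine keeps one two-state alpha filter per (connection
row, postsynaptic neuron) — kernel linearity makes per-synapse filters
redundant — and propagates the filters exactly, which handles sub-step time
constants (down to 0.23 ms) without lookup tables. Delays are rounded to the
nearest step (minimum one); the climbing-fiber-to-interneuron spillover
pathway draws per-synapse delays from Normal(70, 10) ms at build time; the
1-ms delays in the Golgi and interneuron subnetworks approximate gap
junctions with fast chemical synapses. Synaptic weights are read as
per-synapse peak conductances.

Two numerical choices deserve emphasis. First, the synaptic current is
frozen at the step start, which is exact for the linear part but can
overshoot a reversal potential when the total conductance is large relative
to a neuron's capacitance (granule cells have 3 pF); whenever
`G dt / C_m > 0.2` the neuron's update is split into `2^k` exact sub-steps
(k <= 6) with the current re-evaluated from the updated voltage. Without
this, synchronized inhibitory volleys destabilize the granular layer at the
default 1-ms resolution. Second, spikes are emitted at most once per step
per neuron, capping instantaneous rates at `1000/dt` Hz; the default
`dt = 1` ms (configurable to 0.1 ms) matches the stimulation protocol's
resolution.

## Stimulation protocol

The default eyeblink-conditioning-like schedule: 1 s of 4-Hz Poisson
background on all mossy fibers; a conditioned stimulus (light) as a 40-Hz
Poisson train over [1000, 1260) ms on a mossy-fiber bundle inside a
cylinder of radius 150 um at the center of the transversal plane (height
150 um, the full granular depth); an unconditioned stimulus (air puff) as a
regular 500-Hz, 10-ms burst co-terminating with the conditioned stimulus,
injected by forcing spikes of microcomplex-1 inferior-olive neurons so that
both climbing-fiber pathways (to Purkinje cells, and with spillover delays
to the interneurons) carry it; then 500 ms of silence. The burst is regular
rather than Poisson because a 10-ms, 500-Hz "burst" reads as a
deterministic volley; this is configurable. Membrane potentials are
initialized uniformly between each population's resting and threshold
potential to avoid artificial onset synchrony, in both network variants.
Four independent seed streams (placement, connectivity, initialization,
simulation) keep structural and dynamical stochasticity separable; the
default experiment reuses one network across the five simulation seeds.

## Analysis

Population activity is summarized as peristimulus time histograms (5-ms
bins) and Gaussian-kernel instantaneous rates (5-ms kernels for Purkinje
cells, 10-ms for nuclear cells; kernels truncated at four sigma and
renormalized by in-support mass so each spike contributes unit area). The
response-speed statistic locates the maximum and minimum of a rate trace in
the 100-ms window starting 5 ms after the climbing-fiber burst onset and
reports `(max - min)/(t_max - t_min)`: negative when the maximum precedes
the minimum (burst-then-pause) and positive for the reverse order
(pause-then-burst); a flat trace gives zero by convention. Speeds are
computed per neuron (the defining formula) and also from the population-mean
trace, since the two weight noise very differently at small population
sizes. Group comparison uses a Welch two-sample t-test on per-neuron speeds
pooled across simulations. The eyeblink readout decodes each microcomplex's
DCNp spikes with an update-and-decay rule (update 1.0 per spike, 10-ms decay
constant), smooths with a 50-sample moving average (50 ms at the default
resolution; configurable), and combines the microcomplexes as a
baseline-subtracted sum (a difference mode is selectable).

# Placeholder electrophysiology and what the tests show

Published per-population EGLIF parameter sets for this class of model are
not redistributed here. The package instead ships a
*synthetic placeholder* parameter table
(`inst/extdata/neuron_params_synthetic.csv`), produced by its own
autorhythm-tuning routine (`tune_intrinsic_current`, monotone bisection over
the endogenous current against simulated tonic rate, alternated with a
bisection on the escape-noise sensitivity against the interspike-interval
coefficient of variation). Calibration targets are the operating points the
circuit is documented to express: isolated Purkinje cells at 85 Hz with
CV = 0.2, nuclear projection neurons at 65 Hz (realized CV 0.18), Golgi
cells at 8 Hz, interneurons at 12 Hz, granule cells silent at rest, and the
qualitative phenotypes (Purkinje burst-pause, nuclear rebound) through the
adaptation and rebound currents described above. Passive values are
plausible for each cell class but are not measurements; anyone holding a
published parameter set can substitute their own CSV with the same columns.

Two consequences of the placeholder route are documented rather than hidden.
The LIF inferior-olive current is set subthreshold instead of tuned to ~1 Hz:
a deterministic-threshold neuron near 1 Hz sits on a knife edge (its rate
jumps from 0 to ~8 Hz within a tenth of a picoampere), and the marginal
current locks a network-wide disinhibition loop; the LIF olive's only role in
the protocol is carrying the forced burst. And the quantitative speed means
reported for fully fitted parameter sets are not reproducible without those
parameters: with the placeholder set the EGLIF-vs-LIF Purkinje contrast is
-10.4 vs -3.4 Hz/ms (p < 1e-70, pooled per-neuron n = 155 per group), and
the nuclear contrast preserves sign and ordering (+0.81 vs +0.49 Hz/ms) but
not per-neuron significance — six projection neurons per microcomplex leave
10-ms-kernel single-neuron traces noise-limited. The qualitative dichotomy
is robust across seeds: the EGLIF nuclear population dips and then rebounds
above baseline (rebound-window mean 1.08-1.13x baseline) while the LIF
population restarts synchronously without a rebound (0.73-0.79x); the LIF
Purkinje burst is not followed by a pause. The decoded eyeblink transient,
whose sharpness contrast depends on the same rebound magnitude, is computed
and written by the pipeline but its model contrast is not asserted.

What passing tests do show: the scaffold's structural contract is exact
(census, satellite geometry, confinement, fixed in-degrees, synapse total
within 2%); subthreshold integration is exact to 1e-9 against an adaptive
ODE oracle; synaptic kernels match their closed forms to numerical
precision; the protocol and analysis operations match hand-computable
oracles; and runs are byte-reproducible given seeds. What they cannot show:
fidelity of the absolute response magnitudes to a fully fitted
parameter set, or anything about biological data beyond the
constraints listed above. The synthetic network emulates the reference
circuit's geometry, census and synaptic parameters; it does not emulate
morphology-derived connectivity microstructure, synaptic plasticity,
dendritic non-linearities, or true gap-junction coupling.

Problem sizes used by the test-suite and the acceptance script: the full
96767-neuron network is built once; single-neuron calibrations use 20-s
isolated simulations; network statistics use five paired 1.76-s EGLIF/LIF
simulations at 1-ms resolution on one network instance. Unit tests run on
reduced networks from `make_toy_network()` (2% scale, convergences clipped
to feasible pools).

# A short tour

```{r}
library(ocsnn)

net <- build_network(seed_placement = 1, seed_connectivity = 2)
connectivity_report(net)

par <- default_neuron_params()
spikes <- run_simulation(net, par, ebcc_protocol(), model = "eglif", seed = 201)

psth(spikes, "PC", network = net, bin = 5, microcomplex = 1)
population_speeds(spikes, net, "PC", microcomplex = 1)

# or end-to-end with artifacts on disk:
res <- run_experiment(default_config(), out_dir = "ocsnn_run")
```

# Known limitations

- Convergence statistics are enforced; geometric microstructure within the
  candidate pools is uniform, so higher-order connectivity motifs of the
  precursor scaffold are not reproduced.
- Gap junctions and spillover are delay-based approximations; no
  bidirectional electrical coupling.
- No synaptic plasticity; the protocol covers a single pre-learning trial.
- At `dt = 1` ms each neuron spikes at most once per step; complex-spike
  spikelet counts saturate accordingly (use `dt = 0.1` ms to relax this at
  10x cost).
- The placeholder electrophysiology reproduces documented operating points
  and phenotypes, not the reference parameter values; absolute response
  magnitudes shift accordingly.
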