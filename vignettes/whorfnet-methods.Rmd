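---
title: "Model and methods: simulating color-label learning in a brain-constrained network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: simulating color-label learning in a brain-constrained network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

whorfnet simulates how learning color words shapes the cortical
representation of color. Two color categories (blue, green), each with a
light and a dark shade, are learned perceptually by a spiking network of
twelve cortical areas; the network is then duplicated and the copies
learn color terms under two naming systems — a one-label system in which
both shades of a color share a word (as English does for blue), and a
two-label system in which the two blue shades receive distinct words (as
Russian goluboj/sinij). The package measures how the naming system
reshapes the neural representations: representational dissimilarity,
shared versus shade-unique assembly neurons, and a mismatch-negativity
proxy built from unique-neuron spiking.

## The network

Twelve areas model the ventral visual stream (V1, TO, AT), the lateral
motor stream (PFL, PML, M1L), an auditory stream (A1, AB, PB) and an
articulatory stream (PFi, PMi, M1i). Each area is a 25 x 25 grid of
excitatory cells — one leaky integrate-and-fire cell with adaptation per
cortical microcolumn — paired with one graded-response inhibitory cell
per column, 15,000 cells in total. Adjacent areas within a stream are
reciprocally linked, the four multimodal hubs (AT, PFL, PB, PFi) form a
complete subgraph, and each primary area carries a non-adjacent
"jumping" link to its stream's hub. Synapses are sampled from clipped
Gaussian kernels over topographically aligned neighborhoods: within-area
excitatory links with center probability 0.28 and sigma 6.5 in a 19 x 19
square, between-area links with 0.15 and sigma 4.5, and the local
excitatory/inhibitory loop with 0.295 and sigma 2.0 in a 5 x 5 square.
Grids are toroidal by default so border cells are not under-connected
(`torus = FALSE` selects clipped borders).

Per timestep (explicit Euler, dt = 1 step) each excitatory cell updates

    tau_e dV/dt = -V + [ sum_y w_xy phi(y) ] + k1 (Inp - k_G omega_G + k2 eta)

with binary output `phi = 1` iff `V - alpha omega > thresh`, adaptation
`tau_adapt d omega/dt = -omega + phi`, a low-passed rate estimate
`tau_favg d omega_E/dt = -omega_E + phi`, and per-area global inhibition
`tau_glob d omega_G/dt = -omega_G + sum_area phi`. Inhibitory cells
integrate their local excitatory input with `tau_i` and emit the
rectified membrane potential. The stage order within a step is fixed:
net input from the previous step's outputs, membrane integration,
outputs, trace updates, then (during learning) plasticity.

### The input-scaling convention

The defaults follow the published constants: tau_e = 2.5, tau_i = 5
steps, k1 = 0.01, k2 = 3 sqrt(24 / 0.5) ~ 20.78, k_G = 0.73,
thresh = 0.18, alpha = 7, tau_adapt = 10, tau_glob = 12, Inp = 700 per
stimulated cell. One structural decision deserves emphasis: the package
treats synaptic weights as *effective couplings* — the weight sum enters
the membrane equation directly, while the scaling constant k1 rescales
the external drive, the global-inhibition term and the noise. Applying
k1 to the weight sum as well, with weights initialized in [0, 0.1] and
clipped near 0.2, yields a provably dead network: the largest attainable
synaptic drive (every in-neighborhood link saturated and firing) stays
below the spiking threshold, so no activity can ever propagate between
areas. Under the effective-coupling convention every published constant
works as printed, and the threshold layout becomes meaningful: the
maximal noise excursion of a free cell is k1 k2 / 2 ~ 0.104, just below
the homosynaptic-LTD threshold 0.14 — membrane noise alone never fires a
cell and never triggers plasticity, which is evidently how the constants
were calibrated. The corridor between the LTP threshold (0.15) and the
spiking threshold (0.18) is where learning starts: weak convergent input
plus noise can depolarize a cell enough to learn before it is strong
enough to fire.

Noise `eta ~ U[-0.5, 0.5]` is drawn freshly for every excitatory cell at
every step (inhibitory cells receive none); it is present during
learning and, by default, during the extraction and recognition probes
(`noise = FALSE` gives fully deterministic probes — useful for testing,
and numerically almost identical because the noise is subthreshold).

### Plasticity

Excitatory-to-excitatory links are plastic under a discretized
Artola-type rule driven by the presynaptic rate estimate `r` and the
postsynaptic membrane potential `v`: LTP (`+0.008`) when `r >= 0.15` and
`v >= 0.15`; homosynaptic LTD (`-0.008`) when `r >= 0.15` and
`0.14 <= v < 0.15`; heterosynaptic LTD (`-0.008`) when the input is
silent (`r < theta_zero`) and `v >= 0.15`; otherwise no change. Weights
are clipped to `[0, w_max]`.

The package resolves the rule's presynaptic structure as *three-zone*:
`theta_pre = 0.15` is the output required for LTP, and heterosynaptic
LTD befalls only truly silent inputs (`theta_zero = 0.05` by default),
leaving a neutral band in between. The two-zone alternative — in which
any input below `theta_pre` is depressed whenever its target is strongly
depolarized — is available by setting `theta_zero = theta_pre`, but it
cannot support the phenomena the model exists to produce: with
adaptation strength 7, a synaptically driven cell fires at a duty cycle
of 10–25%, so its rate estimate spends most of the stimulation period
below `theta_pre`; under the two-zone rule every relay synapse between
two synaptically driven populations (hub to hub, secondary to hub) is
then depressed faster than coincidence can potentiate it, no
cross-modal association can form, and the one-label and two-label
models remain exactly identical in every readout. In the three-zone
reading, moderately active inputs are protected, fully silent inputs are
still pruned (which keeps assemblies apart), and label-color binding can
develop.

The plasticity rule's presynaptic eligibility uses the fast rate
estimate (`tau_favg_plasticity`, default 5 steps, the same constant the
assembly-extraction procedure uses): a single spike then raises the
estimate to 0.2 > `theta_pre`, so any recently spiking cell can teach
its efferents for the next couple of steps. With the slow estimate
(tau = 30) a cell must fire on roughly half the steps of a 16-step trial
before it becomes eligible, which the adaptation makes impossible for
every cell that is not driven externally — recruitment into an assembly
would then be possible, but no recruited cell could ever extend the
assembly further.

### Free magnitudes

Two magnitudes are not fixed by the published constants and were set
once, on dynamical grounds:

- `w_init_max = 0.07`. Initial weights are uniform on
  `[0, w_init_max]`. The corridor requirement is that two or three
  convergent initial links plus a favorable noise excursion can cross
  the LTP threshold (bootstrap) but not the firing threshold (no
  avalanche in the naive network): `theta_plus < 2 w_mean + 0.104 <
  thresh`. An upper bound of 0.1 violates the right inequality — two
  maxed initial links alone exceed the firing threshold and the naive
  network ignites area-wide on the first stimulus.
- `w_inhib_max = 1`. The published initialization range covers
  excitatory links; the local excitatory/inhibitory loop needs
  functional strength to act as lateral competition. Without it,
  assemblies either merge into one global attractor or (with the
  competition replaced by a lower weight ceiling) never extend beyond
  the stimulated area. The value sets the uniform initialization range
  of the non-plastic e-to-i and i-to-e couplings.

The weight ceiling `w_max` (default 0.225) is the published clip of the
predecessor architecture; with effective couplings it also sets the
relay property that one saturated link plus noise can fire a silent
cell, which is what lets a learned assembly re-ignite across areas
during extraction.

## Stimuli

All inputs are synthetic 22-cell binary patterns (3.5% of an area's 625
cells). The four color patterns target V1 and carry the prescribed
similarity structure: the two shades of one color share
`round(0.228 * 22) = 5` cells (22.7% realized), and every blue/green
shade pair shares `round(0.05 * 22) = 1` cell (4.5% realized), drawn
outside the within-color overlaps so the four-set Venn structure stays
simple. The three word forms are pairs of 22-cell patterns over A1
(auditory) and M1i (articulatory), pairwise disjoint within an area —
the strongest reading of "no structural similarity". Patterns are
deterministic in their seed and shared by all network instantiations,
mimicking learners exposed to one common world.

During learning, non-relevant primary areas receive a fresh uncorrelated
drive every trial. The default form is a new random 22-cell pattern at
full input strength, structurally matched to the learned stimuli; a
`"spread"` alternative distributes the same total budget uniformly over
the area. The matched form is the default because the spread form
depolarizes a large fraction of the area past the LTP threshold on every
trial, and the resulting heterosynaptic pruning pressure erases the very
assemblies the drive is meant to discipline.

## Protocols

Phase 1 (perceptual/babbling): the 4 color patterns and 3 word-form
pairs (auditory and articulatory halves simultaneously) are presented
separately, 1000 randomized trials each at full scale. A trial is: reset
of all membrane potentials, 16 stimulation steps, then an inter-stimulus
interval of up to 30 steps that ends early once the global inhibition of
V1, TO, AT and PFL all fall below 0.55. Noise drives go to the
non-relevant primaries (A1, M1i, M1L during color trials; V1, M1L during
word trials). Plasticity is active throughout learning trials; traces
persist across the reset (only membrane potentials are zeroed, read
literally from the protocol; a full reset is available behind a flag).

Phase 2 (semantic): each color is co-presented with its mapped word
(V1 + A1 + M1i) under the language's mapping, 1000 randomized trials per
pairing at full scale, with noise to M1L. The English-like mapping uses
2 words (one per color), the Russian-like mapping 3 (distinct words for
the blue shades). Both language branches start from the byte-identical
phase-1 snapshot.

Extraction reactivates a trained network with one color pattern for 16
steps from a fully zeroed state, plasticity frozen, no drives elsewhere,
and records every cell's fast rate estimate over the 30 post-stimulation
steps. Recognition records spikes over a 40-step window (10 baseline, 2
stimulation, 28 post-offset), matching the neurophysiological protocol.

## Analyses

- Cell assemblies: per area, the membership threshold is `gamma` times
  the peak rate estimate over cells and the 30 post-stimulation steps
  (`gamma = 0.5` default; `0.2` implements the 20%-of-peak
  responsiveness rule, and `gamma = 0.5` members are always a subset of
  `gamma = 0.2` members). Areas whose peak stays below 0.2 contribute no
  members.
- RSA: per region, activation vectors are the unthresholded per-cell
  mean rates over the window; representational dissimilarity matrices
  are pairwise Euclidean distances over the four color stimuli. Region
  groupings (visual, auditory, articulatory, the four hubs, and the 10
  relevant regions — all but the lateral motor PML/M1L) collapse by
  averaging per-region distances (`mode = "concat"` measures distance in
  the concatenated space instead). Averaging regions before or after
  averaging networks commutes; the package averages regions first.
- Neuron types: per region, shared neurons belong to both shade
  assemblies of a color, unique neurons to exactly one; sharedness is
  `shared / (shared + unique) * 100`.
- Mismatch-negativity proxy: spikes among the presented shade's assembly
  cells (`Rtot`) minus spikes among cells in both shade assemblies
  (`Rshared`) give the unique response `uniqueR`, summed over the 10
  relevant regions (per-area traces available). The statistics window is
  the 10 steps starting 2 steps after stimulus offset (the quoted
  "2–12 simulation steps" span 11 step indices; the 10-step reading
  drops the last).
- Exclusion: a network is dropped when two color assemblies exceed a
  Jaccard overlap of 0.8 over the relevant regions (assembly merging) or
  when one stimulus recruits more than half of any area (activation
  spread). The thresholds are package choices — the study reports the
  phenomenon but no numbers — and are exposed as arguments.

The hub grouping is {AT, PFL, PB, PFi}; the methods' listing is taken
over the results section's variant that swaps AB in for PB, because AB
is a secondary auditory area, not a hub. A repeated-measures ANOVA
wrapper (`anova_dissimilarity()`) over model type and color is provided
for description only; desk-scale runs do not license the published
inferential statistics.

## Scale, determinism, and what the tests show

The full published protocol (16 networks, 1000 trials per stimulus,
11,000 learning trials per network) runs in a few hours on one core. The
package's own validation experiments use a reduced protocol — 4
networks, 300 phase-1 trials per pattern, 300 phase-2 trials per
pairing — chosen so a complete pipeline (both language models, all
probes) finishes in minutes while the qualitative contrasts remain
measurable. Every random choice descends from one master seed through
named sub-seeds, so any run is exactly reproducible; the compiled engine
is verified step-for-step against a scalar R reference implementation on
small circuits.

The synthetic stimuli emulate the prescribed overlap structure, not
color vision: there is no wavelength, hue or luminance encoding
(deliberately outside the model's design), no temporal misalignment of
word and referent, and single-trial binary patterns stand in for the
graded, context-rich input of real perception. Passing tests therefore
show that the mechanism — overlap-structured perceptual input plus
label-structured co-activation under competitive Hebbian learning —
produces the claimed representational reorganization in this idealized
setting; they say nothing about real cortex beyond the model's
assumptions. Known limitations: the adaptation constant caps firing duty
cycles well below biological burst rates, which makes reverberant,
area-wide assembly ignition dynamically impossible in this
implementation — responses are brief feed-forward bursts, and label
feedback into the visual system is correspondingly weak. At the
validation scale the consequences are systematic, as the acceptance
tests make explicit: the two-label contrasts reproduce (the distinctly
labeled blue pair grows more dissimilar than the one-label blue pair in
every retained network, the green pairs stay matched, the two-label
blue assemblies are dominated by shade-unique neurons, the two-label
blue pair moves apart from the perceptual baseline in the visual system
while the two-label green pair moves together, and the
mismatch-negativity contrast is larger under two-label naming), but the
same-label *convergence* effects do not: shared neurons never come to
outnumber unique neurons for same-label pairs, blue-shade sharedness in
secondary visual areas stays near 40% rather than under 25%, and the
one-label visual dissimilarities barely move. All of these require
massive word-circuit reactivation feeding back into vision, which the
burst-limited dynamics cannot supply. The inhibitory loop is
non-plastic, axonal delays are absent (one-step transmission), and at
the reduced scale assemblies are tens of cells per area, so
network-to-network variability is substantial and individual networks
can fail to show an effect that holds in the mean.
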