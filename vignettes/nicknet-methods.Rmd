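---
title: "Methods: simulating neural computation on nicked DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating neural computation on nicked DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicknet)
```

## The model

nicknet simulates a molecular neural engine in which numbers live in test
tubes. A value $x \in [0,1]$ is stored as the *fraction* of double-stranded
template molecules that carry a nick (a single-strand backbone break) at a
designated site: if $C_0$ is the overall template concentration and $C_1$
the concentration nicked at the site, the stored value is $x = C_1/C_0$.
This is the molecular analogue of stochastic logic, where a value is the
fraction of 1s in a random bitstream, and it inherits that framework's
arithmetic: an AND of two independent stochastic values multiplies them.

Each template has two neighbouring nick sites, A and B. Encoding $a$ at A
(by splitting the solution $a : 1-a$, nicking one part, and remixing) and
$b$ at B independently leaves four molecule species with fractions

$$(1-a)(1-b), \quad a(1-b), \quad (1-a)b, \quad ab,$$

so the doubly nicked species *is* the product $ab$ — a fraction of a
fraction. Readout exploits the geometry: the two nicks must sit within
about 18 bp of each other, so gentle heating denatures only the short
fragment between them, exposing a toehold exclusively on doubly nicked
molecules. Excess probe strands displace that fragment
(toehold-mediated strand displacement), magnetic beads pull down everything
still attached to a template, and the free ssDNA count equals the $ab$
count.

A dot product is a row of such multiplications. In a $k \times k$ valved
microcell array, row $i$ holds neuron $i$: cell $(i,j)$ mixes a DNA droplet
encoding input $x_j$ with an enzyme droplet whose concentration encodes
weight $w_{ij}$ via the dosing rule $E = b\,t\,(1/k)$ ($t$ molecules per
droplet, each enzyme nicking $k$ strands). Merging the row's $k$ droplets
adds fragment counts and totals, so the merged fraction is the
$1/k$-normalised dot product $\tfrac1k \sum_j w_{ij} x_j$. Activation is a
seesaw-gate cascade: a threshold strand consumes input ssDNA below a
user-set transition point $\theta$, and excess replenishment strands
amplify any surviving signal to a saturated output — a step function on
$(0,1)$, optionally capped below 1 by limiting replenishment. A final
translation reaction releases one nicking enzyme per output strand, which
nicks a fresh pool at site A, re-encoding the activated value as the next
layer's input.

## Fidelity modes

Every chemical container runs in one of two modes.

* **ideal** — species are real-valued fractions and every operation is
  exact algebra. `measure(both)` after encoding $a$ and $b$ equals $ab$ to
  machine precision; a whole network run equals a directly computed
  step-activation MLP.
* **sampled** — a pool is an integer population of `t` molecules and every
  nick is an independent, seeded Bernoulli draw, so the doubly nicked count
  is Binomial$(t, ab)$ and all downstream quantities carry the counting
  noise a finite droplet would. Splitting a droplet partitions each species
  multinomially.

The ideal mode is the specification against which the sampled mode's
convergence is tested (mean absolute output error is non-increasing in
$t$ over $10^2, 10^3, 10^4$ in the shipped tests). Independence of the two
nick events is enforced by construction — each site's draw is a separate
per-molecule Bernoulli — which is exactly the assumption under which the
four-species distribution above holds.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `t` | molecules per unit droplet (sampled mode) | 10^4 | counting noise $\sigma \approx \sqrt{p(1-p)/t} \le 0.5\%$, small but visible |
| `threshold` | seesaw transition point $\theta$ | 0.5 | centre of the normalised pre-activation scale |
| `replenishment_cap` | output saturation $\rho$ | 1.0 | excess replenishment (full amplification) |
| `turnover` | strands nicked per enzyme $k$ | array dimension for engine doses; explicit elsewhere | the $1/k$ dosing compensation |
| `max_toehold_gap` | largest nick separation that denatures | 18 bp | fragment must melt under gentle heat |
| `t_transport` | droplet transport per pass | 2 min | the only independently estimated stage time |

Thresholds are always interpreted on the $1/k$-normalised pre-activation
scale (`pre = (1/n_in) * w.x`). Without this convention the same weights
would mean different things on arrays of different width; with it, a
compiled network is portable across device configurations, and the array
width enters only through serialization and timing.

## Scheduling and traces

Droplet logistics are modelled as a discrete-event state machine, not a
fluid simulation. A microcell cycle is six steps — route flow left (L open,
R closed); DNA droplet parks left; valves swap; enzyme droplet parks right;
both valves open; both droplets exit and mix — and the row merge is two
valve phases (Y open/Z closed rightward flow, then Y closed/Z open upward
merge). Every operation emits a tidy trace tibble recording valve states
and droplet movements, and the state machine refuses any movement through
a closed valve, so protocol safety is a testable property rather than a
drawing. Transport time is a fixed per-pass latency; the laminar/diffusive
flow regime that motivates it is not parameterised.

`execute_layer()` and `run_network()` perform the same pool algebra in
vectorised form (matrices of species fractions, or binomial draws per
cell) rather than looping over droplet objects; the per-droplet operations
(`microcell_cycle()`, `row_merge()`, `reaction_pipeline()`,
`split_droplet()`) are first-class and the property suite replays their
traces. The two paths are algebraically identical, and the equivalence is
pinned by tests that compare an engine layer against the droplet-level
chain and against an independently coded reference network.

## Serialization

A layer wider than the physical array runs in passes. Computationally,
`ceiling(input_dim / k_physical)` passes accumulate partial fragment
counts in an external reservoir, and one activation closes the layer —
so serialized and full-width execution give identical outputs. For
*timing*, the per-stage serialization factor follows the published
accounting: each stage of the network (the input-encoding stage of width
`input_dim`, then each layer of width `n_neurons`) contributes
`ceiling(width / k_physical)` passes. A 784-784-10 network therefore has
stage factors (4, 4, 1) on a 196-wide array and (196, 196, 3) on a 4-wide
array. The two notions coincide for the square hidden layer and differ
only for the narrow output layer, where the published accounting charges
the passes to the stage that produced the 784 inputs rather than to the
10-neuron consumer; we follow it as the device's cost model.

## The latency and area models

The factor-1 layer latency decomposes as
$t_\mathrm{layer} = t_\mathrm{transport} + t_\mathrm{mult} +
t_\mathrm{merge} + t_\mathrm{activation}$, with the activation further
split into displacement, threshold, gate, translation and nicking stages.
Serialized execution repeats only the transport and multiplication per
pass:

$$t_\mathrm{layer} = \left\lceil \frac{k_\mathrm{layer}}{k_\mathrm{physical}} \right\rceil (t_\mathrm{transport} + t_\mathrm{mult}) + t_\mathrm{merge} + t_\mathrm{activation} = f\,A + B.$$

Only the grouped constants $A$ and $B$ are identifiable from published
latency totals, and `calibrate_timing()` fits them by least squares; with
the two published points $(f=1, 8.07\,\mathrm{h})$ and
$(f=4, 14.17\,\mathrm{h})$ the solve is exact:
$A = 6.1/3 \approx 2.033$ h per pass, $B \approx 6.037$ h. The default
stage split underneath ($t_\mathrm{mult} = A - 2\,\mathrm{min}$,
$t_\mathrm{merge} = 0$, all of $B$ in the gate stage) is a transparent
convention, flagged `unconstrained`, because no individual stage times are
published. Evaluated at the remaining configurations the model gives
38.57, 105.67 and 404.57 h against published 38.6, 105.6 and 404.6 h; the
published rows are mutually inconsistent at $\pm 0.1$ h under any single
$(A, B)$ (presumably author-side rounding), so the package's own
acceptance tests use a $\pm 0.15$ h band rather than printed precision.

Area scales quadratically: a cell occupies $m$ channel widths per side, so
a $k \times k$ array occupies $(m\,c\,k)^2$. The pessimistic preset
($c = 200\,\mu m$, $m = 6$: two channel tracks per axis plus a separation
track, each double-width) gives $1.44\,k^2$ mm²; the optimistic preset
($c = 35\,\mu m$, $m = 3$) is published rounded to $0.01\,k^2$ mm², and we
adopt that rounded coefficient as the default so reported areas match the
published table cell-for-cell, keeping the exact $(3 \times 0.035)^2 =
0.011025$ available via `area_optimistic(use_printed = FALSE)`. Report
rounding is two decimals, falling back to three when two would print a
positive area as zero (the 4 × 4 optimistic cell, 0.002 cm²).

```{r perf}
fit <- calibrate_timing(reference_delay_points())
glance(fit)
config_report(fit)
```

## The synthetic-data generator

The package ships no external data. `generate_fixture_mlp()` draws weight
matrices uniform on $[0,1]$ — already in the engine's representable range,
so compilation is the identity — and `generate_toy_digits()` paints binary
28 × 28 stroke patterns (bars, cross, box, diagonal) with positional
jitter as a stand-in for handwritten-digit frames. These emulate the
*shape* of the real workload: nonnegative bounded weights, sparse binary
784-pixel inputs, a 5-way argmax readout. They do not emulate trained
structure — there is no learned correlation between weights and strokes,
no class imbalance, no grey levels — so passing tests demonstrate that the
engine computes its defining algebra exactly and converges with molecule
count, not that any particular accuracy would be achieved on real
handwriting. The published classification accuracies (96% digit, 90% text)
depend on externally trained weights and an architecture that are not
published, and are therefore documented but not reproduced; users with
their own trained weights can run them through `read_idx()` /
`read_weights_csv()` and the ordinary compile/run path.

## Numerical choices

* **Compilation.** Negative raw weights are clipped to zero (count
  reported per layer); a layer is rescaled only when its maximum exceeds 1,
  so fixtures already in range compile to themselves. An all-zero layer
  warns rather than errors.
* **Step boundary.** `seesaw_activate()` outputs 0 at $u = \theta$ exactly
  (the threshold strand consumes a matching input completely); the output
  is `min(replenishment_cap, gate_supply)` strictly above.
* **Rounding.** Sampled-mode deterministic sub-operations round half away
  from zero and repair the largest class so molecule counts are conserved
  exactly; conservation outranks rounding symmetry.
* **Ceilings.** Serialization ratios always use `ceiling()`; all published
  configurations either divide evenly or match the ceiling (e.g.
  $\lceil 10/4 \rceil = 3$).
* **Seeds.** Every stochastic operation takes an explicit seed
  (`withr::with_seed`, so the global RNG state is untouched) and pools
  record their seed lineage. Engine runs derive per-layer seeds by offset
  from one run seed.
* **Degenerate inputs.** $k = 1$ arrays (scalar engines) are permitted;
  empty pools refuse measurement; a nick pair wider than the toehold gap
  refuses readout at toehold creation, before any displacement happens.

## Test problem sizes

The shipped suite checks the exact-product grid at 101 × 101 values,
sampled binomial moments at $t = 10^4$ over 200 replicates, the gate
algebra against bitstream Monte Carlo of length $10^5$ on a 21 × 21 grid,
engine/reference equivalence on 50 random networks with layer widths up to
16, and sampled-mode convergence over $t \in \{10^2, 10^3, 10^4\}$ with
100 trials per level. These sizes make the suite exhaustive for the
algebra (which is exact, so scale adds nothing) while keeping the
stochastic checks at 4-standard-error resolution.

## Known limitations

* No reaction kinetics: every operation is an endpoint. Insufficient
  reaction time is an error, not a partial product; the seesaw cascade is
  its fixed point, with the logistic variant provided only as a
  smooth-response convenience.
* No leakage or secondary-structure failure modes: these are documented
  hazards of strand-displacement systems, listed qualitatively in the
  source material without a quantitative model, so the simulator exposes a
  displacement-efficiency multiplier for exploration but models no leak
  reactions.
* No thermodynamics: toehold formation is a boolean gated by the nick-pair
  distance, not a melting-temperature calculation, and generated template
  sequences are constraint-checked placeholders, not designed orthogonal
  libraries.
* No hydrodynamics: transport is a constant per pass; channel geometry
  enters only through the area model.
* No training: weights arrive trained (or synthetic); variability-driven
  on-line training is out of scope.
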