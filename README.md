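# nicknet

A desk-scale simulator of a DNA neural engine: an architecture for running
artificial-neural-network inference directly on data stored in DNA, inside
a droplet-microfluidic lab-on-chip, with no electronic readout in the loop.

**Who it is for.** Molecular-programming and DNA-storage researchers who
want to explore the design space of this architecture — fidelity versus
molecule count, activation thresholds, device size versus latency — without
a wet lab, and to check the architecture's published performance envelope
from its closed-form models.

## The idea in one paragraph

A value `x ∈ [0, 1]` is stored as the fraction `C1/C0` of double-stranded
template molecules nicked at a designated site (a nick is a single-strand
backbone break; the duplex holds together). Encoding `a` at site A and `b`
at a neighbouring site B by *independent* nicking leaves the doubly nicked
species at fraction `a·b` — multiplication for free, exactly as an AND gate
multiplies independent stochastic bitstreams. Gentle heat denatures only
the short fragment between the two nicks, creating a toehold exclusively on
`a·b` molecules; probe strands displace that fragment and bead pull-down
isolates it, reading the product out as ssDNA. A `k × k` valved microcell
array performs a matrix–vector product: each row mixes input droplets with
weight-enzyme droplets dosed as `E = b·t·(1/k)`, merges the row into the
`(1/k)`-normalised dot product, thresholds it through a seesaw-gate cascade
(a step activation with user-set transition point), and re-encodes the
output into fresh singly nicked DNA for the next layer. Latency follows
`t_layer = ⌈k_layer/k_physical⌉·A + B` and die area `(m·c·k)²`.

## Worked example

Multiply two values chemically, read them out, and threshold:

```r
library(nicknet)

p <- molecule_pool() |> encode_by_split("A", 0.9) |> encode_by_split("B", 0.8)
measure(p, "both")
#> [1] 0.72
measure_all(p)
#> # A tibble: 4 × 3
#>   species  quantity fraction
#>   <chr>       <dbl>    <dbl>
#> 1 unnicked   0.0200   0.0200
#> 2 nickA      0.18     0.18
#> 3 nickB      0.08     0.08
#> 4 both       0.72     0.72

mix <- p |> create_toeholds() |> displace_and_separate()
mix$ssdna_input          # displaced ssDNA = the product
#> [1] 0.72
seesaw_activate(c(0.45, 0.55), seesaw_gate(threshold = 0.5))
#> [1] 0 1
```

The four species fractions are the independent-nicking joint distribution
`((1-a)(1-b), a(1-b), (1-a)b, ab)`; only the doubly nicked 0.72 carries a
toehold, so 0.72 is what displacement releases. The step activation kills
0.45 (below threshold, consumed by the threshold strand) and amplifies 0.55
to the replenishment-limited maximum 1.

Run a small network on a 4 × 4 array (two serialized passes over the
8-wide input):

```r
set.seed(1)
net <- compile_network(generate_fixture_mlp(c(8, 6, 3), seed = 7),
                       seesaw_gate(0.3))
run <- run_network(microcell_array(4), net, runif(8))
run
#> <engine_run: 8-6-3 network on 4 x 4 array, ideal mode, 28.28 h>
#> # A tibble: 3 × 3
#>   neuron pre_activation output
#>    <int>          <dbl>  <dbl>
#> 1      1          0.418      1
#> 2      2          0.400      1
#> 3      3          0.360      1
```

Pre-activations are `(1/n_in)·w·x` — normalised dot products on the scale
set by the `1/k` enzyme dosing — and all three clear the 0.3 threshold, so
all three neurons fire. `tidy(run)` and `glance(run)` give per-neuron and
run-level tibbles; in `mode = "sampled"` the same call simulates binomial
molecule-counting noise at a chosen droplet size `t`.

Calibrate the latency model and reproduce the device performance table:

```r
fit <- calibrate_timing(reference_delay_points())
glance(fit)
#> # A tibble: 1 × 5
#>       A     B n_points    sigma factor1_delay_hours
#>   <dbl> <dbl>    <int>    <dbl>               <dbl>
#> 1  2.03  6.04        2 2.68e-15                8.07
config_report(fit)
#>   configuration k_physical microcells factor area_pessimistic_cm2 area_optimistic_cm2 delay_hours
#> 1      Config-1        196  196 x 196      4               553.19               3.840       14.17
#> 2      Config-2         49    49 x 49     16                34.57               0.240       38.57
#> 3      Config-3         16    16 x 16     49                 3.69               0.030      105.67
#> 4      Config-4          4      4 x 4    196                 0.23               0.002      404.57
```

Each row is a device configuration: its microcell count, die area under
pessimistic (200 µm channels, 6-width cells) and optimistic (35 µm, 3-width)
fabrication assumptions, and the serialized per-layer execution time for a
784-wide layer from the calibrated delay law `⌈784/k⌉·A + B`.

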