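# sistermem

Non-genetic (epigenetic) memory analysis of single-cell growth data from
mother-machine and sisters-machine microfluidic devices — and a calibrated
stochastic generator of sisters-machine lineage data to drive and validate
it.

## The problem

Clonal bacteria in a constant environment vary in cycle time, size and
growth rate. How much of that variation is inherited — passed from mother to
daughters and retained for generations — and how much is local environment
or fast noise? Lineage autocorrelation functions conflate these sources. The
pair design separates them by comparing aligned pairs of cells:

* **SC** — sister cells, the two daughters of one mother (shared inheritance
  *and* shared trap);
* **NC** — neighbor cells, co-trapped non-siblings aligned where both start
  a cycle at nearly identical length (shared trap only);
* **RP** — random pairs from different traps, aligned artificially (shared
  nothing).

For a property *y*, the pair correlation function is the Pearson correlation
across pairs at matched generation/time,

    PCF(y)(t) = (1/n) Σᵢ (yᵢ⁽¹⁾(t) − ⟨y⁽¹⁾⟩)(yᵢ⁽²⁾(t) − ⟨y⁽²⁾⟩) / (σ_y⁽¹⁾ σ_y⁽²⁾),

set to 1 at the alignment origin; memory is summarized by the half-life
ln 2 / λ of an exponential fit A·e^(−λg). Divergence is tracked by the
across-pair variance of δy(t) = y⁽¹⁾(t) − y⁽²⁾(t), e.g. the elongation rate
α = d ln L/dt over 6-min windows. SC-vs-NC differences isolate inherited
memory; NC-vs-RP differences isolate the shared micro-environment.

The package implements the full pipeline — TSV lineage tables, cycle
segmentation, pair construction, PCF/ACF series with bootstrap errors and
half-life fits, δα/δf variance dynamics with saturation metrics — plus a
generative sisters-machine simulator (adder size control, AR(1) heritable
growth and size factors, OU intrinsic and trap-shared environmental noise,
post-division growth-rate compensation, symmetric protein partitioning,
measurement noise) whose LB-default preset emulates rich-medium growth:
34-min generations imaged every 3 min.

## Worked example

```r
library(sistermem)

cfg <- sim_config(seed = 1)          # calibrated LB-default preset
tab <- simulate_experiment(cfg)      # lineage table, one row per cell per frame
res <- run_analyze(tab, seed = 1)    # full pair-memory analysis
print(res)
```

```
<results_bundle>
  cycles 19803; pairs SC 400 / NC 96 / RP 120
  mean T 34.87 min (sd 10.29), 11.6 frames/cycle
  T-PCF half-lives: SC 3.77, NC 0.69, RP 0.23 gen; size SC 3.10 gen
  delta-alpha: SC initial excess 40.5% over NC/RP plateau, minimum at 24 min
  delta-f saturation 1.16 generations
  |mean growth-rate difference|: sd_SC/sd_RP = 0.689
```

Reading the output: sister pairs remember their shared cycle-time state for
about 4 generations (half-life 3.77), several-fold longer than neighbor
pairs (0.69), whose correlation reflects the shared trap and residual
relatedness rather than direct inheritance; random pairs carry essentially
no correlation. Sister elongation rates are ~40% more variable than the
neighbor/random plateau immediately after division — the smaller sister
transiently grows faster — and the excess relaxes to its minimum within one
cycle (~24 min). The protein-concentration difference of sisters saturates
within about one generation, the expression-noise memory. Sisters' average
growth rates also stay closer than random pairs' (ratio < 1), reflecting
trap micro-niches. Fitted half-lives are seed-to-seed variable at these
ensemble sizes; replicated runs (see below) use medians over five seeds.

`run_analyze(tab, out = "results/")` additionally writes a JSON bundle and
per-series TSVs; `run_simulate("LB-default", out = "data/", seed = 1)`
writes a lineage TSV with a config echo. A thin command-line front end with
`simulate | analyze | calibrate` verbs is in `inst/scripts/sistermem.R`.

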