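# oriMFA — replication origin mapping by marker frequency analysis

`oriMFA` is an R package for simulating and analysing genome-wide
replication profiles of circular archaeal chromosomes. It addresses a
question typical of haloarchaeal replication studies: a chromosome
carries several `cdc6`-associated origins of unequal firing efficiency,
some of them **dormant** — sequence-intact but silent until the stronger
origins are deleted. The package lets you reproduce that whole analysis
at the desk: simulate the data, process it the way marker frequency
analysis (MFA) is done on real arrays, call origin peaks, detect
dormant-origin activation, and predict origins from sequence.

It is aimed at researchers modelling archaeal (or bacterial/plasmid)
replication dynamics and at anyone who needs a fully testable, seeded
MFA processing chain.

## The model and the method

**Forward model.** For origins $o_1,\dots,o_k$ with efficiencies $e_i$ on
a circle of length $L$, a replicating cell fires a random subset $S$
(each origin independently, empty subsets excluded); the locus at $x$
replicates at $t_S(x) = \min_{i\in S} d_\circ(x,o_i)/v$ at fork speed
$v$. With exponential age structure over the doubling time $T$ and a
cycling fraction $f$, the expected marker frequency is

$$\mathrm{MF}(x) \;=\; f\,\mathbb{E}_S\!\big[2^{\,1-t_S(x)/T}\big] \;+\; (1-f)\;\in\;[1,\,1+f].$$

`expected_marker_frequency()` evaluates this exactly by subset
enumeration (checked against a Monte-Carlo oracle in the tests).

**MFA chain.** Per-probe exponential/stationary ratios → exclusion of
outliers (ratio > 2 or < 0.5, strict) → 30-probe bin means located at
the first probe → centered 5-point smoothing with 1-point slide
(circular wrap); sequencing mode counts read starts in 1-kb windows.

**Calling.** `call_peaks()` detects broad replication peaks with a
robust adaptive prominence threshold and localizes them with a
broken-stick (kinked regression) fit; `estimate_efficiency()` converts
peak heights into normalized relative firing efficiencies;
`compare_profiles()` turns parent/mutant peak sets into
`lost` / `activated` / `active` calls — the dormant-origin activation
signature. `predict_origins()` finds origins from sequence alone:
upstream intergenic extraction, an exhaustive mismatch-tolerant
18–35-bp repeat search, the G-string rule, and the inverted-ORB-pair
requirement; `cdc6_identity()` scores initiator conservation by global
BLOSUM62 alignment.

## Worked example

Simulate the wild-type condition (three active origins of efficiency
0.9/0.5/0.3 plus one dormant origin on a 2.9-Mb circle, half the cells
cycling), process it, and call peaks:

```r
library(oriMFA)

chr     <- chromosome("chr", 2.9e6)
origins <- origin_set(c("oriC1", "oriC2", "oriC3", "oriC4"),
                      c(3e5, 1.3e6, 2.2e6, 2.7e6),
                      c(0.9, 0.5, 0.3, 0))
params  <- replication_params(fork_speed = 10069, doubling_time = 180,
                              cycling_fraction = 0.5)
design  <- probe_design(2.9e6)              # ~34 probes per kb

tab <- simulate_microarray(chr, origins, params, design,
                           noise_model(0.07), seed = 1)
tab <- filter_outliers(tab)
cat("probes:", nrow(tab),
    " excluded:", sprintf("%.3f%%", 100 * attr(tab, "excluded_fraction")))
#> probes: 98600  excluded: 0.011%

profile <- smooth_profile(bin_probes(tab, 30), 5)
peaks   <- estimate_efficiency(call_peaks(profile), profile)
print(as.data.frame(peaks), digits = 3)
#>   position height prominence relative_efficiency
#> 1   296647   1.48     0.2187               0.679
#> 2  1303559   1.35     0.0314               0.321
```

Reading the output: 98,600 probes were simulated and only 0.011% fell
outside the ratio bounds. Two peaks are called, within a few kb of the
true origins at 300 kb and 1.3 Mb, with the stronger origin carrying
about two thirds of the normalized initiation activity. The third origin
(efficiency 0.3) is a real but marginal feature of this model — its peak
rises only a few thousandths of a ratio unit above the neighbouring
passive-replication saddle, below the detection limit at this noise
level; on a noiseless profile `call_peaks()` recovers all three origins
exactly. The dormant origin (efficiency 0) produces no peak; rerun with
the triple-knockout configuration (`efficiency = c(0, 0, 0, 0.8)`) and
`compare_profiles()` reports it `activated` while the three deleted
origins are `lost`.

`run_pipeline(pipeline_config(...))` chains all stages (including
synthetic-genome generation and sequence-based origin prediction) under
one YAML-serializable configuration and writes FASTA/GFF3/TSV/bedGraph/
BED6 outputs plus a JSON report stamped with the config hash and seed;
`inst/scripts/run_pipeline.R` is a command-line wrapper around it.

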