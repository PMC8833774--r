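# iodamage

Strand-break modelling for DNA-incorporated iodine-125 decays.

## The problem

^125^I decays by electron capture and releases a cascade of low-energy Auger
electrons that deposit their energy within a few nanometres. When the iodine
is incorporated into a short DNA duplex, each decay produces a highly
localised pattern of strand breaks, and the classical end-labelled assay
measures it at base-pair resolution: a ^32^P label at one strand end, gel
electrophoresis of the fragments, and scintillation counting per band give
the fraction of detected fragments whose break lies at each distance from the
iodine. This is one of the few benchmarks available for nanoscale Monte Carlo
DNA-damage models, and it comes with a built-in trap: the data are
*normalised* fragment fractions, blind to the absolute break yield.

`iodamage` is an R package for analysing this system end to end, written for
radiation biophysicists who want to fit and stress-test damage models against
fragment-fraction data. It provides:

* a calibrated synthetic generator for per-decay scored events (energy
  depositions and scavenged OH-radical hits per strand and base), emulating
  the statistical structure of tuple-scorer output from track-structure
  codes, plus readers for real scored data (site-indexed or raw 3D positions
  via a cylinder-and-arches DNA geometry classifier);
* direct-damage calling by energy threshold (break iff accumulated energy in
  a backbone volume exceeds `E_thresh`) or probabilistic window (linear ramp
  between `e_low` and `e_high`), indirect-damage calling with a per-OH-hit
  break probability `P_OH`, SSB yields, and DSBs as opposite-strand breaks
  within 10 bp;
* fragment-size distributions (most distant break per decay), their analytic
  forward model `F_i = p_i * prod_{j>i} (1 - p_j)`, and the iterative
  correction `p_i = f_i / (1 - sum_{j>i} f_j)` — including a demonstration
  that on breaks-only data this correction *always* returns a 100% break
  probability at the innermost occupied site, so absolute yields are
  unrecoverable from normalised fragment data;
* grid-search fits of `E_thresh` (high-scavenging data, direct damage only)
  and `P_OH` (low-scavenging data, threshold fixed) minimising
  `SSE = sum_i (log f_i - log F_i)^2`, with residual curves, a broad-minimum
  diagnostic, SSB/DSB yield curves, and a replicated parameter-recovery
  experiment;
* broom-style `tidy()`/`glance()` methods, `autoplot()` figures, delimited
  text I/O for every artefact, and a reproducible `run_pipeline()` driver.

## Worked example

```r
library(iodamage)

cfg <- generator_config(seed = 1)      # calibrated defaults
decays <- generate_events(cfg, 50000)
decays
#> <track_dataset> 50000 decays, 40 bp strand [synthetic]
#>   980721 energy depositions, 410608 OH hits

subset(per_base_statistics(decays), strand == 0 & base %in% c(0, 5, 10))
#>    strand base mean_energy_per_decay frac_nonzero mean_oh_hits
#> 1       0    0            90.2058052      0.99764      0.40136
#> 6       0    5             2.5558174      0.15696      0.13572
#> 11      0   10             0.7851413      0.04972      0.10330
```

Energy deposition is steeply dominated by the bases nearest the iodine
(base 0 holds the iodine); by base 10 only ~5% of decays deposit anything.
Call direct breaks at a 29.5 eV threshold, add indirect OH breaks at
`P_OH = 0.16`, and count yields:

```r
calls <- merge_breaks(
  call_direct_threshold(decays, e_thresh = 29.5),
  call_indirect(decays, p_oh = 0.16, seed = 2)
)
ssb_yield(calls, strand = 0)
#>   strand n_breaks yield      se
#> 1      0   118083  2.36 0.00687
dsb_yield(calls)
#>   n_dsb yield      se
#> 1 78358  1.57 0.00560
```

The fragment-size distribution over the measured sites, the corrected break
profile it implies, and the true per-base break rates:

```r
frag <- fragment_distribution(calls, strand = 0, max_base = 15,
                              mode = "breaks_only")
corrected <- kandaiya_inverse(frag)
head(corrected, 2)
#>   base         p
#> 1    0 1.0000000
#> 2    1 0.3935084
head(break_profile(calls, strand = 0, max_base = 15), 2)
#>   base       p
#> 1    0 0.93404
#> 2    1 0.37974
```

The corrected profile claims a 100% break probability at base 0 even though
the true rate is 93.4%: breaks-only normalisation forces probability 1 at the
innermost occupied site, whatever the underlying rates (`autoplot()` on
either object draws the profiles). Finally, fit the threshold against an
independent synthetic "experiment" generated at 29.5 eV:

```r
obs <- synthetic_observation(generator_config(seed = 99), 50000,
                             e_thresh = 29.5)
fit_threshold(decays, obs)
#> <damage_fit> e_thresh = 29.25 +/- 0.125 (min SSE 0.03729 over 121 grid points)
```

The recovered threshold sits one 0.25 eV grid step from the generating value;
`broad_minimum(fit)` shows the wide basin of near-equivalent thresholds that
normalised fragment data cannot distinguish, and
`recovery_experiment()` repeats the whole two-stage fit over independent
replicate pairs (at 20 replicates of 200,000 decays the medians recover
29.5 eV and 0.16 exactly).

`run_pipeline(run_config(seed = 1), "out/")` runs the whole chain and writes
every table (TSV), figure (PNG), a `summary.yaml` and a log, all derived from
a single master seed.

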