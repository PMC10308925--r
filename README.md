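# nitripartition

Who oxidizes the ammonia in a sediment? Three microbial guilds can:
ammonia-oxidizing archaea (AOA), ammonia-oxidizing bacteria (AOB), and
comammox *Nitrospira*, which complete the whole oxidation to nitrate in a
single cell. Bulk nitrification rates cannot separate them, but a
differential-inhibitor microcosm design can: chlorate knocks out comammox
(and strict nitrite oxidizers) while sparing AOA and AOB, and 1-octyne
additionally knocks out AOB. Fitting the accumulation of oxidized nitrogen
(NO2⁻ + NO3⁻) in parallel treatments gives treatment-level potential
ammonium-oxidation rates (PARs), and the guild rates follow by
subtraction:

    PAR_cmx = PAR_I − PAR_II        (I: no inhibitor)
    PAR_aob = PAR_II − PAR_III      (II: chlorate)
    PAR_aoa = PAR_III               (III: chlorate + 1-octyne)

with a nitrate-only treatment IV guarding against nitrate-consuming
processes (DNRA, denitrification).

`nitripartition` implements this partition for intertidal-sediment-style
microcosm data, plus the two companion measurements such studies lean on:

* **DNA-SIP gradient analysis** — weighted-mean-density and peak-shift
  statistics over CsCl buoyant-density fraction profiles, with a formal
  dual criterion for calling a taxon ¹³C-labeled;
* **qPCR absolute quantification** — standard curves with amplification
  efficiency QC, copies-per-gram back-calculation, fold changes;
* **a mechanistic synthetic-data generator** — Michaelis–Menten-softened
  guild kinetics with daily substrate dosing, inhibitor logic, salinity
  scaling with adaptation lags, transient nitrite accumulation, Gaussian
  taxon bands in a linear density gradient, and lognormal count noise —
  so the entire pipeline is testable against known truth without field
  data.

## Worked example

Feed published treatment-level PARs (mg N/day/kg soil, saline condition)
through the partition:

```r
library(nitripartition)
p <- partition_guilds(3.36, 2.76, 1.02)
p
#> <partition_result>
#>   total (treatment I):   3.36 +/- 0.00 mg N/day/kg soil
#>   AOA:        1.02 +/- 0.00  (30%)
#>   AOB:        1.74 +/- 0.00  (52%)
#>   comammox:   0.60 +/- 0.00  (18%)
```

AOB dominate under saline conditions (52%), comammox drop to 18%. Or run
everything from synthetic data — simulate a freshwater four-treatment
panel (3 replicates, sampled 6-hourly for 48 h) and re-estimate the rates:

```r
cfg <- microcosm_config(seed = 42)
panel <- simulate_treatment_panel(cfg, salinity = 0.06,
                                  sample_times = seq(0, 48, 6))
estimate_partition(panel)
#> <partition_result> salinity 0.06%
#>   total (treatment I):   7.81 +/- 0.13 mg N/day/kg soil
#>   AOA:        0.06 +/- 0.13  (1%)
#>   AOB:        3.55 +/- 0.14  (45%)
#>   comammox:   4.20 +/- 0.14  (54%)
#>   DNRA control: passed (NO3 slope 0.1119 mM/day)
```

The configured truth behind this run is AOA 0.12, AOB 3.58, comammox 4.37
mg N/day/kg soil; the estimates land within the propagated uncertainty
(slightly low because Michaelis–Menten softening keeps realized rates a
few percent under the configured maxima — see the methods vignette). The
DNRA control line confirms nitrate did not decline in treatment IV.

A SIP labeling call on a noiseless synthetic gradient, with a comammox-like
band (GC 0.485) given 0.236 excess ¹³C atom fraction:

```r
g <- gradient_config(noise_cv = 0)
t12 <- simulate_gradient(g, taxon_band("CMX", gc = 0.485))
t13 <- simulate_gradient(g, taxon_band("CMX", gc = 0.485,
                                       atom13c_excess = 0.236),
                         isotope = "13C")
detect_labeling(t12, t13, "CMX")
#> <sip_result> CMX: WMD 1.7075 -> 1.7160 g/mL (delta +0.0085), peak 10 -> 9: LABELED
```

The peak moves one fraction heavier, from 1.7075 to 1.716 g/mL — the
classic labeled signature.

There is also a thin command-line wrapper over the same functions:

```sh
Rscript inst/cli/nitripartition.R run --seed 1 --out results/demo
Rscript inst/cli/nitripartition.R partition --in timeseries.csv \
    --exclude-before-hours 12 --out results
```

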