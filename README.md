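# magbalance

Genome-resolved quantification of microbial immigration in an aerobic
granular sludge (AGS) wastewater treatment plant.

A full-scale reactor receives a continuous load of living biomass with its
influent. Some populations detected in the sludge genuinely grow there;
others decline and persist only because immigration keeps replacing them.
`magbalance` separates the two at the resolution of metagenome-assembled
genomes (MAGs) with a steady-state mass balance over the plant's
compartments — influent, mixed reactor (flocs FL, small granules SG, large
granules LG), excess sludge and effluent — applied to relative-abundance
(metagenomic) and relative-expression (metatranscriptomic) profiles.

For MAG *x* with compartment fractions *p*, reactor inventory `M_AGS`
(kg TSS) and daily fluxes `J_ES`, `J_EF`, `J_WW` (kg TSS/d):

```
theta_x = p_AGS * M_AGS / (p_ES * J_ES + p_EF * J_EF)                  # SRT, d
mu_x    = (p_ES * J_ES + p_EF * J_EF - p_WW * J_WW) / (p_AGS * M_AGS) # 1/d
```

`mu_x < 0` marks an immigration-sustained (source–sink) population. The
package also runs the balance per aggregate-size class, classifies MAGs as
dominant/rare (0.1% mean reactor abundance) and active/inactive (RNA/DNA
relative activity with an estimated cutoff, plus a transparent MAG-level
differential-expression test between influent and reactor with
`|log2 FC| >= 1` and/or `P < 5%` significance tiers), computes Bray–Curtis /
PCoA / ANOSIM / UPGMA community statistics from definitions, and ships a
forward simulator of a steady-state plant with known per-MAG growth rates so
every stage can be verified by parameter recovery.

## Worked example

Plant parameters and single-MAG arithmetic:

```r
library(magbalance)
plant <- read_plant_config(system.file("extdata", "plant_full_scale.yaml",
                                       package = "magbalance"))
daily_load_ratio(plant)                       # 7.36529  (% of reactor biomass per day)
compute_srt(0.05, 0.02, 0.001, plant)         # 62.47433 (d)
compute_net_growth(0.01, 0.01, 0.01, 0.10, plant)  # -0.6751947 (1/d)
```

A MAG occupying 5% of the reactor but wasted slowly is retained for 62 days;
a MAG at 1% everywhere that makes up 10% of the influent is declining at
−0.68/d — it only persists through immigration. The plant receives 7.4%
(about 7.5% at half-percent resolution) of its standing biomass per day with
the influent.

Full pipeline on a simulated 300-MAG plant:

```r
cfg    <- synthetic_config(n_mags = 300, noise = "multinomial",
                           depth = 1e6, seed = 17)
truth  <- generate_truth(cfg)
tables <- emit_profiles(truth)
res <- run_pipeline(tables$dna, tables$rna, truth$plant,
                    counts_rna = tables$counts_rna,
                    mags = synthetic_mag_metadata(truth),
                    outdir = "ags_run", seed = 17)
```

`ags_run/summary.txt` then reads (excerpt):

```
[metagenomics]
  whole positive: n = 78.33 +/- 2.08 (30.0 dominant / 48.3 rare); AGS 12.49 +/- 0.10%; influent 1.21 +/- 0.02%
  whole negative: n = 221.67 +/- 2.08 (85.0 dominant / 136.7 rare); AGS 57.51 +/- 0.07%; influent 68.80 +/- 0.04%
  ...
  immigration rate: whole 57.51%, FL 36.76%, SG 61.63%, LG 69.89%

group relative activity (negative growth): 0.97 (= 56.0 / 57.5)
group relative activity (positive growth): 0.33 (= 4.1 / 12.5)

RNA/DNA activity cutoff (slope): 1.0348

growth x activity quadrants (sign-only, 201 MAGs):
  positive / active: 52
  positive / inactive: 0
  negative / active: 54
  negative / inactive: 95

ANOSIM on Bray-Curtis (DNA): R = 0.938, p = 0.001
```

Reading: per replicate, about 222 of 300 MAGs have negative net growth; they
hold 57.5% of the reactor community while contributing 68.8% of the influent
community — this simulated plant is fed an immigrant-rich influent. The
negative-growth group's per-biomass activity (cumulative RNA over cumulative
DNA, 0.97) is about three times that of the growers (0.33): declining
immigrants are not necessarily dormant. ANOSIM confirms compartments differ
far more between than within groups (R = 0.94). On noise-free output of the
same generator, `run_mass_balance()` recovers every true `mu` and `theta` to
1e−9 — the simulator exists precisely to make that check possible.

The methods vignette (`vignettes/immigration-mass-balance.Rmd`) documents
the model assumptions, the apportionment options, the generator design and
its limitations.

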