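# micdiag

Metabolomic and metagenomic diagnostics for microbially influenced
corrosion (MIC) in oil-production pipelines.

Pipeline biofilms corrode carbon steel through their metabolism —
classically via sulfate-reducing bacteria (SRB), which operators try to
suppress by injecting nitrate. `micdiag` is for microbiologists and
integrity engineers who have untargeted LC-MS feature tables and
metagenome annotation products from pigging-debris samples and want to
answer: *which terminal-electron-acceptor (TEA) strategy dominates each
system, and what does the chemistry say the community is actually doing?*

The package implements, as tested and reusable functions:

* **Exact-mass chemistry** — formula parsing, monoisotopic masses, ESI
  adduct conversion with the proton mass, signed ppm/mDa errors, and
  nitrogen-rule parity (odd nominal mass ⇔ odd nitrogen count for
  even-electron CHNOPS molecules).
* **Feature-table processing** — single-linkage alignment at 6 ppm /
  0.25 min, dual-mode de-duplication, the 1,000 i.u. abundance floor, and
  shot-noise QC (12.5 i.u. per detected ion; expected replicate RSD
  1/√N).
* **Putative identification** — exact-mass library matching, a
  six-descriptor least-squares retention-time model with a 45% rejection
  gate for positive-mode features, a deterministic 1–10 confidence
  rubric, best-match selection, and pathway roll-up.
* **Targeted screening** — alkyl- and benzylsuccinate homolog series
  (diagnostic of anaerobic hydrocarbon activation by addition to
  fumarate) at ±2 ppm and ±10% retention time, with anchored
  linear-in-carbon-number retention interpolation.
* **System statistics** — the odd-mass abundance statistic
  R_N = 100 × Σ abundance(odd-mass features) / Σ abundance(all features),
  high- vs low-corrosion differential features (>10,000 i.u. in one
  system and ratio ≥ 5), abundance-ratio similarity, identified ratios
  among the top-200 features, and PCA of replicate profiles.
* **Metagenome TEA arithmetic** — gene frequencies per million reads,
  fold contrasts, marker-gene pathway calls on genome bins, and
  coverage-based estimates of the community fraction carrying
  denitrification or dissimilatory sulfate reduction
  (Σ coverage × bin length / total bases).
* **A seeded synthetic-data generator** producing every input with
  recorded ground truth, so the whole pipeline is testable without raw
  instrument data.

## Worked example

```r
library(micdiag)

# chemistry: hexylsuccinic acid, a hexane-activation marker
monoisotopic_mass("C10H18O4")
#> [1] 202.1205

# acetate in the high-corrosion system's produced water: 311 mg/L
round(mg_per_l_to_mm(311, "C2H4O2"), 1)
#> [1] 5.2   # mM

# full synthetic run: generate inputs, then process -> annotate ->
# screen -> stats -> TEA
cfg <- generator_config(seed = 1)
lib <- generate_library(cfg)
gen <- generate_feature_tables(cfg, lib)
mg  <- generate_metagenome_tables(cfg)
res <- run_pipeline(gen$table, library = lib,
                    standards = generate_rt_standards(cfg, lib),
                    screen_series_list = list(gen$spike_series),
                    bins = mg$bins, gene_counts = mg$gene_counts,
                    sizes = mg$sizes)
res
#> <micdiag_run>
#>   features: 418 in, 415 retained (floor 1000 i.u.)
#>   shot-noise consistent: 98.3%
#>   accepted annotations: 252
#>   differential features: lc_enriched_count=18, hc_enriched_count=38
#>   RN (%): LC3=39.9, LC11=55.0, HC3=40.0, HC11=30.0
```

Reading the output: 418 aligned features enter; three fall below the
1,000 i.u. floor in every sample. 98.3% of replicate triplets scatter no
more than ion-counting statistics allow, so the abundances are
quantitatively trustworthy. 253 features match library compounds within
6 ppm (and the retention gate, for positive-mode features). The
differential counts say which features are ≥5-fold enriched per system.
RN — the abundance share of odd-nominal-mass (odd-nitrogen) features —
starts near 40% in both early pig samples, then diverges with deposit
depth: up to 55% in the low-corrosion system (accumulating
organonitrogen compounds under denitrifying conditions) and down to 30%
in the high-corrosion system. `res$cell_fractions` holds the
coverage-based TEA estimates (here ≈78%/39% denitrifiers in LC3/LC11 and
≈29%/34% sulfate reducers in HC3/HC11, matching the generator's
community), and `fold_comparison()` on the packaged gene-frequency table
gives the LC:HC monooxygenase contrast (~258-fold).

A shell entry point over the same functions is installed at
`inst/scripts/run_pipeline.R` (supports `--simulate` and file inputs).

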