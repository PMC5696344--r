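# cochip

Downstream quantification for ChIP-seq co-occupancy studies of the
*Drosophila* Ash1 histone methyltransferase complex and its stimulatory
subunit Mrg15, plus Michaelis–Menten kinetics for the in vitro enzyme
assays.

Ash1 deposits H3K36me2, an active mark that antagonizes Polycomb
silencing at HOX and other developmental loci. Mrg15 co-occupies Ash1
sites, stimulates Ash1's catalytic activity, and is required for full
H3K36me2 deposition at Ash1 targets. Testing that picture on sequencing
data needs a specific set of downstream computations, which this package
implements as reusable, tested functions:

- **Normalized read densities.** Reads are extended to the average
  sonication fragment (250 bp), piled up, and normalized to a reference
  depth and region length:
  `density = count × (depth_scale / library_size) / (length / 1 kb)`,
  reported as RP10M (reads per 10 million) or RPM per kb.
- **Peak-set overlap** with Venn semantics, and **intensity
  correlation** (Pearson on `log2(1 + density)`).
- **Metaprofiles and signal matrices** around peaks across
  (antibody × condition) samples.
- **Stratified comparison**: H3K36me2 at Ash1 peaks, split by Mrg15
  high/low (median) within Ash1-abundance tertiles.
- **Knockdown dependency**: per-quintile retained signal fraction
  `median(kd / (wt + ε))` — rising profiles mean weak peaks depend more
  on the depleted factor.
- **Super-target genes**: genes ranked by Ash1 density in the first
  exon (floored at 200 bp); the super set is the minimal prefix of the
  top-200 ranking holding ≥ 45% of the summed score mass.
- **Expression integration**: two-fold up/down classification of
  knockdown response and enrichment of repression among super targets.
- **Kinetics**: per-replicate Michaelis–Menten fits
  (`v = Vmax·S/(Km+S)`, log-parameterized Levenberg–Marquardt) with
  mean ± s.e.m. reporting and pooled-variance t comparison of enzymes —
  the design in which Mrg15 raises Ash1's Vmax with little Km change.
- **Synthetic data**: a generator that reproduces the assumed
  statistical structure (3678 Mrg15 / 562 Ash1 peaks, 41% overlap,
  ρ = 0.58 log-intensity correlation, 398 targets, 26 super targets at
  45%, 18 down / 8 up responders, stratum-dependent knockdown retention)
  with a machine-readable truth set, so the whole pipeline is validated
  closed-loop.

## Worked example

Simulate the default experiment and run the full analysis:

```r
library(cochip)
b <- run_pipeline(run_config(seed = 11, out_dir = "results"))

b$overlap$fraction_a            # Ash1 peaks overlapping Mrg15 peaks
#> [1] 0.4092527
b$correlation$r                 # log-intensity correlation at Ash1 peaks
#> [1] 0.5568712
b$targets$super$n_super         # super targets among the top 200
#> [1] 26
sum(b$expression$target_classes$class == "down")  # 2-fold down, Ash1 KD
#> [1] 18
sum(b$expression$target_classes$class == "up")
#> [1] 8
b$expression$enrichment$odds_ratio   # repression enriched in supers
#> [1] 48.60743
```

So on synthetic data generated at the study's conditions, 41% of Ash1
peaks carry a called Mrg15 peak while Mrg15 intensity correlates with
Ash1 intensity across all of them (r ≈ 0.56 here); exactly 26 of the
top 200 target genes hold ≥ 45% of the first-exon Ash1 signal; and the
18 two-fold-repressed genes concentrate heavily in those super targets
(odds ratio ≈ 49, exact p ≈ 5e-12). Stage outputs (signal matrix,
profiles, stratified medians, dependency table, rankings, classes) land
as TSV/JSON files in `results/`, with a timing log and a full config
echo for reproducibility; reruns with the same seed are byte-identical.

The pieces are usable on their own — e.g. for real data:

```r
peaks  <- read_intervals("ash1_peaks.bed", "bed")
reads  <- read_reads_bed("ash1_chip_fragments.bed")
dens   <- quantify_regions(reads, peaks)            # RP10M per kb
models <- read_intervals("genes.gtf", "gtf")
rk     <- score_and_rank(models,
                         assign_targets(models, peaks)$gene_id,
                         reads, top_n = 200)
detect_super_targets(rk, share_threshold = 0.45)
```

A thin command-line wrapper lives at `inst/cli/cochip.R`
(`Rscript cochip.R run --config run.yaml`).

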