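# zedsense

Analysis pipeline relating **H2A.Z (Htz1) occupancy at gene 3′ ends** to
**antisense non-coding transcription** in budding yeast.

Most H2A.Z studies focus on the histone variant's hallmark enrichment at
the −1/+1 nucleosomes of promoters. A sizeable fraction of the signal,
however, sits at the *3′ ends* of protein-coding genes — and those 3′
peaks coincide with the transcription start sites of antisense
transcripts that become visible when the nuclear exosome (rrp6Δ) is
disabled. `zedsense` packages the full chain of inference behind that
observation for anyone who wants to apply it to their own ChIP-seq/
strand-specific RNA-seq pairs, or to study its statistical behaviour on
simulated data:

* **ChIP background model** — per-bp ChIP:input ratio r(x); background
  B = mean(r) + k·sd(r) with k = 1.2; signal(x) = max(r(x) − B, 0).
* **Gene-anatomy partition** — every base assigned to 5′ (TSS ± 300 bp),
  3′ (TES ± 300 bp), CDS or IGR, with totals, percentages and RPKM
  densities.
* **Metagene profiles and 25-dimensional occupancy vectors** (nine 50-bp
  TSS windows, ten CDS windows, six 50-bp TES windows) with hierarchical
  clustering (Euclidean distance, average linkage).
* **Strand-specific RNA normalisation** — one factor scaling the total
  sense-transcript signal to 10⁸ arbitrary units, applied to both strands;
  per-transcript levels per kilobase.
* **Peak–transcript association** — a 3′ window is associated with an
  antisense transcript when downstream RNA signal (in the antisense
  direction) exceeds upstream signal more than 3-fold.
* **Contingency + randomisation inference** — 2×2 high-vs-none occupancy ×
  antisense tables with log-space Fisher's exact test (stable down to
  p ~ 1e-300), independence expectations, and a gene-resampling null
  (add-one empirical p, never literally zero).
* **Differential expression stand-in** — median-of-ratios size factors and
  a negative-binomial likelihood-ratio test with trended dispersion
  moderation; externally computed DE tables can be imported instead.
* **Gene-arrangement typology** (tandem/convergent × close/far at the 3′
  side, "close" < 300 bp) and the **four-class 5′/3′ occupancy scheme**
  with per-class sense fold-change comparisons.
* **Synthetic-data generator** — a compact genome of tandem/convergent
  gene pairs with planted 5′/3′ peaks, antisense transcripts initiating
  inside 3′ windows, exosome-mutant-style transcript visibility and
  programmable condition effects, so the whole pipeline runs at desk scale
  with a recoverable ground truth.

## Worked example

```r
library(zedsense)

cfg <- sim_config(n_genes = 600)          # study-condition defaults
sim <- simulate_genome(cfg, seed = 11)
chip <- simulate_chip(sim$catalog, sim$truth, cfg, seed = 11)

signal <- subtract_background(normalize_rpm(chip$chip),
                              normalize_rpm(chip$input), k = 1.2)
ee <- add_occupancy_calls(quantify_end_enrichment(signal, sim$catalog))
as_set <- classify_antisense(sim$catalog)

overlap_contingency(ee, as_set, "high_vs_none")
#> 2x2 contingency (observed | expected):
#>      col1 col2     col1     col2
#> row1   76   55 24.92478 106.0752
#> row2   10  311 61.07522 259.9248
#> Fisher two-sided p = 6.339e-39; odds ratio = 42.97

high <- ee$id[ee$three_call == "high"]
randomization_test(sim$catalog, as_set, high, iters = 500, seed = 3)
#> Randomisation: observed 76 of 131 windows with an antisense TSS;
#>   null mean 20.8, empirical p = 0.001996 (500 iterations, add-one estimator)
```

Reading: of the genes whose 3′ window carries a high occupancy call, 76 of
131 host an antisense transcript versus the ~25 expected under
independence (odds ratio ≈ 43); drawing the same number of 3′ windows at
random co-localises with antisense TSSs only ~21 times, so the observed
count exceeds every resample and the add-one empirical p is at its
minimum.

`run_pipeline(pipeline_config(...), out_dir = "...")` chains every stage
(simulate → ChIP → RNA → association → DE → arrangement/classes → report)
and writes TSV/JSON outputs whose bytes are reproducible from config +
seed. A thin command-line wrapper is installed at
`inst/scripts/zedsense` (`zedsense simulate|run --config cfg.yaml --seed N
--out DIR`).

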