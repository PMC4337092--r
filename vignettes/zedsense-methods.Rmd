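---
title: "Linking 3' H2A.Z occupancy to antisense transcription: models and methods"
author: "zedsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking 3' H2A.Z occupancy to antisense transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zedsense)
```

## The scientific question

The histone variant H2A.Z (Htz1 in *Saccharomyces cerevisiae*) is famous
for flanking nucleosome-depleted promoter regions, but an appreciable
share of its ChIP signal sits at the **3′ ends** of protein-coding genes.
Those 3′ peaks coincide with the start sites of **antisense transcripts**
— unstable RNAs transcribed from the strand opposite a coding gene,
typically initiating in its terminator region and only visible when the
nuclear exosome component Rrp6 is deleted. The analytic chain this
package implements asks, in order:

1. Which genes have H2A.Z at their 3′ ends (background-subtracted ChIP)?
2. Which genes host an antisense transcript (strand-specific RNA,
   transcript catalogue)?
3. Is the co-occurrence of the two larger than chance (contingency +
   randomisation)?
4. Do antisense levels depend on H2A.Z (two-condition differential
   expression), and does perturbing them feed back on the sense transcript
   (coupling, occupancy-pattern classes)?
5. Is the effect concentrated in particular gene arrangements
   (tandem/convergent typology)?

## The ChIP background model

ChIP and input tracks are first normalised to reads per million. At every
base with positive input we form the ratio $r(x) =
\mathrm{chip}(x)/\mathrm{input}(x)$; bases with zero input are masked —
excluded from the moments, zero in the output — rather than rescued with a
pseudocount, which would inject an arbitrary constant into a ratio scale.
The background is

$$B = \bar r + k\,\hat\sigma_r, \qquad k = 1.2,$$

with the sample ($n-1$) standard deviation, and the final signal is
$\max(r(x) - B, 0)$. Two readings of "subtract the background from the
ChIP signal" are possible; we subtract $B$ from the *ratio*, because $B$
is defined on ratios and subtraction in any other unit would be
dimensionally inconsistent. Both $k$ and the per-chromosome/genome-wide
scope of the moments are exposed (`subtract_background(k =, per_chromosome =)`;
genome-wide is the default).

Because the floor at zero makes the transformation idempotent-in-spirit
but not linear, all downstream levels are means of this floored signal;
levels are therefore invariant under joint rescaling of chip and input
but not under rescaling of only one.

## Gene anatomy, profiles, vectors

The signal partition assigns every base to exactly one of four
categories: 5′ (TSS ± 300 bp), 3′ (TES ± 300 bp), CDS (inside a gene,
outside the end windows), IGR (elsewhere). Where windows of neighbouring
genes collide the precedence is 5′ > 3′ > CDS > IGR — deliberately
conservative for the central claim, since it credits ambiguous bases to
promoters *before* 3′ ends, so 3′ signal cannot be inflated by a
downstream neighbour's promoter.

Occupancy vectors summarise each transcript in 25 windows laid out in the
direction of transcription: nine 50-bp windows over $[\mathrm{TSS}-300,
\mathrm{TSS}+150)$ — the −2/−1/+1 nucleosome region at canonical ~150-bp
spacing — ten equal-width windows over the CDS core, and six 50-bp
windows over $[\mathrm{TES}-150, \mathrm{TES}+150)$. The exact window
coordinates are an interpretation (only the 9/10/6 layout is fixed by the
design); they are documented here and kept in one place
(`feature_vectors`). Transcripts shorter than 310 bp cannot fill ten
non-empty core windows and are excluded, with their ids recorded.
Clustering uses Euclidean distance with average linkage — the default
middle ground when the linkage is otherwise unspecified — and rows are
sorted by transcript id first, so the dendrogram does not depend on input
order.

## End enrichment and the three-tier call

5′ and 3′ levels are means of the background-subtracted signal over the
first/last 150 bp inside the transcript (clipped, length-corrected, for
short transcripts). Calls are three-tier: **none** iff the level is
exactly 0 (possible, and common, because of the floor at $B$);
**high** iff the level reaches the mean of all strictly positive levels;
**intermediate** otherwise. The positive-mean rule is scale-free and
needs no tuned constant; an explicit threshold can be passed instead.

## Strand-specific RNA

One scale factor adjusts the **total sense-transcript signal** to 10⁸
arbitrary units and the *same* factor is applied to the antisense strand,
so sense:antisense ratios are preserved. The sense total sums annotated
coding transcripts (a whole-strand variant exists behind
`method = "whole_strand"`); per-transcript levels divide by transcript
length in kb.

A non-coding transcript is assigned as antisense to the opposite-strand
coding gene with the largest overlap, provided at least half of the
non-coding transcript overlaps it (`min_overlap = 0.5`, tie-break by
overlap then id). Candidates that also overlap a *same-strand* coding
gene are flagged `excluded_convergent` and dropped from antisense
quantification: such signal cannot be distinguished from convergent
read-through.

## Association and its null

A 3′ window is associated with an antisense transcript when the mean
antisense-strand RNA signal in the 150 bp downstream of the window (in
the antisense direction) exceeds the 150 bp upstream more than 3-fold.
A pseudocount of 0.1 signal units keeps the 0/0 case well-defined at fold
exactly 1.

The categorical version cross-tabulates the high-vs-none 3′ call against
antisense status (intermediate genes excluded; one-vs-rest variants are
available) and attaches independence expectations $e_{ij} = r_i c_j / N$,
the odds ratio, and a two-sided Fisher p computed as the probability-mass
sum in log space via `dhyper(log = TRUE)` — naive products underflow long
before the p-values this design produces (~1e-200).

The randomisation null draws, in each of 1000 iterations, as many genes
as there are high-3′ genes, uniformly **without replacement** from all
genes with a defined 3′ window, and counts windows containing an
antisense TSS (strictly inside; a distance tolerance is available). The
empirical p is the add-one estimator $(1 + \#\{null \ge obs\})/(iters+1)$,
which cannot return literal zero — a run in which the observed count beats
every resample reports $1/1001$.

## The differential-expression stand-in

The two-condition test is deliberately *not* a re-implementation of any
published tool; imported DE tables (`load_de_table`) are the fidelity
route. The built-in test exists so the pipeline is self-contained and
calibrated: median-of-ratios size factors (rescaled to geometric mean 1),
a per-transcript method-of-moments dispersion from the pooled
within-condition variance, a parametric trend $a_0 + a_1/\mu$ fitted
across transcripts, and a likelihood-ratio statistic (common mean vs
per-condition means, dispersion fixed) against $\chi^2_1$. The testing
dispersion is the **maximum** of the per-transcript estimate and the
trend, floored at 0.01: with two replicates per condition the
method-of-moments estimate is badly downward-noisy, and taking the
maximum trades a little power for type-I control under the asymptotic
reference (measured type-I ≈ 0.035 at a nominal 0.05 in the test suite).
Fold changes use a 0.5 pseudocount on the normalised means, which keeps
log2FC finite and monotone in the counts.

## Arrangement typology and occupancy classes

Arrangement is evaluated at each gene's **3′ side only** — the side where
antisense transcripts initiate: the nearest coding neighbour there makes
the gene tandem (same direction) or convergent (facing), close (< 300 bp,
strict) or far. Divergent 5′–5′ geometry never appears at a 3′ side, so
the four categories are exhaustive for genes with a neighbour.

The four occupancy classes cut the 5′ and 3′ levels at their arithmetic
means over the classified universe (class 1 = 5′ only, 2 = both,
3 = neither, 4 = 3′ only). The default universe is genes hosting a
detected antisense transcript — the population for which the
sense/antisense coupling question is posed — and is configurable. A
positive-only mean variant is available for consistency with the
three-tier call; the plain mean is the default as the more literal
reading of an "average occupancy" threshold.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions, chosen once:

* 4000 genes of 0.8–2 kb on 2-Mb chromosomes; tandem:convergent 60:40
  with close gaps of 100–280 bp and far gaps of 320–900 bp.
* 5′ peaks on 49% of genes; 3′ peaks on 30% of tandem and 8% of
  convergent genes (~20% overall, concentrated at tandem genes).
* Antisense transcripts on 52% of 3′-peak genes and 5% of the rest,
  initiating uniformly within the host's 3′-inner 150 bp on the opposite
  strand and contained in the host span.
* ChIP tracks: flat input of mean 50 with **block-wise** noise (sd 5,
  150-bp blocks — fragment-scale spatial autocorrelation, which is what
  allows entire 3′ windows to be exactly zero after thresholding);
  truncated Gaussian bumps (sd 50 bp, ± 100 bp) of height 150 at the
  −1/+1 nucleosome positions and the 3′-window centre. Unflagged ends
  carry a weak mark (30–50% of full height) with probability 0.3: real
  occupancy is graded, and this weak tier is calibrated so the
  none/intermediate/high composition of the calls (~62/17/20% at 4000
  genes) matches the published three-tier composition of the yeast genome
  (59/21/20%).
* RNA: negative-binomial counts (dispersion 0.05, two replicates per
  condition), per-transcript lognormal baselines (sd 0.8 on the log
  scale) around medians of 200 (sense) and 60 (antisense). The second
  condition multiplies 3′-peak antisense transcripts by 0.25 and their
  hosts by 1.5.

Each artifact (genome, ChIP, RNA) consumes its own RNG stream derived
from the master seed by a fixed offset, so regenerating one never
perturbs another, and identical config + seed is bit-identical.

Deliberately **not** modelled: read-level sampling (FASTQ), sequence and
mappability bias, fragment-size distributions, overlapping genes,
transcript isoforms, and antisense transcripts extending beyond their
host. Passing tests on these simulations therefore demonstrate the
*statistical machinery* — background model, association logic, null
calibration, class recovery — not robustness to alignment artefacts or
annotation error in real data.

## Numerical choices

* Internal coordinates are 0-based half-open everywhere; GFF3's 1-based
  closed convention is converted at I/O only. TSS/TES are strand-aware
  and all flank arithmetic runs in the direction of transcription.
* Windows extending past chromosome ends are clipped and means divide by
  the clipped length, avoiding edge bias on small genomes.
* Fisher's two-sided p uses the probability-mass definition with a
  relative slack of 1e-7 for floating ties; expected counts conserve
  margins exactly.
* Quantile bins place edge ties in the lower bin; degenerate (all-equal)
  inputs collapse to bin 1 with a warning.
* The empirical p of the randomisation test uses the add-one estimator.
* Problem sizes in the shipped tests: unit fixtures of 2–40 genes;
  module-level simulations of 300–800 genes; one full-scale 4000-gene
  recovery run and a 2000-transcript DE calibration in the acceptance
  suite. These sizes make the whole suite run in a couple of minutes
  while leaving every statistical check comfortably powered.

## Known limitations

* The positive-mean "high" threshold is sensitive to the size of the
  intermediate tier; on data without graded occupancy it degenerates
  towards a median split of the positives.
* The DE stand-in's $\chi^2$ reference is asymptotic; at two replicates
  it is kept conservative by the dispersion-maximum rule rather than by
  finite-sample corrections.
* Antisense assignment trusts the transcript catalogue; no de novo
  boundary calling is attempted, so unannotated antisense transcripts are
  invisible.
* The arrangement typology considers only the nearest 3′-side neighbour;
  nested or overlapping coding genes are outside its scope.
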