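---
title: "Nucleosome maps, promoter histone marks, and transcription: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome maps, promoter histone marks, and transcription: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucposer)
```

# Scope and model

`nucposer` implements a deliberately transparent analysis of promoter
chromatin in compact genomes. Its model of a gene's 5′ region is the
canonical one for organisms with strongly phased nucleosomes: a
nucleosome-depleted region (NDR) just upstream of the coding start, flanked
by a well-positioned +1 nucleosome on the gene side and a −1 nucleosome on
the far side, with a regular array continuing into the gene body. The
package takes this architecture seriously as an *assumption*: all promoter
calling is anchored at the annotated gene start on the coding strand (the
ATG), and all windows are measured in transcription orientation. Genomes
with long 5′ UTRs, where the transcription start site and the ATG diverge
substantially, violate this assumption; the anchor would then need to come
from a TSS annotation instead.

Coordinates are 0-based and half-open throughout. GFF3 (1-based inclusive)
and the 1-based IRanges conventions are converted at the I/O boundary, so
interval arithmetic inside the package needs no off-by-one bookkeeping.
bedGraph is the coverage interchange format; fragment pileup is delegated
to `IRanges::coverage`, and GFF3/bedGraph parsing to `rtracklayer`.

# The peak caller

The nucleosome caller rests on a single linear filter. For per-bp coverage
`cov`, the filtered trace is the difference between the mean coverage of
the 75 bp to the right and the 75 bp to the left of each position,

$$ f(i) = \frac{1}{150}\Big(\sum_{j=1}^{75} cov(i+j) - \sum_{j=1}^{75} cov(i-j)\Big), $$

a kernel of total size 151 that sums to zero. On a coverage maximum the
right-minus-left difference changes sign from positive to negative, so
peaks are exactly the *descending zero-crossings* of `f`. The kernel width
matches the ~147-bp nucleosome footprint: narrower kernels chase sampling
noise, wider ones merge adjacent nucleosomes of a 165-bp array.

Three numerical conventions matter:

* A crossing is recorded at the position `i` with `f(i) >= 0, f(i+1) < 0`,
  i.e. by its left index. On an exact-zero plateau this resolves,
  deterministically, to the last index of the non-negative run. A mirrored
  genome therefore reports positions shifted by exactly one base (the
  crossing lies *between* two bases and the label follows the left one);
  gene-level results are unaffected and position comparisons in the test
  suite allow that single base.
* The filter is undefined within 75 bp of a chromosome end (`NA`); no peak
  is ever called there.
* Peak height is read from the *original* coverage at the crossing, not
  from the filtered trace, so heights stay in interpretable units
  (reads/bp for raw MNase input, CPM for normalized ChIP input — whichever
  track the caller is given; the promoter scan's height cutoff is stated in
  reads/bp and expects raw coverage).

# The promoter scan

`find_plus_one()` walks the peak list of a gene's chromosome in
transcription orientation, starting 100 bp downstream of the ATG and
ending 2 kb upstream (defaults in `plus_one_params()`). Peaks below the
minimal height (20 reads/bp) are removed *before* pairing: sub-threshold
coverage wiggles — common inside NDRs, where the filter hovers around
zero — must not break the adjacency of the real flanking nucleosomes. The
first adjacent pair satisfying all of

1. center-to-center distance > 200 bp,
2. gene-side peak height > 20 reads/bp,
3. more than 20 bp of the inter-peak region below
   `min + 0.1 (max − min)` of that region's coverage,

defines the NDR (the open interval between the two peak centers); the
gene-side member is the +1 nucleosome and the far-side member the −1. The
first qualifying pair wins and the scan stops — the promoter-proximal NDR
is the object of interest, not the deepest valley within 2 kb. A gene with
no qualifying pair receives an absent call, which is data, not an error.

Distances are center-to-center because dyad centers are the only positions
the caller estimates; valley rule (3) is the only reading of a
relative-depth cutoff that yields a value between the region's minimum and
maximum. Bidirectional promoters are flagged purely positionally: if one
gene's −1 coincides with a divergently oriented neighbour's +1 within a
tolerance (default 50 bp, deliberately generous against jitter in the two
independent calls), both genes are flagged.

# Occupancy calling

Occupancy is maximum-over-window thresholding, not model-based peak
calling: with only a handful of marks, per-mark CPM thresholds read off the
data (or derived as a 95% quantile of genome-wide peak heights with
`quantile_threshold()`, which uses the `h = (n-1)q` linear-interpolation
definition, `stats::quantile` type 7) are transparent and auditable.
Defaults per mark:

| mark | window (up/down of ATG) | threshold | replicates | negative class |
|------|------------------------|-----------|------------|----------------|
| H2A.Z | 200 / 600 bp | 15 CPM | 2 | < 7.5 CPM in all |
| H3K4me3 | 200 / 600 bp | 20 CPM | 1 | — |
| H3K27me3 | 100 / 1000 bp | 15 CPM | 1 | — |

The H3K27me3 window reaches 1 kb into the gene because that mark forms
broad domains over gene bodies rather than sharp promoter peaks. The
comparison operator is `>=` by default and config-visible (`op = ">"`),
since a boundary-exact maximum is a real occurrence with discretized
tracks. The H2A.Z window is oriented 200 bp upstream / 600 bp downstream by
default; the mirrored geometry (600/200) is one `mark_config()` call away
for users who prefer to weight the upstream side. Replicate order never
affects a call: a gene is positive when at least the required number of
replicates reach the threshold, and the explicit negative class (H2A.Z
below 7.5 CPM everywhere) requires *all* replicates to stay low.

# Integration conventions

* Expression is consumed as log2 RPKM
  (`log2(count/(len/1000)/(lib/10^6) + 1)`; the pseudocount of 1 maps zero
  counts to exactly 0) and DE classes use `|log2FC| >= 1` with `p < 0.01`,
  boundary inclusive. DE statistics themselves (the limma/edgeR layer of a
  real analysis) are out of scope: the package classifies, it does not fit.
* Co-occupancy fractions are computed over *genes* (|reference ∩ mark| /
  |reference|). Computing over individual nucleosomes would weight long
  genes more heavily; the gene-level figure is the one the rest of the
  table (occupancy flags, DE classes) is keyed on.
* The +1-anchored matrix takes an asymmetric window (default 1 kb upstream
  to 5 kb downstream of the +1 dyad) in transcription orientation, rows
  sorted by ascending gene length; binned median profiles (default 21 bp)
  use the median for robustness to the handful of extreme-coverage rows
  every real dataset contains. All-missing bins propagate `NA`.
* BLAST conservation counts *distinct subjects* above 40% identity;
  duplicate HSPs against one subject collapse to one hit. Fewer than 50
  hits is "low", more than 300 "high". The e-value cutoff (1e-10) is an
  upstream BLAST setting, recorded in configuration, not re-enforced at
  parse time.

# The synthetic genomes

`simulate_dataset()` generates the study conditions the test-suite measures
recovery against. Defaults: 2 chromosomes of 550 kb, 200 genes (lengths
500–3000 bp, ≥ 2 kb between transcription units), 10% of genes heading a
divergent pair whose ATGs face each other across 240 bp; every gene gets a
+1 dyad 30 bp downstream and a −1 dyad 230 bp upstream of its ATG (shared
across divergent pairs), a 165-bp gene-body array, Poisson fragment counts
per nucleosome (mean 50), fragment lengths ~ Normal(147, 8) truncated to
[100, 250], 10-bp dyad jitter and 10% uniform background. Chromatin classes
(H2A.Z/K4, H2A.Z/K27, K27-only, H2A.Z-only, unmarked at
0.2/0.1/0.3/0.2/0.2) are planted with H3K27me3 in contiguous runs of at
least three adjacent genes, facultative-heterochromatin style; a divergent
pair shares one promoter nucleosome and hence one chromatin state.
Expression follows the class rules (active classes expressed with
probability 0.9, K27-only silent with 0.9, unmarked mixed), and expressed
H2A.Z/K27 genes flip to a strong down response (log2FC ≈ −3, small p) under
the simulated H2A.Z depletion with probability 0.9.

ChIP tracks are generated directly on the CPM scale — flat background at
half the calling threshold, a 6-fold enrichment (3× threshold) over planted
intervals with 50-bp cosine edges, scaled-Poisson noise, replicates sharing
truth but not noise — rather than by sampling reads. This is a deliberate
generator design: occupancy calling consumes normalized coverage, so
modelling the read layer would add cost without exercising any additional
code path. Expression is likewise emitted at the log2FC/p level.

What the generator does *not* emulate, and what passing tests therefore do
not show: sequence-composition and mappability biases, MNase digestion
preference, fuzzy (delocalized) nucleosomes, input-control structure,
antibody efficiency differences between marks, and genuine count-level DE
statistics. Recovery rates on these genomes are a correctness check of the
calling logic under the stated noise model, not a benchmark of expected
performance on real sequencing data.

Problem sizes in the shipped tests are chosen to keep the whole suite
fast while leaving the statistical assertions well-powered: the default
200-gene genome for end-to-end recovery, 1000 genes for the
class-proportion checks (annotation only), and 1000 random vectors for the
filter/oracle equivalence.

# Degenerate inputs and edge behaviour

Empty annotations, empty fragment sets, and genes without any peak in the
search range all produce empty-but-valid results; errors are reserved for
contract violations (fragments outside the declared chromosome, normalizing
an already-normalized track, replicate counts below a mark's requirement,
empty windows after clipping, duplicate gene identifiers). Windows are
clipped to chromosome bounds; a window entirely off-chromosome is returned
empty and rejected only where a maximum over it would be meaningless.
`normalize_cpm` requires an explicit denominator (filtered fragments for
MNase, mapped pairs for ChIP) because the right denominator is a property
of the upstream processing, not of the coverage vector.

# Limitations

The caller assumes phased arrays and a single promoter NDR; tandem NDRs,
internal cryptic promoters and TSS/ATG divergence are outside the model.
Threshold-based occupancy has no error model — replicate agreement is its
only robustness device — and the quantile-derived threshold inherits any
composition bias of the peak universe it is computed over. The simulation's
class-conditional expression is intentionally coarse (three levels plus
noise); it encodes direction, not effect-size realism.
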