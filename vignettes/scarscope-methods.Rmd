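---
title: "scarscope: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scarscope: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarscope)
```

scarscope quantifies the outcomes of DNA double-strand-break (DSB) repair
from six kinds of readout: translocation-junction scar sequences, END-seq
resection tracks around AsiSI motifs, ddPCR repair-reporter counts, CRISPR
clone genotypes, Mendelian cross tables with dose-response curves, and
immunofluorescence foci images. Each analysis stage is paired with a
seeded generator producing synthetic inputs with the statistical structure
the stage assumes, plus a ground-truth table, so every estimator in the
package can be validated by parameter recovery without wet-lab data. This
vignette explains the models, the conventions, and the choices that were
genuinely open.

## Junction scars

A reciprocal translocation induced by two Cas9 cuts is modelled by its
predicted blunt-fusion product: `product = parent_a[0, cut_a) +
parent_b[cut_b, len)`, with the junction coordinate `j = cut_a` (0-based,
half-open coordinates throughout; `j` indexes the first parent-B base).
Cut positions come either from explicit offsets or from protospacers via
the standard Cas9 rule — a blunt cut 3 bp 5′ of the NGG PAM, i.e. between
positions 17 and 18 of a 20-nt protospacer, strand-aware. The cut rule is fixed by Cas9 biochemistry, not by any assay-specific
convention.

Observed junction reads are primer-anchored PCR products, so
classification uses **anchored exact matching** rather than a general
affine aligner: `p` is the longest common prefix of read and product, `s`
the longest common suffix, capped so `p + s` never exceeds
`min(len(read), L)` (excess assigned to the prefix). This maximizes the
anchored bases, which is exactly the minimal-unexplained-bases criterion
the test suite's enumeration oracle uses; the greedy cap is provably
optimal because prefix/suffix matchability is monotone. The scar is then:

* deletion: the unexplained product interval `[p, L - s)`, `d = L - p - s`;
* insertion: the unexplained read core `read[p, len - s)`;
* microhomology (MH): the junction-shift ambiguity of the deletion within
  the product — the maximal left slide `m_left` with
  `product[p-k, p) == product[L-s-k, L-s)` plus the analogous right slide,
  reported as length, sequence and half-open span.

MH is a property of the two product flanks, so it is reported for the
deletion anchors even when an insertion co-occurs, and a read with `d = 0`
and no insertion has `m = 0` by definition. For insertion-free reads the
product-flank definition coincides exactly with the set of equally
minimal anchored decompositions (the breakpoint-shift range); with an
insertion the two notions can diverge when an inserted base happens to
match the product, and the package standardizes on the product-flank
definition. Reads with an `N` adjacent to the junction, or with an anchor
shorter than `min_anchor` (default 10 bp), are flagged excluded rather
than dropped, mirroring the exclusion of Sanger traces that cannot be
deconvolved; a read identical to the product is never excluded.

Deletion-size summaries use the midpoint median (half-integer medians are
the expected output format for junction spectra). Per-coordinate
deletion/MH frequency profiles count, at every product coordinate in
`[j - window, j + window)`, the fraction of non-excluded reads whose
deletion interval (or MH span) covers it. Translocation frequency from
well grids defaults to the ≥1-of-2-technical-replicates positivity rule;
because the underlying phrase "positive wells across both technical
replicates" is ambiguous, `"all"` and `"sum"` rules are provided.

**The junction generator** emits reads that are the product with one
contiguous deletion whose interval intersects the closed window
`[j - 1, j + 1]` (junction PCR only recovers junction-proximal scars),
sized by a geometric distribution with mean 20 bp by default — published
junction spectra are usually summarized only by medians (~15–20 bp in
TMEJ-proficient cells), so the distribution family is a stated convention
of the generator, not an empirical fact. With
probability `mh_propensity` (default 0.5) the deletion is placed at a
flanking repeat when one exists; otherwise a slide-free placement is
preferred. Insertions (rate 0.1, geometric lengths, mean 3 bp) are
canonicalized: an inserted base that would extend an anchor is redrawn,
so each generated read has a unique minimal scar representation and the
truth table is recoverable in principle. Truth always records the
re-measurable scar of the emitted read. What a green recovery test does
*not* establish: robustness to sequencing error, to chimeric reads, or to
scars produced by multiple repair events — none of which the generator
emulates.

## END-seq resection

END-seq maps DSB ends; around a cut AsiSI site (GCGATCGC, palindromic,
hence a forward-strand scan is complete) the signal width reports how far
5′→3′ resection travelled. The generator draws, per site and per side,
`reads_per_site` endpoint distances from an exponential distribution
(single parameter, heavy right tail — the minimal model for tract
lengths; gamma available), deposits them as single-base end counts moving
outward from the site center, and adds uniform Poisson background.

Quantification follows the figure pipeline: normalize (reads per
million; the choice of normalization is a convention), bin ±20 kb in
250-bp bins, call cut sites by central enrichment (mean of ±1 kb at least
5× the pooled median of the outermost 5 kb flanks, floored at a 0.25
count/bin pseudocount), and measure resection as the distance from the
center to the farthest contiguous bin whose smoothed signal stays at or
above 10% of peak height. Bin size, enrichment factor, height fraction and smoothing width have no
field-wide standard; all are exposed with these defaults and recorded
here as conventions. For an exponential
profile with tract-length scale λ the threshold crossing sits at
`λ·ln(10)`, so the estimator is linear in λ — ratios and rankings of true
means are preserved, which is what the recovery tests assert.
`combined_bp` is the per-site summary, `max(left, right)` by default
(resection is often asymmetric; the max tracks the measurable tract; mean
and sum are available). Ranking takes the top 20 sites by convention.
Strand-resolved tracks, when provided, drive their respective sides
(minus → left, plus → right).

Recovery and rank-correlation tests draw per-site true means lognormally
(sdlog 0.25) around the condition mean: identical means would carry no
rank signal, so the spread is part of the generator's stated world.

## Reporter assays and clone genotypes

ddPCR partitions a sample into ~0.85-nl droplets (industry-standard
volume; configurable); copies land in droplets as Poisson, so the mean
occupancy is recovered from the positive fraction `f` as
`λ = -ln(1 - f)` and concentration is `λ/volume`. A saturated reaction
(`f = 1`) is an error, not infinity. HR activity is repair copies per 100
genomic copies from a control reaction; TMEJ activity is the sum of the
three signature deletion products (del23bp, del39bp, del95bp) divided by
the same sum in the wild-type reference, so the reference scores 1.

CRISPR clones are binned by frameshift status: an allele is frameshift
iff its net indel length is not a multiple of 3 (compound alleles use the
summed net length — the natural reading when an allele carries
several indels), and a clone is a
knockout only if every reported allele (frequency above the 1% reporting
floor) is frameshift. In-frame indels and missense alleles both map to
"retains function". The knockout fraction excludes unedited clones from
the denominator.

## Cross statistics and dose-response

Loci are treated as unlinked (the crosses of interest involve genes on
distinct chromosomes); per-locus transmission probabilities multiply, and
lethal genotype predicates thin matching classes by a survival fraction
(partial lethality is modelled because some genotypes are born at around
half the expected rate) before renormalization. Genotype labels are
canonical: uppercase allele first, multi-character alleles "/"-joined,
byte-order sorting so labels are locale-independent. Goodness of fit is
the plain chi-square `Σ(O - E)²/E` with `df = k - 1` (matching the stated
test, even at small counts); the per-genotype "binomial" test is the same
statistic on the 2-category collapse, df = 1, no continuity correction.
Marker-chromosome counts are scaled to 40 chromosomes per metaphase, the
diploid mouse complement.

Dose-response curves use the 4-parameter log-logistic
`y = bottom + (top - bottom)/(1 + (d/ic50)^hill)`, fit by least squares
(`nls` port algorithm; bounds `bottom ≥ 0`, `top ≤ 1.2 × max`; quartile
initialization; Nelder-Mead fallback) after normalizing to the mean
vehicle response. IC50 is the midpoint concentration; fold change is the
ratio to a reference fit. A single noisy fit at 10% CV has an IC50
sampling sd of roughly 3.5%, so the package follows the standard
reporting procedure for colony-assay IC50s — fit each independent
replicate experiment and average the IC50s (typically n = 3-4 biological
replicates) — which the tests reproduce with a 2-fold dilution series and triplicate wells.
Flat response curves are rejected as unidentifiable rather than fitted.

## Foci counting

The counting pipeline reimplements the classic macro: background
subtraction, linear contrast rescale saturating 0.35% of pixels per tail
(the ImageJ default), Gaussian blur (σ = 1 px), a fixed absolute
threshold on the rescaled image (default 0.35), then connected-component
particle counting inside each nucleus label with a 4–400 px area gate.
Background subtraction uses grayscale opening with a disk (radius 8 px) —
the same idempotent estimate as a rolling ball with a simpler contract —
computed on a lightly pre-smoothed copy (σ = 1), because opening a raw
noisy image tracks noise minima and biases the background low; rolling-
ball implementations pre-smooth for the same reason. In practice such macro thresholds are confirmed manually per experiment
and are not portable, so these defaults are calibration choices validated
by recovery: exact
counts on noise-free stacks, and ≥95% of nuclei within ±1 focus under
Poisson noise at spot SNR 5 (peak amplitude = 5 shot-noise sd).

The generator places non-overlapping disk nuclei (radius 18 px, intensity
100 on background 5) on a jittered grid, draws per-nucleus focus counts
(Poisson, mean 5), and places Gaussian spots (σ = 1.5 px) with a minimum
pairwise separation of 5σ — closer pairs would merge under the analysis
blur and the truth would be ill-posed; requesting more foci than the
nucleus can hold at that separation is an error. Poisson noise replaces
each pixel by a Poisson draw with its intensity as mean. Not emulated:
uneven illumination, touching nuclei, z-structure (images are treated as
maximum-intensity projections), and channel cross-talk; 2-D only.

Images are plain numeric matrices; file I/O uses text TSV matrices
(`write_image_tsv()`), keeping all fixtures text-based.

## Numerical and interface conventions

* Coordinates 0-based half-open everywhere; bedGraph for tracks
  (via rtracklayer), FASTA for sequences (via Biostrings), TSV with
  header for tables.
* All generators draw from one top-level seed through named substreams
  (`substream_seed()`), so stages regenerate independently and
  byte-identically.
* `N` matches nothing in sequence comparisons.
* Ties in site ranking break by (chrom, pos); the overlap tie-break in
  junction anchoring assigns excess to the prefix, and downstream
  profiles are tie-break-invariant because the MH span reports the full
  ambiguity.

## Known limitations

Single-junction scars only (no inversions, no multi-break rearrangement
simulation, no chromatogram deconvolution); no read alignment or
duplicate handling for END-seq (aligned coverage in, per the upstream
toolchain being out of scope); no differential-resection statistics; no
watershed splitting of touching nuclei; the synthetic data state simple
noise models (Poisson intensity, lognormal multiplicative) chosen to be
testable in closed form, not to reproduce instrument detail.
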