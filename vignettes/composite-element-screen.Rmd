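---
title: "Screening for composite EcR-AP-1 regulatory elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for composite EcR-AP-1 regulatory elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrap1)
```

## Overview

`ecrap1` implements a composite-element screen for regulatory regions
where the ecdysone receptor (EcR) is recruited to DNA through AP-1 rather
than through its own response element, plus the downstream annotation,
gene-context and image-quantification analyses that accompany such a
screen. Every stage can be driven either by real files (FASTA, BED,
GFF/GTF, PNG/TIFF) or by the package's synthetic-data generators, which
plant a known ground truth that the pipeline must recover. This vignette
records the model, the parameters that matter, the numerical conventions,
and the design decisions that were genuinely open.

## Coordinates

All genomic coordinates inside the package are 0-based half-open (BED
convention). GFF/GTF input, which is 1-based inclusive, is converted at
the I/O boundary (`start - 1`, `end`) and converted back on writing, so
interval lengths are invariant and round trips preserve the original
coordinates. A single convention internally removes the off-by-one class
of bugs that plagues mixed-convention code; the BED-facing side needs no
conversion at all.

## Degenerate motif matching

A motif is a consensus over the 15 IUPAC codes, compiled to a
per-position set of allowed unambiguous bases. Matching semantics:

* **Genome `N` matches nothing**, including a motif `N`. A site is never
  counted unless every one of its bases can be confirmed from sequence.
  This is deliberately conservative: on assemblies with N-gaps the screen
  can only undercount, never overcount.
* **Both strands are scanned**; hits are reported as plus-strand spans.
  The AP-1 consensus TGANTCA is its own reverse complement, so its plus-
  and minus-strand matches coincide span for span; palindromic motifs
  therefore report **one hit per genomic span** (strand `+`). Without
  this dedup every AP-1 site would count twice and the "at least four
  sites" filter would effectively become "at least two". Non-palindromic
  motifs keep strand-distinct hits.
* **Overlapping occurrences are all counted.** No exclusion or greedy
  masking rule is applied; counting every matching offset is the simplest
  auditable semantics. (TGANTCA cannot overlap itself, so this choice
  does not affect the AP-1 counts; it matters for user-supplied motifs.)

The production scanner is vectorised per motif position; the test suite
holds it to an independent, naive oracle that tests every offset on both
strands with per-character set membership, on 100 random 10-kb sequences,
and additionally checks the analytic expectation for uniform sequence:
a palindromic 7-mer with one free position matches a random offset with
probability $4^{-6}$, so a 10-kb uniform sequence carries
$(10{,}000-6)\cdot 4^{-6} \approx 2.44$ expected spans (checked over 200
seeds against the Monte-Carlo standard error).

## The composite-element screen

A candidate region passes iff it contains at least `min_ap1` (default 4)
AP-1 occurrences and zero EcRE occurrences, counting only occurrences
**fully contained** in the region — regions are the unit of the screen,
and a site straddling a boundary cannot be attributed to the region with
confidence. The screen's configuration (both consensi and `min_ap1`) is
attached to its output and written into the TSV report header, so any
run is reproducible from its report alone.

Two parameters deserve comment:

* **EcRE consensus.** The screen's exclusion motif defaults to
  `RGGTCANTGACCY`, the canonical hsp27-derived palindromic EcRE. This is
  the standard literature consensus, but it is supplied as an ordinary
  `iupac_motif` argument so that a user who prefers a different EcRE
  definition can substitute it without touching the screen.
* **`min_ap1` = 4.** The published screen threshold. Raising it can only
  shrink the passing set (a monotonicity the tests enforce over
  `min_ap1` in 1..8).

The screen cannot reproduce the published 51-of-502 result itself — that
would require the original Kc167 EcR–Usp region set and its genome
assembly, which are external data. What the package verifies instead is
the screen's *mechanics* at that scale: a synthetic 502-region set
constructed so that exactly 51 regions carry a passing composition is
screened, and the screen must rediscover exactly those 51 from sequence
alone.

## Peak-overlap classification

Each AP-1 occurrence is classified against ChIP-seq peak sets:
**green** if it overlaps at least one EcR peak; **red** if it overlaps
Jun and/or Kay (Fos) peaks but no EcR peak; **blue** if it overlaps
none of EcR/Jun/Kay. Overlap means at least one shared base between the
motif span and the peak (half-open arithmetic, no slop window — the
simplest auditable rule).

Two points were genuinely open and are resolved as follows:

* **Precedence.** The colour scheme does not say what happens when a
  site overlaps both EcR and Jun/Kay peaks. We assign green > red > blue
  — EcR binding is the subject of the screen — and report *every*
  overlapping factor in `overlapping_factors`, so the precedence choice
  loses no information.
* **Usp.** Usp peaks never change the category (the colour rules name
  only EcR/Jun/Kay) but are recorded in `overlapping_factors`, preserving
  observations like a Usp-only binding event at a region.

## Gene context

* **Assignment.** A region is assigned to every gene it is contained in,
  overlaps, or lies within `window` bp of. "Near" has no canonical
  definition; the default window is 10 kb — the order of the intergenic
  distances in the loci this screen targets — and is a prominent,
  reported parameter. Distance is the gap between closest edges; for
  touching (adjacent half-open) intervals the gap is 0 and the relation
  is `near_gene`, a documented boundary case.
* **Gene size.** Size statistics use the gene *span* (`end - start`),
  not the exon union, because the comparison of interest — candidate
  genes roughly twice the size of the average gene (≈22 kb vs ≈11 kb) —
  is about gene extent and its large introns.
* **Motif density.** Occurrences fully inside the span, per 10 kb. A
  ~50-kb control gene planted with 5 sites has density 1.0 per 10 kb,
  the background rate reported for large genes not under JNK/20E
  control.

## Image quantification

Two quantifiers mirror the standard manual FISH procedures:

* **ROI pixel fraction** (amnioserosa-style): the image is thresholded
  and the number of signal pixels inside a hand-drawn polygon ROI is
  divided by the ROI's pixel surface area. We fix "signal" as intensity
  `>= threshold` (the original procedure inverts the image so that
  signal is black; apply any inversion before calling — the direction
  had to be fixed somewhere and is documented here). The threshold is an
  explicit parameter, to be held constant across the images of one
  comparison; the package does not auto-threshold.
* **Strip mean gray value** (leading-edge-style): the arithmetic mean
  intensity of a rectangle of fixed size. `fixed_size` enforces the
  constant-selection-size rule across a batch: a mismatched rectangle is
  an error, not a warning, because mean gray values from different areas
  are not comparable.

**Polygon rasterization** uses the even-odd (crossing-number) rule
evaluated at pixel centres `(c - 0.5, r - 0.5)`. Any point-in-polygon
convention would do; what matters is that the convention is stated, so
ROI areas are reproducible across implementations (the suite
cross-checks against an independent point-in-polygon routine). Polygons
must be simple; self-intersecting vertex lists are rejected.

**Group comparison** is a two-sided equal-variance Student's *t*-test
with group summaries as mean ± s.e.m. (`sd/sqrt(n)`), matching the
field's reporting convention. One numerical edge case is handled
explicitly: noiseless synthetic data can produce groups with zero pooled
variance, where the *t* statistic is undefined. Rather than erroring,
`compare_groups()` returns `t = 0, p = 1` for identical means or
`t = ±Inf, p = 0` otherwise, flagged `degenerate = TRUE`. The suite
checks calibration (type-I rate at α = 0.05 over 1,000 null replicates,
within 99% binomial bounds) and power against the closed form.

**PLA classification** uses a centroid-in-mask rule: a punctum is
nuclear iff the pixel containing its centroid is inside the binary
nuclear mask. Puncta are small relative to nuclei, so the centroid pixel
is an adequate and maximally simple criterion; an area-overlap rule
would add a parameter (the punctum radius) without changing calls except
exactly at nuclear boundaries.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
verified:

* `gen_genome()` — i.i.d. background at a chosen GC content (default
  0.5) with concrete motif instances written at prescribed coordinates.
  With `clean_background = TRUE` the finished genome contains **no**
  occurrence of any dictionary motif besides the planted ones: after
  planting, each spurious occurrence is destroyed by mutating one of its
  constrained, unprotected positions to a disallowed base, re-scanning
  to a fixpoint. Local mutation (rather than wholesale resampling) keeps
  base composition essentially unchanged while making planted counts
  exact.
* `gen_region_set()` — a genome plus equally sized regions realising a
  prescribed (AP-1, EcRE) composition per region; sites are placed in
  per-region slots so they cannot overlap each other or region
  boundaries. The screen on this output must reproduce the prescription
  exactly, for any seed.
* `gen_peaks()` — padded peaks over chosen planted sites per factor, so
  classification reproduces the plan exactly.
* `gen_genes()` — gene spans from a gamma distribution (shape 4: right-
  skewed, strictly positive, a realistic span shape) at a chosen mean;
  used to plant the 22-kb-vs-11-kb size contrast.
* `gen_fish_image()`, `gen_strip_image()`, `gen_pla_image()` — one
  generator per quantifier: exact planted signal-pixel counts, exact
  strip means, exact nuclear/cytoplasmic partitions (e.g. 95 of 131
  puncta cytoplasmic, the wild-type-like regime; 44 of 131, the
  hormone-treated-like regime).

Every generator is a pure function of its seed and spec; one global seed
expands into per-component child seeds through a documented integer
derivation (`child_seed()`), so components are independent but a single
`--seed` reproduces an entire run.

**What the generators do not emulate** — and therefore what passing
tests do *not* show about real data: realistic *Drosophila* base
composition, repeat structure or chromatin context (motif counts on real
genomes are burstier than i.i.d. background); ChIP-seq peak-calling
noise (peaks are placed, not called); optical blur, uneven illumination
and segmentation error in images (ROIs and nuclear masks are inputs, not
inferred); and the hand-selection step of the original procedures, which
the package deliberately takes as given rather than automating.

## Problem sizes

The shipped checks run at sizes chosen to make Monte-Carlo error small
relative to the tested effects while keeping a full run fast on one CPU:
100 random 10-kb sequences for scanner/oracle identity, 20 seeds for
planted-truth recovery, 200 seeds for the analytic-density check, a
502-region fixture for screen mechanics, 10,000 random interval pairs
for the overlap oracle, 1,000 null replicates for t-test calibration,
and 60 + 300 genes for the size-ratio recovery. Stochastic checks assert
within 3–4 standard errors of their targets, never to a hand-picked
absolute tolerance.

## Known limitations

* The screen's published result (51 of 502 regions) depends on external
  region sets, peak files and an unstated genome assembly; the package
  verifies the method, not that number, and treats assemblies as opaque
  user-supplied files.
* Whether the original screen counted a palindromic site once or twice
  is unstated; span-dedup (count once) is the package's documented
  default and the conservative choice for an "at least four" filter.
* Motif matching is consensus-based by design; no PWM scoring, match
  p-values or motif discovery are provided.
* `read_gff_genes()` supports the common flat case (exons whose
  `Parent`/`gene_id` names the gene directly); deep
  gene→mRNA→exon hierarchies should be flattened upstream.
* The t-test is the field's reporting convention and is provided as
  such; it assumes equal variances and approximate normality, which the
  noiseless generators trivially violate (zero variance) — hence the
  explicit degenerate handling.
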