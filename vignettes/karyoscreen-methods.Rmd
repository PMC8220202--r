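---
title: "Methods: karyotype recurrence, FISH fusion calling, and the breakpoint-window expression screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: karyotype recurrence, FISH fusion calling, and the breakpoint-window expression screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoscreen)
```

# The biological setting

Barrett's esophagus is a premalignant columnar metaplasia of the esophageal
lining in chronic reflux patients and the precursor lesion of esophageal
adenocarcinoma. In an *in vitro* carcinogenesis model, telomerase-immortalized
Barrett's epithelial cells exposed daily to acidified bile salt acquire, in
independent replicate cultures, the same three-way chromosomal translocation
t(2;10;16)(p22;q22;q22) — together with a doubled chromosome-20 gain — weeks
before any malignant phenotype appears. Break-apart/fusion FISH probes
spanning the three breakpoints turn this event into a countable assay
(co-localized red/green = fusion), and RNA-seq of the culture time points
shows expression changes concentrated around the breakpoints.

`karyoscreen` implements the three computational readouts of that design —
karyotype recurrence mining, FISH signal calling, and the breakpoint-window
fold-change screen — plus a synthetic-data generator that stands in for the
raw cells and tissues so that every stage is testable end to end.

# Karyotype model

A karyotype is a modal chromosome count, a verbatim sex designation, and an
*ordered multiset* of aberrations. The parser covers exactly the dialect
that occurs in replicate-culture karyotype tables of this kind: `add`
(added material of unknown origin), `i` (isochromosome), `dup`, multi-way
`t`, and `+n`/`-n` whole-chromosome gain and loss. Everything else (`der`,
`ins`, `inv`, mosaic `[n]`, `?`) is rejected with an error naming the token
and its position — honest scope beats silent misparsing, and the grammar is
a single function to extend.

Three deliberate choices:

* **Multiset semantics.** `+20,+20` is two entries, not one; recurrence
  mining reports membership (how many karyotypes carry the event at all)
  and multiplicity (how many carry it twice or more) separately. The
  doubled-gain-in-four-of-six readout depends on exactly this
  distinction between trisomy and tetrasomy.
* **Band resolutions instead of a verdict.** Published tables print the
  same recurrent translocation with terminal bands q22 and q21 in different
  replicates. Whether that is a typographic variant or a genuinely distinct
  breakpoint is unknowable from printed text, so `match_aberration` exposes
  `exact`, `major_band` (arm + first band digit, q21 ≡ q22 ≡ "q2") and
  `chromosomes_only`, with the guarantee that matches are nested across the
  three levels. `major_band` merges q21/q22 without equating distant bands
  such as q2x and q3x.
* **Sex field stored verbatim.** Strings like `48,XY` are not internally
  consistent with strict ISCN sex-count rules; validating them would reject
  real published data.

`diff_karyotypes` performs a greedy multiset difference under the chosen
resolution; re-applying the reported gained/lost sets reconstructs the
target multiset (a property the tests check on random karyotypes).

# FISH enumeration rules

Cells are *counts*, not images: colocalization is assumed resolved upstream
by the microscopist or the imaging software. Per nucleus the classifier
applies, in strict precedence:

1. any co-localized (yellow) signal → `fusion_positive`;
2. exactly two red and two green → `normal`;
3. three or more of either color → `gain_or_break` (gain of a chromosome or
   a break without fusion — indistinguishable from counts alone);
4. anything else → `uninformative`.

Rule 1 before rule 3 means a (3,3,1) cell is fusion-positive: the yellow
signal is the defined positive event, while the same-color-surplus rule is
explicitly ambiguous. The `uninformative` category is a package addition:
nuclei truncated by 4–5 µm sectioning routinely lose signals, standard FISH
practice excludes them from the denominator, and the published enumeration
rules are silent about them. Exhaustive enumeration of all count triples up
to 6 against an independent restatement of the rules is part of the test
suite; the rules are total and deterministic.

Sample calls require at least `min_cells = 25` informative nuclei (the
minimum scored per hybridization) and by default `min_fusion_cells = 2`
fusion-positive nuclei for positivity. The 2-cell bar operationalizes
"multiple cells … some with a fusion signal"; it is a package convention —
no published per-cell threshold exists — and both knobs are arguments.

# Expression normalization and the window screen

The normalization is two exact steps:

1. **Median adjustment**: each sample is divided by its own median over
   *all* genes, zeros included, making the per-sample median exactly 1. A
   median ≤ 0 is an error by default; `nonzero = TRUE` switches to the
   median of expressed genes (the variant phrasing that appears in figure
   captions).
2. **Log transform**: `expression = log10(1 + 99 · x)`. Fixed points by
   construction: unexpressed genes stay at 0, the median gene maps to
   exactly 2. Both are asserted to 1e-12 in the tests.

**Signed fold change.** A ratio `r` is reported as `+r` (r ≥ 1) or `-1/r`,
so magnitude reads the same in both directions and `|fc| ≥ 1` always. The
default `shifted` mode computes `r = (1 + 99a)/(1 + 99b)`, i.e. `10^` of
the normalized-expression difference. It is finite when a denominator gene
is off (a median-level gene against an absent one gives ±100) and is
self-consistent with the transform used for the landscape plots; that
consistency is why it is the default, and it is how a silent/expressed
flip can legitimately produce the hundreds-fold values seen in published
window tables. A `raw` mode (`(a + ε)/(b + ε)`, ε = 0.01) is available
where plain FPKM ratios are wanted; ε only matters for near-zero
denominators.

**Windows.** The probes' genomic extent is not published, so the three
windows (2p22, 10q22, 16q22) default to the minimal Hg19 intervals covering
the published breakpoint-region gene coordinates (chr2 27.71–33.79 Mb,
chr10 81.66–90.68 Mb, chr16 66.96–68.31 Mb), and membership is ≥ 1 bp
overlap, not containment. Window geometry is ordinary data
(`region_window`), not hard-coded policy. Internally all coordinates are
1-based inclusive; BED input/output converts at the boundary (via
rtracklayer).

**The p-value.** The design has one sample per time point, so no
replicate-based test exists; any p-value here is a reconstruction. The
package uses a two-sided empirical null: a window gene's `|log10 fc|` is
ranked against the genome-wide background of all non-window genes,
`p = (1 + #{bg ≥ obs}) / (1 + n_bg)`. A gene "passes" when `|fc| > 2` and
`p < 0.025`. The +1 correction keeps p valid (never exactly 0) and the
screen conservative at small background sizes. This choice is a
convention, clearly not the (unstated) method behind published tables;
with only the filter thresholds shared, exact gene lists should not be
expected to reproduce.

# What the synthetic generator emulates — and what it does not

`gen_expression_dataset` draws a gene-level log-normal baseline
(`meanlog = log(5)`, `sdlog = 1` — a realistic several-orders-of-magnitude
abundance spread with median FPKM ≈ 5), multiplies by independent
per-sample log-normal noise (`background_sd = 0.2` on the natural-log
scale, ≈ 1.2-fold typical between-sample variation — the technical scale
appropriate to comparing cell-line time points without biological
replicates), zeroes out a 5% fraction of genes in all samples (exercising
the transform's 0 fixed point), and multiplies planted effect genes by
their true fold ratio in the contrast numerator sample. Effect genes sit at
the typical (median) baseline: a fold change planted on a nearly silent
gene is attenuated by the shifted transform, which is a property of the
method, not of the generator. The baseline is shared across samples rather
than redrawn per sample — between-sample ratios are what the screen
measures, and only the noise term should drive them; the marginal
distribution per sample is still log-normal.

Annotation places effect genes uniformly inside their declared window and
all other genes in fixed regions disjoint from every window, so a
background gene can never contaminate a window (a tested invariant).

`gen_fish_cells` draws nucleus states from a mixture (`normal`, `gain`,
`break_no_fusion`, `fusion`), emits the canonical count signatures
((2,2,0); one extra of a random color; 3 + 2; and for fusion one red and
one green consumed into the co-localized signal, giving (1,1,1) — the
consumption is configurable since some scoring schemes keep (2,2,1))
and then applies two noise processes: independent per-signal dropout
(section truncation) and per-red/green-pair spurious colocalization.
`gen_karyotype_set` serializes a base karyotype with added aberrations at
a configurable penetrance (or an explicit carrier vector), adjusting the
modal count by the net gain/loss.

The generators do **not** model hybridization chemistry, probe design,
image formation, tissue heterogeneity, or correlated gene expression
(co-regulation, GC/length biases). Passing tests on this synthetic data
demonstrate that the *rules and estimators* are implemented correctly and
are recoverable under calibrated noise — not that real tissue sections or
real RNA-seq will behave as cleanly.

Every generator takes an explicit seed, restores the caller's RNG state on
exit, and is bit-reproducible under a fixed seed.

# Numerical and degenerate-input choices

* Median adjustment uses `stats::median`; division preserves the median
  exactly in floating point, and the operation is idempotent.
* Ties in window extraction and landscape tracks break by gene id after
  start coordinate, making output order deterministic.
* `classify_cell` rejects negative or non-integer counts; `call_sample` on
  an empty table returns `insufficient_cells` with zero tallies rather
  than erroring.
* Empirical p-values use the +1-corrected rank, so `p ∈ (0, 1]` always.
* `find_recurrent` on empty input returns an empty table; group
  representatives are first-seen, and rows sort by descending membership
  then representative string.
* Parse errors always name the offending token and its field position;
  whitespace anywhere in a karyotype string is ignored (published tables
  space tokens inconsistently), and unicode minus/en-dash normalize to `-`.

# Problem sizes in the shipped tests

The test suite and demo run at deliberately small scale: 400–500 gene
matrices over 4 samples, 100 replicate screens for the recovery study,
10,000 nuclei for the binomial consistency checks, and 6,000 replicates
for the penetrance check. These sizes give the stochastic assertions
comfortable margins (e.g. binomial 99% bounds of ±1.3 percentage points at
n = 10,000) while keeping a full run in tens of seconds.

# Known limitations

* The ISCN grammar is the dialect above, not full ISCN 2020; derivative
  chromosomes, insertions, inversions and mosaicism are rejected, and no
  band-to-genome-coordinate mapping is attempted.
* The empirical-null p-value is a reconstruction (see above); with single
  samples per condition it measures "extreme relative to the genome-wide
  contrast distribution", nothing more.
* Tissue-level claims (what fraction of tumors carry a fusion) depend on
  per-cell data that published work does not provide; the package can only
  assert behavior on simulated cohorts.
* `gain_or_break` is irreducibly ambiguous from counts; resolving gain vs
  break requires probe-design knowledge outside the scoring rules.
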