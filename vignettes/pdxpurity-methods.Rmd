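---
title: "Models and methods behind pdxpurity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pdxpurity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxpurity)
```

# The two problems

A patient-derived xenograft (PDX) sample is always a human/mouse DNA
mixture: the engrafted tumor cells are human, the stroma that the host
rebuilds around them is mouse, and occasionally a spontaneous murine tumor
(most often lymphoma in severely immunodeficient strains) replaces the graft
outright. `pdxpurity` implements (i) the ssPAL assay's computational half —
turning fragment-analysis traces into murine DNA fractions and origin calls
— and (ii) a fully synthetic "virtual PDX" benchmark measuring what mouse
read contamination does to somatic mutation calling.

# ssPAL quantitation

## Model

Each ssPAL primer pair amplifies a locus conserved between the species whose
PCR product lengths differ slightly: pair 5 gives a 272 bp human and 278 bp
mouse product, pair 43 a 211 bp human and 206 bp mouse product. On a
capillary-electrophoresis trace the two products appear as well-separated
peaks, and the peak areas are proportional to the species template amounts,
so the murine fraction is the area ratio
$f = A_\text{mouse} / (A_\text{mouse} + A_\text{human})$.
Per-pair fractions always sum to one by construction; the sample-level value
is the plain arithmetic mean of the available pairs. Whether the original
assay averaged replicate PCRs with weights is not documentable from the peak
tables alone; the plain mean matches how the two pairs are combined into a
single passage curve and is what we use throughout.

## Trace synthesis

Synthetic electropherograms are sampled on a 0.1 bp grid spanning both
amplicon sizes ±15 bp: a Gaussian at each amplicon size with area
proportional to the species fraction, a constant baseline, plus i.i.d.
Gaussian intensity noise truncated at zero. Defaults:

* `peak_sigma` = 0.4 bp — a sharp capillary peak, a few grid points wide;
* `noise_sd` = 0.002 × the major peak height — clean modern instrument
  baseline ripple, low enough that a 1% minor component (relative height
  ~0.01) stands clear of the noise floor;
* `baseline` = 0.

These defaults are the "study conditions" of every dilution-series and
calibration result in the tests: with them the 1% detection limit of the
real assay is reproducible, and at 0.5% detection becomes unreliable
(roughly half the replicates), which matches the assay's stated 1–99%
sensitivity range.

## Peak detection and integration

The baseline is estimated as the median intensity and subtracted. Local
maxima are located on a 5-point (0.5 bp) moving average of the trace —
without this, grid-level jitter in a noisy trace splits single peaks into
twin maxima — while heights and areas are always measured on the unsmoothed
baseline-subtracted trace. Maxima closer than 0.5 bp are merged (taller
wins). A peak's bounds are its flanking minima, capped at centroid ±3 bp
(7.5 σ at the default width, so >99.999% of a Gaussian's area is inside);
its area is the trapezoid integral between the bounds. On noise-free
single-Gaussian traces the integral matches the analytic area
$h\sigma\sqrt{2\pi}$ within 1%.

`min_rel_height` defaults to 0.005 of the global maximum: half the relative
height of a 1% mouse component, and ~2.5 noise SDs above zero, so real minor
peaks pass while most baseline ripple does not. Spurious noise maxima that
do pass are harmless: species assignment only accepts peaks within `tol` =
1.5 bp of an amplicon size, keeps at most one peak per species, and breaks
ties by area. The 1.5 bp default leaves margin against centroid error while
staying below half the smallest inter-species gap (5 bp for pair 43), the
point past which assignment would be ambiguous.

## Censoring, classification, published panel

Combined fractions below 1% or above 99% are flagged (`below_1pct` /
`above_99pct`): outside that range the assay loses sensitivity and the
number should be read as a bound, not a value. Classification of the species
of origin is a strict step: `suspect_mouse` iff the combined fraction is
strictly greater than the 95% threshold, so exactly 95% is still called a
human tumor.

The package ships a small TSV panel of published per-pair ssPAL percentages
for four PDX lines that STR analysis later confirmed were not human tumors.
One row's percentages sum to 100.1 (printed rounding); such rows are
renormalized by their sum before use — a package decision, made once.
Applying the strict rule to the pair-averaged panel flags all four lines,
including the one whose pair-5 value alone (94.5%) sits below the cutoff —
which is why classification uses the pair-averaged fraction rather than any
single pair.

# The virtual-PDX benchmark

## Synthetic genome pairs

The human contig is drawn i.i.d. over ACGT and acts as the ancestor; the
mouse homolog is derived from it by i.i.d. substitutions at a configurable
per-base divergence (default 10%, the order of human/mouse divergence in
alignable regions). One-directional derivation keeps amplicon placement
deterministic. Inside each embedded ssPAL locus the two ~20 bp primer sites
are copied unchanged and a single indel in the amplicon interior sets the
mouse product length, so orthologous amplicons differ in length exactly as
the real loci do while remaining amplifiable by the same primers. The
simulator introduces no other indels, which is why the aligner can be
ungapped.

## Reads, mutations, virtual samples

Reads are single-end, fixed-length (default 100 bp), constant-quality, with
uniform starts and strands and i.i.d. substitution errors; per-contig read
count is `round(depth × L / read_len)`. Paired-end structure and quality
models would add nothing to the contamination question, which is purely
about read counts and species assignment.

Somatic truth sets sample distinct positions uniformly on the human contigs
with the alternate allele uniform over the three non-reference bases. VAFs
cycle through {0.05, 0.1, 0.2, 0.5} by default — the real spike-in set's VAF
distribution is not documented, so this grid is a package choice spanning
"clearly subclonal" to "clonal heterozygous"; `n` divisible by 4 gives a
balanced design. Spiking is per-read Bernoulli(VAF) at each covering read
(haplotype structure is out of scope; the marginal pileup VAF is what
matters and is binomial by construction).

The three virtual samples mirror the real construction: virtual normal
(30×) and virtual tumor (60×, mutations spiked) are two *independently
seeded* simulations of the same genome — the analogue of two technical
replicates — and the virtual xenograft replaces each tumor read
independently with probability λ by a mouse read drawn without replacement
from a mouse pool, preserving total read count exactly. Whether the original
replacement was exact-fraction or Bernoulli is not stated anywhere we can
check; Bernoulli is simpler and its variance is testable. Count-preserving
replacement (rather than adding mouse reads on top) is our reading of
"replaced": total depth stays constant and human depth scales as (1−λ).

## Hybrid-reference alignment

The reference is the concatenation of all human and mouse contigs. The
aligner indexes every forward k-mer position (k = 15 by default) and, per
read and orientation, looks up exact seeds at three fixed offsets (start,
middle, end), then scores every candidate placement by ungapped full-length
comparison (score = matches − mismatches, i.e. len − 2·mismatches). A read
is `unique` with exactly one best-scoring placement, `ambiguous` on ties,
`unmapped` above `max_mismatch` (default 10% of read length — at 10%
divergence a read's second-species placement carries ~10 mismatches per
100 bp, so cross-species placements lose to the true one but remain
plausible seeds). Ambiguous reads are dropped entirely rather than assigned
at random: how the original pipeline's aligner resolved multi-mapping reads
is not recoverable, and dropping them reproduces the multi-mapping depth
loss in an auditable way. Ties need no further tie-break — a tie *is* the
ambiguous status. Coordinates are 0-based half-open internally and 1-based
only in VCF output.

## Calling and evaluation

The somatic caller is a transparent binomial tumor-versus-normal test: a
site is called iff tumor depth ≥ 10, alternate count ≥ 3, the binomial
upper tail P(X ≥ alt | depth, e/3) < 10⁻³ with per-base error rate e = 0.01
(a third of it per specific alternate allele), and the matched normal's
alternate fraction is ≤ 0.03. No multiple-testing correction is applied —
evaluation is against a known truth set, so calibration is absorbed into
precision and recall. The parameters are package defaults chosen so that
uncontaminated 60× calling of VAF ≥ 0.2 mutations is essentially perfect;
production LOD machinery is deliberately out of scope. The alternate allele
at a site is the most frequent non-reference base, ties broken in ACGT
order (deterministic, and immaterial at any realistic depth).

Evaluation matches calls to truth on the exact (contig, position, alternate)
triple; position-only matches are false positives. True positives and false
negatives are binned by truth VAF, false positives by observed alternate
fraction; bins default to (0,0.1], (0.1,0.2], (0.2,0.33], (0.33,1].
Precision is tp/(tp+fp) with 1 for an empty, miss-free call set (0 when
calls exist but fn>0 with none true); recall is tp/(tp+fn) with 1 on empty
truth; F1 is 0 when both are 0.

## Seeds

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; there is no global-state coupling, and each stage is
bit-reproducible. Multi-stream stages (dilution replicates, per-λ sweeps)
derive child seeds as `(48271·seed + index) mod (2³¹−1)` — one MINSTD step —
so any single replicate or λ can be re-run in isolation.

# Problem sizes and what the tests do (and do not) show

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical assertions have power: 10–50 kb
genomes for alignment properties, a 500 kb genome for the 30× hybrid
coverage measurement, 100-replicate dilution series, and ten-seed sweeps of
four λ levels on 15 kb genomes for the directional recall result. Larger
genomes change none of the mechanisms, only the constants' precision.

The generator emulates: homologous two-species sequence at a fixed i.i.d.
divergence, length-shifted orthologous amplicons, area-proportional traces
with additive noise, uniform coverage, and binomial VAFs. It does not
emulate: repeat structure or low-complexity sequence (so ambiguity rates
here are lower than on real genomes), PCR stutter and dye pull-up, indel
divergence outside ssPAL loci, base-quality structure, GC-coverage bias, or
capture-bait behavior. Consequently the passing tests demonstrate the
*mechanisms* — area-ratio calibration, strict-threshold flagging, depth
loss ∝ (1−λ) and its preferential destruction of low-VAF recall — not
performance figures transferable to any particular real genome region.

# Known limitations

* Ungapped alignment only; indel-bearing reads would go unmapped.
* No SAM/BAM, STR analysis, copy-number, or indel calling.
* The trace model's noise is additive and Gaussian; instrument-specific
  artifacts would need their own model before quantitative claims about a
  particular machine.
* The >95% origin rule is a screen, not a verdict: its output is
  "suspect, confirm by STR".
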