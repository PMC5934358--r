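---
title: "Models and methods behind snoproc5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snoproc5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`snoproc5` analyses Rnt1-dependent 5′ end processing of independently
transcribed yeast snoRNA and its coupling to 3′ end maturation and rRNA
2′-O-methylation. This vignette explains the models each stage implements,
the parameters that matter and why their defaults were chosen, what the
synthetic-data generator does and does not emulate, and the numerical
conventions used in edge cases.

## Coordinates and strand handling

All intervals are 0-based half-open, the native convention of BED and
bedGraph; GFF-style 1-based input would be converted once at the boundary.
Stored tracks stay genome-oriented; every per-gene computation is done in
*transcript orientation* — `tx_values()` and `transcript_seq()`
reverse(-complement) at extraction time — so "upstream", "downstream" and
metagene offsets have a single meaning regardless of strand. On the minus
strand a gene's `tss` field is the half-open upper bound of the transcript
(the TSS base is `tss - 1`), mirroring the plus-strand contract.

## Hairpin model and cleavage-site prediction

An Rnt1 cleavage structure is modelled as a 4-nt loop matching the AGNN
consensus on top of a double-stranded stem. The scanner enumerates every
consensus-matching loop and extends the stem pair by pair outward from the
loop. Conventions:

* the closing pair (adjacent to the loop) and the outermost pair must
  pair; up to `max_mismatch` (default 0) interior positions may be
  unpaired;
* G·T counts as paired when `allow_wobble` is on (default), reflecting
  rG·U wobble pairing in the RNA;
* the reported stem is maximal for its loop; `N` never appears inside a
  reported span (structure is not called over ambiguity);
* `min_stem` defaults to 10 bp and `max_stem` to 25 bp. The stem-length
  floor is a precision choice: short extensions (tens of nt) would
  otherwise produce spurious weak stems. Both are exposed in
  `hairpin_params()`, as is the loop consensus (an "NGNN" mode is one
  argument away).

The scanner is deliberately combinatorial, not thermodynamic: Rnt1
recognition is structure-based and the tetraloop/stem geometry is the
discriminating feature, so free-energy minimization would add a model
without adding the signal that matters here. The test suite checks the
scanner against an exhaustive brute-force enumerator on random sequences.

`predict_rcs()` scans the 5′ extension plus a 5-nt overhang into the
mature sequence (so hairpins straddling the boundary are not lost) and
reports, per hairpin, candidate cleavage positions at `d_point` (default
14 nt, the centre of the expected 12–18 nt band) from *both* loop
boundaries — one candidate per arm — because which arm yields the
nascent-3′-end-visible cut is not fixed a priori. Distances are measured
in transcript nucleotides from the nearest loop boundary, which is also
the anchor (offset 0) of the loop-anchored metagene axis.

## NET-seq co-localization

For each predicted structure the sense-strand NET-seq 3′-end counts are
searched in a window of ±25 nt around the loop (which also covers both
stem arms at the stem lengths considered). The window maximum is compared
with a per-gene background: the median count over the transcribed region
excluding the window. A structure is "supported" when

* the window maximum is at least `min_peak` reads, and
* the peak is at least `min_enrichment` (default 5) times the background
  (with a pseudocount floor of 0.5 on the denominator).

`min_peak` defaults to 10. The choice is driven by the null
distribution: with a Poisson background of rate about 1 read per base, a
54-position window exceeds 4 reads somewhere about one time in five, so a
threshold of 5 would produce decoy false-positive rates near 20%, while
P(Poisson(1) ≥ 10) ≈ 1e-7 makes false support essentially impossible
without costing sensitivity against real cleavage pileups that are an
order of magnitude above background. Both thresholds are parameters, and
the synthetic decoy-window false-positive rate is the tool for re-tuning
them on other backgrounds.

Antisense signal is computed alongside sense signal in the loop-anchored
metagene but never mixed into it. Metagene rows are library-normalized
(counts per million) before averaging; windows truncated by a chromosome
end are zero-padded (with a warning in the single-window API).

## 3′-end metagene, normalization and classification

The 3′ analysis anchors at the mature 3′ end: offset 0 is the last coding
base, positive offsets are downstream. Because a deletion strain's library
depth differs from WT, mutant rows are rescaled by a **normalization
factor** computed from the data: mean WT coverage over the last 6 coding
nucleotides divided by the mean mutant coverage over the same window,
averaged across the cohort after removing excluded genes. Outlier genes
(for example H/ACA genes with very high expression) can be excluded by id;
exclusion happens before both the factor and the averages. A zero mutant
reference signal makes the factor undefined and is an error, not a
silent fallback. Applying the factor and re-deriving it yields 1 (the
idempotence property in the test suite).

A gene is classified 3′-extended in the mutant when the normalized mutant
coverage averaged over the `L = 15` nt past the mature end is

* at least `floor = 0.1` of the WT coding-body signal (last 6 nt), and
* at least `ratio_min = 3` times the WT signal over the same extension
  window (pseudocount 0.5 in the denominator).

`L` is 15 nt because observed unprocessed extensions reach about 10 nt
plus margin. The body floor is 0.1 rather than a higher value because the
shortest real extensions (2 nt) contribute only 2/15 ≈ 0.13 of body-level
coverage when averaged over the fixed window; a floor of 0.2 would define
the shortest extensions out of existence. The ratio test carries the
specificity burden (an extension present equally in both conditions is
never called), and the floor only guards against calling noise over empty
windows. Pseudocounts of 0.5 are used in every ratio denominator to avoid
division by zero with minimal bias.

`detect_five_prime_extension()` uses the same logic upstream: per-base
mutant/WT ratio after library-size scaling, requiring ratio ≥ 3 over at
least 10 contiguous nt, and reports the longest qualifying run as the
estimated extension length.

## CR-RT-PCR junction calling

A circularized clone read is a rotation of one molecule
`T[s, e) + A^t`: genome-templated transcript sequence plus a
non-templated oligo(A) tail. Two identifiability issues require explicit
conventions:

1. **Extension/tail boundary.** An A at the junction that matches the
   genome cannot be distinguished from a tail A; it is counted as
   *templated* (maximal-templated-first), matching how such clones can be
   read at the bench.
2. **Rotation ties.** A tail-free molecule whose flanking bases coincide
   (`T[s-1] == T[e-1]`) has several decompositions describing the same
   circle. `canonicalize_junction()` resolves both issues in one place:
   absorb tail A's into the template (3′ side first), then, among
   fully-templated rotation ties, pick the 5′ terminus closest to the
   annotated mature start. The generator stores ground truth in the same
   canonical form, so "exact recovery" is well defined.

The search itself anchors `min_anchor = 12` nt seeds of the mature
sequence (at three offsets, so one sequencing error cannot lose the
clone) inside the doubled read, then evaluates every candidate 5′
terminus upstream of the mature start with one tolerant pass over the
whole molecule. The tolerant matcher returns the prefix maximizing
`matched bases − 4 × substitutions`: a substitution hypothesis is only
accepted when it buys more than 4 further matched bases, which prevents
crossing the ligation junction on substitution evidence alone. An exact
(zero-substitution) parse is always attempted first; the tolerant pass
only rescues reads the exact pass cannot place. Reads with no adequate
anchor, or whose non-A remainder exceeds a small error budget, are
reported `unmappable`; two distinct maximal decompositions are reported
`ambiguous` — never force-called. There is no indel handling: the clones
this models are Sanger-sequenced plasmid inserts where substitutions
dominate, and the robustness target (junction within 1 nt at a 1%
substitution rate) is met without an alignment engine.

## RTLN-qP methylation scoring

Reverse transcription at low dNTP concentration stalls at 2′-O-methylated
positions. Per region and condition, `delta_ct = Ct(low) − Ct(high)`
(replicates aggregated by mean; a median option exists), the delta of the
unmethylated reference region is subtracted to give `ddct`, and
`fold_block = 2^ddct` under the standard perfect-doubling assumption.
Replicate scatter is reported both as the SD of per-replicate paired
deltas and as the standard error of `delta_ct`; parameter-recovery checks
in the test suite use a three-standard-error band on that reported SE,
the usual calibration test for a mean estimator. Two conditions are
compared by `2^(ddct_A − ddct_B)`; how to aggregate per-region folds into
one number is left to the user, since different aggregations answer
different questions. All scores are invariant under a global Ct shift.

## What the synthetic generator emulates — and what it does not

`sim_config()` defines the study conditions: category counts (12
extension-bearing box C/D, 4 cap-retaining box C/D, 15 capped H/ACA, 6
extension-bearing H/ACA, 2 two-unit box C/D polycistrons) echoing the
genomic census of independently transcribed yeast snoRNA; 5′ extensions
of 30–120 nt each carrying exactly one planted AGNN hairpin (stems 12–16
bp, up to two wobbles) with the cleavage point 14 nt upstream of the
loop; NET-seq pileups of 50 reads over a Poisson(1) background; WT
coverage of 800× over mature spans (snoRNA are among the most abundant
Pol II transcripts, and at this depth the Poisson standard error of the
normalization-factor estimate is well under 1%); a mutant library scaled
by 1/1.73 whose precursors run from the TSS through a planted 2–10 nt 3′
extension on Rnt1-dependent box C/D units only; clone cohorts
(5′-extended + oligo(A) mutant clones, mature WT clones, and a
precursor-focused WT cohort with extensions from 2 nt up to the
terminator); and Ct tables with planted low-dNTP blockages (about 2, 2
and 6.8 cycles in WT; 0.36, 0.36 and 1.7 in the mutant; reference region
0) under Gaussian noise of 0.15 cycles, three replicates by default.

Planted extensions are rejection-sampled so they contain no hairpin other
than the planted one at default scanner settings; accidental hairpins
elsewhere in the genome are left in place as specificity decoys. In a
polycistron the proximal unit's "3′ extension window" is the covered
inter-unit spacer of the uncleaved precursor, so both units are marked
Rnt1-dependent at the 3′ end in the ground truth.

What passing on this cohort shows: the scanner, the co-localization
logic, the normalization arithmetic, the classifier thresholds and the
junction caller recover planted truth through the same file formats and
code paths real data would take. What it does not show: robustness to
mappability artifacts, non-uniform coverage along transcripts, RT/PCR
sequence biases, overlapping transcription, or annotation error — real
genomes are not uniform random sequence, and real backgrounds are not
exactly Poisson (an overdispersion knob exists, default off). Real-data
thresholds should be re-examined with the decoy and ROC machinery rather
than assumed.

## Determinism and problem sizes

Every generator output is a pure function of the configuration seed
(sub-generators derive fixed offsets from it), and the workflow writers
produce byte-identical TSV/JSON on reruns — reproducibility is a tested
property, not an aspiration. The test suite and the acceptance script use
cohorts of roughly 30–50 genes, 1000 random sequences for the
scanner-versus-enumerator comparison, 75 clones per error-rate cohort and
200 qPCR replicates for the recovery check — sizes chosen so the whole
suite runs in well under a minute per module while keeping the binomial
uncertainty of every rate estimate a few percent or less.

## Known limitations

* The hairpin model ignores thermodynamics and multi-branch structures;
  a hairpin with a large interior loop or bulge larger than the mismatch
  budget is invisible.
* The co-localization background assumes the gene body is a fair null;
  genes with strong internal pausing would need the thresholds revisited.
* The clone parser handles substitutions but not indels.
* RPKM is provided for per-gene quantification but the metagene logic
  deliberately works on raw per-base counts plus explicit normalization,
  so the two normalizations should not be mixed.
* The polycistron model is two units per TU; deeper clusters would need
  the generator (not the callers) extended.
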