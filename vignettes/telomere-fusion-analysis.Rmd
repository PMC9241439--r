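---
title: "Telomere fusion analysis during telomere-driven crisis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomere fusion analysis during telomere-driven crisis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telofuseq)
```

## The biological problem

When telomeres erode below a protective length — or are cut by a targeted
nuclease — the exposed chromosome ends become substrates for end-joining
repair. The resulting telomere fusions drive breakage–fusion–bridge cycles
and the genome instability of telomere-driven crisis. Fusion-amplicon
sequencing captures these events by PCR between subtelomere-specific
primers: each sequenced amplicon spans a fusion junction between two
chromosome ends (or between one end and a distant genomic locus).

Three fusion classes are distinguished:

* **intra-chromosomal** — between sister chromatids of one chromosome end;
  the fused molecule is a fold-back palindrome;
* **inter-chromosomal** — between distinct chromosome ends;
* **genomic** — between a telomere and a distant locus anywhere in the
  genome.

The chemistry of each junction carries a repair signature: **microhomology
(MH)** — bases shared by both partners across the junction, the hallmark of
polymerase-theta-mediated end joining; **insertions (INS)** — junction bases
belonging to neither flank, called *locally templated* when they occur near
either breakpoint (iterative strand-switching synthesis); and **blunt**
junctions, typical of classical non-homologous end joining. Each resolved
junction is exactly one of the three.

This package implements the complete desk-scale analysis chain: a seeded
synthetic-data generator that emulates the assay, a junction caller, the
comparative statistics (fusion frequencies, junction chemistry, enrichment
against a simulated uniform null), whole-genome instability summaries
(copy-number background subtraction, unique segments, SV/fusion proximity,
VAF clonality), and satellite/rDNA content from normalized read depth.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every downstream guarantee is validated.

**Subtelomere panel.** Panel members are grouped into families; the default
panel carries a unique end (17p), a second unique end (XpYp) and one
homologous family (16p/21q), mirroring the chromosome ends that
fusion-amplicon assays target. Family members share their telomere-proximal
2 kb up to a per-member divergence of 3% per base (pairwise identity ≈ 94%),
while the centromere-proximal remainder is member-specific. This reproduces
the central analytical nuisance of the assay: homology between family
members precludes definitive discrimination of sister-chromatid fusions.
Sequences run centromere → telomere; the telomere origin (default 5 kb) is
the coordinate from which chromatid deletions are measured.

**Realizing junction chemistry on fixed references.** A simulator that
pastes an arbitrary microhomology into an amplicon would contradict the
reference sequence it claims the junction came from. Instead, the generator
*selects* partner breakpoints whose sequence-determined junction
microhomology equals the requested length: for arm-A breakpoint `p` it scans
candidate arm-B boundaries and keeps those where the backward plus forward
exact-match runs sum to the target. Requested lengths follow a truncated
geometric distribution whose parameter is solved numerically so the
truncated mean equals the configured mean exactly (default 4 bp, support
1–10 bp; exact joint matches much beyond 10 bp are combinatorially absent
from a few hundred kilobases of fixed sequence, so longer requests would be
unrealizable). Blunt junctions require zero-length runs on both sides.
Insertions are drawn either as copies from within the 50 bp template window
around either breakpoint (either strand) or as random sequence rejected
until absent from both windows, and are always rejected if their terminal
bases would extend either arm. The insertion length support is 6–12 bp: a
random trimer occurs by chance in essentially any 100 bp window, which would
make untemplated ground truth unrealizable under the occurrence-based
definition of local templating. Templated status and length are fixed per
event *before* any rejection so differential rejection rates cannot bias the
templated fraction.

**Ground-truth convention.** When a junction has microhomology its placement
is inherently ambiguous over the shared bases. Both the simulator and the
caller adopt the same leftmost convention — the shared bases are assigned to
the second arm — so "exact recovery" is a well-defined comparison.

**Reads.** Each amplicon joins up to 250 bp of retained sequence on each
side of the junction (the intra class reverse-complements arm B, producing
the fold-back palindrome). Read 1 of each pair is placed uniformly among the
positions that leave at least 50 bases on each side of the junction; read 2
is the reverse complement of the far end of a 300 bp fragment. The error
model is uniform substitution only (default 0); a substituted base always
differs from the original, so the realized mismatch rate equals the
configured rate. Events whose amplicon cannot accommodate the read length
are recorded as skips, never silently dropped. All generators draw from
named streams derived from a single root seed, so adding a generator never
perturbs the others, and every output is byte-reproducible.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: PCR bias, chimeric amplicons and duplicates,
quality-score error profiles, indel errors, the true repeat structure of
subtelomeres and satellites (fixtures are i.i.d. random sequence plus
controlled homology), diploid genotypes beyond binomial VAF sampling, and
real segmental duplication. Real-data alignment, SV and CNV calling are out
of scope; segment and SV tables are consumed, not produced.

## The junction caller

The caller is seed-and-extend with *exact-run* arms:

1. every k-mer (default k = 15) of the panel and toy genome is indexed on
   both strands, repeats retained;
2. read k-mers (stride 3) vote for (reference, strand, diagonal) candidates;
3. each candidate is grown outward from its seed into the maximal run of
   exactly matching bases. An exact run ends precisely at the first
   mismatch, so the overlap of the two chosen arms on the read *is* the
   junction microhomology — identical to a brute-force scan over junction
   placements, with no scoring heuristics to overshoot it.

The best-scoring candidate becomes arm 1; arm 2 is the best candidate that
overlaps arm 1 by at most `max_mh` (default 25 bp — a generous ceiling given
junction MH means of a few bp) while contributing at least `min_arm`
(default 30) new matched bases. A gap between the arms is the insertion;
templating is tested by exact occurrence (either strand) within the 50 bp
windows flanking both breakpoints. Classification follows the panel: same
member or same family → intra (the family case is flagged), different
families → inter, exactly one panel arm → genomic. Chromatid deletion is the
distance from the telomere origin to the breakpoint in kb; it is undefined
for genomic arms.

**Family ambiguity is flagged, never resolved.** An arm with a same-family
alternative within 4 matched bases of the chosen candidate is flagged
`family_ambiguous`: discrimination then rests on at most a couple of
divergent sites, and a single site can be defeated by one chance matching
base across the junction. The margin of 4 bounds the length by which a
homolog can beat the true member through chance junction-side extension
(each extra base costs a factor of 4 in probability). Reads are never
discarded for family ambiguity; ties are broken by reference name order and
the flag travels with the call.

N bases break seeds and never match during extension. Read 1 is attempted
first; the reverse complement of read 2 is the fallback. Failures are
logged with reasons (`no-seed`, `single-arm`, `ambiguous`) rather than
silently dropped. With substitution errors, arms shorten to the error-free
run around the seed; the caller targets the near-error-free amplicon
consensus regime and makes no attempt at gapped alignment.

## Statistical conventions

* **Fusion frequency** is amplicons per diploid genome equivalent:
  `count / (ng × 1000 / 6.6)`; 6.6 pg is the standard mass of one diploid
  human genome and is configurable.
* **Fisher's exact test** (2×2, two-sided) sums hypergeometric
  probabilities of all tables, at fixed margins, no more probable than the
  observed one (relative tolerance 1e-7). Zero margins are degenerate:
  p = 1 with a warning.
* **Chi-squared with Yates' correction** replaces Fisher when one group is
  a large simulated set; the statistic is clamped at zero when the
  correction exceeds the deviation.
* **Mann–Whitney U** is exact by enumeration of all group assignments for
  combined n ≤ 20 (midranks handle ties); beyond that, a normal
  approximation with tie and continuity corrections.
* **Wilcoxon signed-rank** drops zero differences (reported), is exact over
  all sign patterns for n ≤ 15, and otherwise uses the tie-corrected normal
  approximation. Two-sided p is `min(1, 2 × min(lower tail, upper tail))`
  throughout.
* **Chromosome enrichment** reads "per-chromosome exact tests against
  size-normalized expectation" operationally as a central two-sided exact
  binomial test of each chromosome's count against its length share; the
  two-sided p sums outcome probabilities ≤ that of the observed count,
  mirroring the Fisher convention. Exact binomial tests are discrete and
  mildly conservative (the achieved size at n = 200, p = 0.2 is 0.0415 at
  nominal 0.05); the calibration check therefore estimates the type-I error
  of one designated chromosome's test across 1,000 independent simulations,
  where that conservatism sits well inside the 99% band. Holm-adjusted
  p-values are reported alongside raw ones; raw values drive comparisons.
* **Growth divergence** is the control-minus-clone difference of OLS slopes
  of population doublings over days; groups are compared with Welch's
  unequal-variance t-test.
* 95% CIs are t-based for means; proportions use exact binomial bounds.

## Genome-instability analyses

Copy-number profiles are differenced bin-by-bin (background subtraction of
parental from crisis samples); grids must match exactly — there is no
silent re-binning. Segments are maximal same-sign runs of at least 10 bins
at |log2| ≥ 0.3. A segment is *cohort-unique* iff no other sample has a
same-direction segment with reciprocal overlap ≥ 0.5 — the conventional
CNV-matching cutoff, since no operational definition of uniqueness is
standard; direction-awareness keeps a gain and a loss over the same
interval both unique. SV/fusion proximity reports,
for increasing distance bins (default 0.1, 1, 5, 10 Mb), the fraction of
genomic fusion junctions whose nearest unique SV breakpoint on the same
chromosome lies within the bin; translocations contribute both breakpoints,
and other chromosomes are infinitely far. Clonality: a clone is polyclonal
when its median unique-variant VAF falls below 0.4 — "a considerable shift
below" the heterozygous expectation of 0.5. No cutoff is stated at source;
0.4 sits three binomial standard deviations below 0.5 at depth 100 while
remaining far above the 0.25 expectation of a 50/50 two-subclone mixture,
and it is exposed as configuration and reported with every verdict. Verdicts
need at least 20 variants; fewer is indeterminate.

## Satellite read depth

Region depth is the coverage-weighted mean over the region (absent bases
count zero). Normalization offers two denominators: the unweighted mean
over the mini-reference regions (default; idempotent, normalized values
average exactly 1) and an externally supplied genome-wide mean depth. The
choice matters: with self-normalization, classes that are genuinely
expanded contaminate the denominator and every log2 ratio shifts by
−log2(sample mean). With three altered classes among thirteen at 1.5×,
1.5× and 0.7×, that shift is −log2(13.7/13) ≈ −0.076 — large enough to
displace neutral classes from zero. The recovery validation therefore uses
the genome-wide denominator, which is immune to the expansions under test;
the default remains the mini-reference mean for fidelity to depth-tool
practice on a satellite-only reference. Regions with zero wild-type depth
are excluded from ratios (counted, warned), never clamped. Per-class
summaries are unweighted means of region ratios, so swapping samples
negates every value. Class-wise comparisons use the Wilcoxon matched-pairs
test on paired normalized depths, indeterminate below 5 shared regions.

## Validation problem sizes

The test suite and the acceptance script validate on: 2,000 events at the
junction-chemistry mixture (MH 60% at mean 4 bp, INS 25% with templated
fraction 0.7, blunt 15%); 500 error-free events per fusion class for exact
ground-truth recovery; 10,000 read pairs for the error-rate calibration;
1,000 uniform-null simulations of 200 junctions for enrichment calibration;
200 replicate clonality simulations at depth 100 with 500 variants; and 200
regions per satellite class at dispersion 0.05. These sizes give the
binomial/CLT bands quoted in the tests while keeping the whole validation
run in a few minutes on one CPU.

## Known limitations

Ungapped arms only: junctions whose flanks contain indels relative to the
reference will not resolve. The caller assumes amplicon-style reads that
span the junction; it is not a general-purpose split-read SV caller. The
uniform null for feature coincidence ignores mappability and GC. Family
ambiguity flags are conservative by construction and may mark calls that a
longer read would have resolved. The satellite module quantifies relative
content only; it does not model mappability within repeat arrays, where
real short-read depth is systematically distorted.
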