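---
title: "Forensic mitogenome haplotyping from read evidence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic mitogenome haplotyping from read evidence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohap)
```

## Scope

`mitohap` implements the analysis chain used to turn whole-genome
sequencing (WGS) read evidence over the human mitochondrial genome into
forensic-quality haplotypes and population statistics: threshold-based
variant calling with heteroplasmy and NUMT handling, EMPOP-style
rCRS-relative notation, literal/pattern haplotype matching over the
standard forensic ranges, random match probability and haplotype
diversity, maternal-relative deduplication, haplogroup assignment against
a variant-annotated tree, and a seeded simulator that generates the kind
of data the caller is meant to handle. Upstream read alignment and
database services (EMPOP submission, LISA) are out of scope; the package
starts from per-position pileup tables.

## The calling model

A pileup row carries the read depth and the A/C/G/T, deletion and
insertion-event counts at one reference position. Calling applies, per
position:

* **Minimum variant frequency (`min_vf`, default 0.10).** An allele is
  called only when its read fraction reaches 10%. This single threshold is
  the NUMT defence: nuclear mtDNA segment reads co-align at low fractions
  (typically below 10% of the mtDNA-aligned reads), so they are excluded
  wholesale without read-level deconvolution.
* **Point heteroplasmy (PHP).** Exactly two bases at or above the
  threshold yield the two-base IUPAC code (`Y` for C/T, `R` for A/G, ...)
  and the minor fraction is recorded. Three or more alleles above the
  threshold are not representable as a single-source state: the major
  base is reported and the position counts toward the mixture flag.
* **Depth thresholds.** Positions below `min_depth` (100X) count toward
  the coverage class; positions below `fallback_min_depth` (20X) are not
  genotyped at all and are reported as uncovered. The class boundaries
  follow the published convention: 0 low positions is *complete*, 1–4
  *nearly complete*, 5 or more *incomplete*. Re-analysis of low-coverage
  samples at a 20X minimum is expressed by lowering `min_depth`.
* **Homopolymer regions.** In the configured C-stretches (HVS1/HVS2/HVS3,
  the AC repeat at 513–524, and the short C-stretches preceding 356, 460,
  498, 960, 5899, 7471 and 8276) insertion and deletion evidence is
  summarized into *length molecules*; the haplotype reports only the major
  length molecule, and a region with two or more molecules at or above
  `min_vf` is flagged as length heteroplasmy (LHP). Low-level mixed base
  calls at the polyA artifact positions 302, 16,182 and 16,183 are
  suppressed to the major nucleotide, since post-homopolymer sequencing
  errors make PHPs there unreportable.
* **NUMT hotspots.** Calls inside the known hotspot blocks
  (nps 12,501–13,105 and np 16,496) are annotated in `numt_flags`, and
  hotspot alleles between the noise floor (2%) and the calling threshold
  set `sub_threshold_numt_signal`. Flagging, not removal, is deliberate:
  the threshold itself is the mitigation, and a flagged call preserves the
  evidence for review.

The QC metric `avg_vf` is the mean major-nucleotide frequency across the
haplotype's variant positions (not all 16,569 positions); computed without
PHP positions and LHP regions it is expected above 98% in single-source
data, and the mixture flag combines that floor with a cap (more than 3
multi-allelic non-hotspot positions) reflecting the maximum PHP count seen
in single-source mitogenomes.

## Notation and matching

Haplotypes are ordered rCRS-relative variant sets: `263G` (substitution),
`315.1C` (insertion; `309.xC` preserves a wildcard insertion index),
`8281DEL` (deletion; `8281-` accepted on input). Matching over a range
(HVS = 16,024–16,365 plus 73–340; CR = 16,024–16,569 plus 1–576; or the
full mitogenome) drops indels by default and compares substitution maps,
filling the reference base at positions where only one sample varies.
*Literal* matching is symbol equality; *pattern* matching succeeds when
IUPAC expansions intersect, so `152Y` pattern-matches `152C`, `152T` and
the rCRS state `152T`. `N` is treated as missing data and never decides a
comparison.

Literal matching is transitive and classes are exact key groups. Pattern
matching is not transitive (`Y` matches both `C` and `T`, which do not
match each other), so pattern classes are built by a deterministic greedy
merge in input order with complete linkage: a haplotype joins the first
class *all* of whose members it matches. This was a genuinely open design
point; complete linkage was chosen because it keeps every reported class
internally consistent (all pairs match) and makes the greedy order the
only source of path dependence. Pattern-mode class counts can therefore
never exceed literal-mode counts.

## Forensic statistics

For a frequency spectrum with class sizes $n_i$ over $n$ samples,
$\hat p_i = n_i/n$:

* observed RMP $= \sum_i \hat p_i^2$ (random pair, with replacement);
* empirical RMP $= \sum_i n_i(n_i-1) / (n(n-1))$ (distinct pairs);
* haplotype diversity $= \frac{n}{n-1}(1 - \sum_i \hat p_i^2)$.

The two RMP variants are not interchangeable: the observed form includes
self-pairs and upper-bounds the empirical form. Both definitions were
fixed by requiring exact agreement with the published diversity table at
the printed precision, and the spectrum-based formulas are verified in the
tests against brute-force enumeration of all sample pairs. Reporting
precision follows the published convention: RMP percentages to two
decimals, diversity to four, proportions to one (round-half-even).

Shared-haplotype grouping for maternal-relative screening ignores indels
*and* drops heteroplasmic (ambiguous) positions entirely, rather than
pattern-matching them; within a shared group, related samples (from an
externally supplied kinship table) are reduced to one, keeping the lowest
sample id so removal is reproducible. Haplogroup-distribution comparisons
use the chi-squared statistic with Yates's continuity correction
$\sum (|O-E|-0.5)^2/E$ (correction capped at $|O-E|$), which matches the
standard 2x2 implementation to machine precision and is applied uniformly
to larger tables.

## The synthetic reference

The package does not ship the rCRS sequence. `synthetic_reference()`
builds a deterministic 16,569-bp stand-in: an arbitrary base fill overlaid
with the documented rCRS states at every position the package's examples,
fixtures and default configurations cite (for example 263A, 13105G, the
310T and 16189T stretch interruptions), and with the canonical
homopolymer structure at the C-stretch coordinates. All coordinate
arithmetic, fixtures and simulations are internally consistent against
this object; analyses of real data should load the true rCRS with
`read_reference_fasta()`.

## The simulator and what it does (not) emulate

`simulate_population()` draws one distinct haplotype per configured clade
(Poisson number of substitutions, mean 25 — matching the observed mean
variant load — with a 0.9 transition weight) and gives every sample in a
clade the same haplotype, so the realized frequency spectrum *is* the
configured clade-size vector. The default configuration reproduces the
study conditions: 934 samples with the published sharing spectrum;
per-sample mean depth log-uniform over 500–3000X with negative-binomial
per-position depth (size 100, about 10% coefficient of variation);
per-base miscall rate 0.5%, well under the 2% noise floor; PHP counts per
sample distributed 729:177:25:3 over 0–3 with minor fractions uniform in
10–50% and a 76.7% transition weight; per-region LHP probabilities set to
the published region tallies (about 73% of samples overall, as mixtures
of length molecules whose minor total stays below 50% so the major
molecule is the reference length); NUMT contamination detectable above
the noise floor in 40% of samples, with fractions up to 8%; and a 0.5
depth multiplier over homopolymer windows (0.2 reproduces severe
dropout). `inject_numt()` adds the expected contaminating read count at
hotspot positions so the NUMT allele frequency equals the contamination
fraction by construction.

Deliberate simplifications: substitution positions are uniform outside
the homopolymer windows, so variation is not concentrated in the
hypervariable segments the way real control-region data is — simulated
HVS-range statistics are therefore flatter than published ones, and only
the full-range spectrum is meaningful quantitatively. Population
structure is a labeled-clade model, not a coalescent; no read-level
artifacts (strand bias, mapping quality) are modeled; LHP mixtures use a
single inserted base. Passing parameter-recovery tests on these data
shows the thresholds and reporting rules are implemented correctly, not
that the caller is robust to artifacts the simulator does not produce.

## Numerical and edge-case choices

Zero-depth or sub-fallback positions are uncovered: no calls, reported as
gaps. Frequencies are compared with `>=` against thresholds, so a minor
fraction exactly at 10% is called (the threshold-sharpness tests pin this
boundary). Ties for the major base resolve to the first base in A/C/G/T
order; ties in haplogroup scores resolve to the shallower node, then
lexicographically, and are reported. The haplogroup score is matches
minus 0.5 per expected-but-absent variant with private variants
unpenalized — deliberately simple; back-mutation tokens (`263A!`) denote
the stated base, which is how the reference-identical haplotype scores
into H2a2a1 on the packaged 25-node synthetic tree rather than the root.
The doubleton/tripleton reconstruction solves a 2x2 linear system and
refuses non-integer or negative solutions.

## Problem sizes used in validation

The shipped tests run the full chain at reduced scale chosen to keep the
suite fast while still exercising every rule: parameter recovery on 200
simulated samples at 1000–3000X (PHP fractions at least 12%, NUMT at most
8%), NUMT threshold behaviour on 100 contaminated samples, all-pairs
oracle comparisons on populations of up to 934 (key-based) and 100
(full pairwise-matching) samples, and property checks with fixed seeds
throughout. The acceptance script regenerates the 934-sample spectrum
population from scratch on every run.

## Known limitations

Pattern-mode class counts depend on input order (documented,
deterministic); the package does not emulate EMPOP query semantics or
alignment-based notation disambiguation beyond the stated rules; the
haplogroup fixture tree is synthetic and tiny compared to Phylotree, so
haplogroup *frequencies* are never a validation target; and HVS/CR-range
statistics on simulated data underrepresent real hypervariable-segment
diversity, as noted above.
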