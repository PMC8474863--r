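---
title: "Noninvasive fetal RHD genotyping from amplicon reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive fetal RHD genotyping from amplicon reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay

RhD-negative pregnant women can be sensitized by an RhD-positive fetus, the
main cause of hemolytic disease of the fetus and newborn. Anti-D prophylaxis
is unnecessary when the fetus is RhD-negative, so noninvasive fetal *RHD*
genotyping from cell-free DNA (cfDNA) in maternal plasma is clinically
valuable. In East Asian populations the common European strategy — test for
presence of any *RHD* sequence — fails, because *RHD*-positive but D
antigen-negative alleles (the c.1227G>A D-el allele `RHD*01EL.01` and the
RHD-CE hybrid `RHD*01N.04`) are frequent among RhD-negative individuals. The
assay `rhdamp` models therefore distinguishes the wild-type allele `RHD*01`
from all three common RhD-negative alleles.

Two primer pairs co-amplify four genomic regions:

* a 105-bp amplicon matching both the *upstream* and *downstream Rhesus
  boxes*, the homologous segments flanking *RHD* whose recombination creates
  the deletion allele `RHD*01N.01` (one hybrid box, modeled as
  downstream-type); the two boxes differ at one diagnostic base
  (upstream G at chr1:25,592,628; downstream A at chr1:25,662,955);
* a 148-bp amplicon matching both *RHD* exon 9 and *RHCE* exon 9, differing
  at two paralog-diagnostic bases (amplicon offsets 23 and 119) plus the
  c.1227 position (offset 57), where *RHD* wild type carries G, the D-el
  variant A, and *RHCE* C (chr1:25,648,453 / 25,696,958).

Because each read is a full-length amplicon, the base observed at these
offsets assigns it to its genomic source, and the five diagnostic counts
(upstream box, downstream box, RHD wild type, RHD c.1227G>A, RHCE) carry all
of the assay's information.

## The mixture model

Each allele contributes a fixed unit vector of amplifiable copies per allele
copy:

| allele | up box | down box | RHD wt | RHD var | RHCE |
|---|---|---|---|---|---|
| `RHD*01` | 1 | 1 | 1 | 0 | 1 |
| `RHD*01N.01` | 0 | 1 | 0 | 0 | 1 |
| `RHD*01EL.01` | 1 | 1 | 0 | 1 | 1 |
| `RHD*01N.04` | 1 | 1 | 0 | 0 | 2 |

A maternal/fetal mixture with genome-equivalent weights $(1-f, f)$ has
expected class fractions proportional to the weighted sum of the two
genotypes' unit vectors, normalized within each co-amplified group
(`expected_ratios()`). For a del/del mother the upstream-box fraction $u$
among box reads is a strictly increasing function of the fetal fraction $f$;
for an `RHD*01`/del fetus it inverts in closed form as $f = 2u/(1-u)$
(`fetal_fraction_from_upstream()`). The general inversion
$f = u\,d_m / (u_f - u\,(u_f + d_f - d_m))$ covers any fetal genotype with
upstream units $u_f > 0$ and downstream units $d_f$, given maternal
downstream units $d_m$. This estimate is a proxy under an assumed fetal
genotype, not a measured fetal fraction — the assay by itself cannot
determine the fetal fraction, which is why the molecule counting below
matters.

Two modeling choices were genuinely open and are worth recording. First, the
hybrid Rhesus box of the deletion allele is modeled as a downstream-type
amplicon: cfDNA from del/del mothers shows ~98% downstream reads, which is
only consistent with the deletion allele amplifying as downstream-type —
if it did not amplify at all, a heterozygous RhD-positive fetus would drive
the upstream fraction toward 50% rather than the observed ~2%. Second,
`RHD*01N.04` keeps both boxes intact and contributes two RHCE-type exon-9
units, following the hybrid-gene structure (exons 3–9 of *RHD* replaced by
*RHCE*). The unit table ships as JSON
(`inst/extdata/allele_units.json`), so additional alleles can be added
without code changes.

## From reads to counts

The pipeline follows the amplicon structure rather than a genome aligner:

1. **Adaptor trimming.** Read-through adaptors are located by a 12-base
   seed allowing one mismatch (implemented as exact 6-mer halves by
   pigeonhole, then window verification) or by an exact terminal prefix of
   at least 3 bases. Over-trimming a few 3'-end bases is harmless: the
   overlap merge reconstructs the full amplicon from the other mate.
2. **Overlap merging.** Read 1 and the reverse complement of read 2 are
   merged at their maximal-length overlap of at least 10 bases with *zero*
   tolerated mismatches (`max_mismatch_density = 0`). This is deliberately
   strict: any sequencing error inside the overlap discards the pair, which
   is the main reason the assay's residual error ratios are so low. Merged
   qualities take the per-base maximum of the two mates. Failed merges are
   recorded as rejections, not errors.
3. **UMI extraction** (UMI protocol only). The first 12 bases of the merged
   read — read 1's 5' prefix — are moved to a UMI field *before* size
   filtering, since they are not part of the amplicon.
4. **Size filter.** Only merged lengths of exactly 105 or 148 bases
   survive, removing primer dimers and artefacts.
5. **Quality filter.** Mean Phred quality of the merged read must be at
   least 25 (boundary inclusive). The read-level mean was chosen as the
   interpretation of a "base quality cutoff 25" read filter; per-base
   masking would alter counts position-wise and is not what a read-removal
   filter does.
6. **UMI deduplication.** Reads are grouped by exact UMI within an amplicon
   length class; each group is one template molecule and contributes one
   read: the plurality sequence, ties broken by the lexicographically
   smallest (a deterministic, order-independent rule). No Hamming-distance
   UMI network correction is attempted; with ~40,000 molecules against
   4^12 ≈ 1.7e7 UMIs, collisions are rare (and the simulator records them),
   while UMI sequencing errors slightly inflate the molecule count without
   biasing class fractions.
7. **Classification.** After size filtering every read is an ungapped
   full-length amplicon, so alignment reduces to Hamming distance against
   the references of its length class. A read is assigned to the unique
   closest reference iff the distance is at most 3 *and* the second-best
   reference is strictly worse; ties (e.g. an N at the single
   discriminating base) are "ambiguous", distant reads "unassigned". The
   margin rule reproduces the intent of mapping-quality-based unique-read
   selection without a genome aligner: a bwa MAPQ cutoff distinguishes
   unique from repeat placements, which for fixed-length paralogous
   amplicons is exactly the requirement that one reference beat the other.
8. **Counting.** Per region, a position × {A,C,G,T,other} count matrix is
   accumulated (`count_bases()`, exported as a wiggle-style text track);
   diagnostic counts are read off at the declared offsets
   (`extract_diagnostics()`).

## Ratio statistics and the error ratio

`allele_ratios()` keeps exact fractions and renders display percentages the
way the assay reports them: minor fractions at two decimals (three when
below 0.005%), and the largest fraction of each group as 100 minus the
rounded minor fractions, so a reported group always totals 100%.

The per-position **error ratio** pools the two co-amplified regions of a
group: at each amplicon position, the number of reads whose base differs
from *their own region's* reference base, divided by the pooled read count.
Using each region's own base as reference makes the paralog-diagnostic
positions contribute correctly. Primer footprints (nt 1–20/81–105 for
boxes, nt 1–22/120–148 for exon 9) are excluded, as is the c.1227 site,
which legitimately varies between alleles of the same region. That leaves
60 analyzable interior positions for the boxes and 96 for exon 9 (the
97-position interior span nt 23–119 minus the variant site). Positions with
no data are reported as such and excluded from the `max`/`median`/pooled
summaries.

`summarize_run()` bundles counts, ratios, error summaries, the filter
ledger and QC flags. A diagnostic class whose fraction sits *above* the
run's own interior background maximum but *below* the positive-call
threshold is flagged as possible carry-over contamination — the signature
of a stray signal too strong to be sequencing error yet too weak to be a
fetal allele.

## Genotype calling

`call_maternal()` matches the observed (upstream, c.1227G>A) fraction
pattern by L1 distance against each candidate maternal genotype's expected
pattern at fetal fraction zero, defaulting to the three common RhD-negative
genotypes (del/del, del/hybrid, del/D-el). The RHD-wild-type fraction joins
the distance only for candidates that themselves carry `RHD*01`: for
RhD-negative candidates any wild-type signal is fetal in origin and must
not penalize the match. The tolerance default of 0.12 admits the fetal
perturbation of the maternal pattern (up to 2/23 ≈ 0.087 in the 10:1
validation mixtures) while remaining far below the ≥ 0.167 separation
between candidate patterns.

`call_fetal()` then applies the assay's asymmetric logic: detecting
`RHD*01` proves an RhD-positive fetus, while its absence leaves either a
true RhD-negative fetus or a fetal fraction too low to detect. The call is

* **RhD-positive** iff the wild-type fraction is at least
  `min_positive_frac` (default 0.5%) *and* the wild-type count is at least
  `min_positive_count` (default 50; unique molecules when UMIs were used)
  *and*, for a del/del mother, the independent upstream-box signal
  corroborates;
* **RhD-negative (del/del)** iff the wild-type fraction is at most
  `max_negative_frac` (default 0.1%) and the upstream fraction matches the
  maternal-only expectation;
* **inconclusive** otherwise, with notes explaining which band was hit.

The printed cutoffs are anchored to the assay's observed scales — interior
background error ratios peak around 0.06–0.12% while true fetal signals at
8–28 weeks run 1.3–2.1% — with `min_positive_frac` placed between them and
a count floor so that a fraction threshold cannot be satisfied by a handful
of reads at low depth. All thresholds are configuration, not code.

## The simulator

`simulate_reads()` emulates the data-generating process the pipeline
assumes, so every stage is testable without sequencing data: molecules are
drawn per group from the closed-form mixture fractions (times an optional
per-class amplification bias, mirroring the bias towards *RHCE* exon 9
observed under the linear-amplification UMI protocol); each molecule gets a
uniform random 12-base UMI and `1 + Geometric` PCR duplicates (mean 3 by
default; the true duplicate distribution after 30–35 cycles is unknown and
geometric is a pragmatic stand-in); PCR substitution errors (default 1e-4
per base per duplication) are inherited by both mates, sequencing errors
(default 1e-3 per base) hit each read independently; reads carry the
adaptor read-through structure and Phred qualities around Q35, so the
default filters pass clean reads. All randomness derives from one seed and
identical configurations give byte-identical output.

`simulate_twelve_panel()` enumerates the 3 × 4 validation design — each
RhD-negative maternal genotype against the RhD-positive heterozygote or any
of the three negatives — at a 10:1 genomic DNA ratio, modeled as fetal
fraction 1/11 since both contributors are diploid.

What the simulator does *not* emulate: fragment-size distributions,
index hopping, polymerase-specific error spectra, strand bias, or the
position-dependent quality decay of real flow cells. Passing tests
therefore demonstrate the pipeline's arithmetic and its statistical
behavior under the stated model, not performance on real instrument data.
The shipped reference panel is synthetic (random sequences satisfying all
structural invariants — lengths, primer spans, diagnostic offsets/bases,
published genomic anchors); real amplicon references can be supplied via
`load_reference_spec()`.

## Numerical and degenerate-input choices

* Ratios are computed from integer counts and divided once; group fractions
  sum to 1 to floating-point accuracy, and displayed groups total exactly
  100% by construction.
* Zero-read groups give "no data" values (`NA`), never exceptions; merge
  failures and filter rejections are data with reasons, and every stage
  ledger sums exactly.
* Classification ties break to "ambiguous" (excluded from counting) rather
  than to either paralog; an N at a diagnostic offset counts as "other",
  never toward an allele.
* The pipeline is deterministic given input order; all stochastic behavior
  lives in the simulator behind a single seed, and the simulator restores
  the caller's RNG state.
* Problem sizes in the test-suite: the twelve-combination panel runs at
  20,000 molecules per group with duplication mean 3 and sequencing error
  1e-3; calibration checks use 4,000–23,000 molecules. At these depths the
  binomial standard error of a 1/23 fraction is ~0.13 percentage points,
  small enough to separate every genotype pattern by a wide margin.

## Known limitations

* The maternal caller only ranks the supplied candidate genotypes; an
  unexpected maternal pattern (e.g. an RhD-positive mother) is reported as
  an error value, not resolved.
* The fetal call reports RhD status and the compatible allele, never a full
  two-allele fetal genotype — co-amplified counts cannot phase fetal
  alleles.
* The mixture-fraction estimate assumes a fetal genotype; a SNP-panel
  fetal-fraction method would be needed for a true measurement.
* Exact-UMI grouping slightly overcounts molecules in the presence of UMI
  sequencing errors; plurality consensus suppresses, but cannot eliminate,
  PCR errors in singleton families.
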