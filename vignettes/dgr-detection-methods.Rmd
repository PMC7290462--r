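---
title: "Detecting diversity-generating retroelements: models and methods"
author: "dgrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversity-generating retroelements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrscan)
```

## The biological model

Diversity-generating retroelements (DGRs) diversify a target protein by
error-prone retrohoming.  A cassette carries two near-identical repeats: a
**template repeat (TR)**, usually intergenic, and a **variable repeat
(VR)** at the 3' end of the target gene.  A cassette-encoded reverse
transcriptase (RT) copies an RNA transcript of the TR into cDNA with a
characteristic infidelity: positions that are **adenine in the TR** can
become any base ("A-to-N" mutagenesis), while non-adenine positions are
copied faithfully.  The cDNA overwrites the VR, so the TR is the invariant
donor and the VR accumulates substitutions exactly at TR-adenine columns.
Short elements at the 3' ends of both repeats — **IMH** (initiation of
mutagenic homing, on the VR) and **IMH\*** (on the TR) — delimit the
diversified region.  In crAss-like gut phages the documented architecture
is `TG-VR(IMH)-TR(IMH*)-RT`, with the target gene encoding a tail-collar
fiber protein, flanked upstream by a tail-needle-protein (TNP) gene and
downstream by a hypothetical protein and an integration-host-factor (IHF)
gene.

Three consequences of this model drive every algorithm in the package:

1. a true TR/VR pair is gap-free and ~70-90% identical, with mismatches
   concentrated at TR adenines;
2. the copy carrying `A` at mismatched columns is the TR — orientation is
   a statistical property of the mismatch spectrum;
3. the pair shares an exact 3' suffix (the IMH), which both guarantees a
   seed for exact-match discovery and pins the 3' boundary.

## Repeat discovery

`find_repeat_pairs()` seeds on shared exact k-mers (k = 12 by default; an
IMH of at least 10-14 nt guarantees a seed for any true cassette) and
extends each seed diagonal without gaps under an adenine-tolerant score
(match +1, mismatch involving adenine -0.3, other mismatch -3, X-drop 12).
A mismatch penalty blind to adenine would terminate extension inside the
A-to-N mismatch field and shred real repeats.  Each rough extension is then
trimmed to its maximal-scoring contiguous subsegment under the symmetric
column log-likelihood ratio described below, so that the alignment entering
orientation is not padded with unrelated flank columns.  Pairs must satisfy
length in [50, 200] nt, identity >= 0.70 and separation <= 10 kb —
brackets chosen around the known cassette geometry (105 nt, ~80% identity,
~250 nt separation) with generous margin.  Both same-strand and
reverse-strand (`inverted`) pairs are searched.

## Orientation by adenine bias

For a pair with at least one mismatch, `assign_tr_vr()` computes, for each
copy, the fraction of mismatched columns at which that copy carries `A`.
The copy at or above `bias_threshold` becomes the TR.  Because the two
fractions sum to at most 1, any threshold above 0.5 makes double
qualification impossible.  The default is 0.60 rather than a stricter
value: the expected TR-side bias is ~0.9, but with only ~15 mismatched
columns the observed bias of a genuine TR fluctuates substantially
(a pair with 11 A-to-N and 3 other mismatches has bias 0.79), while the
VR-side bias stays near (1/3) x (non-A-to-N fraction) ~ 0.1.  A 0.6
threshold separates the two populations with a wide margin in both
directions; 0.8 rejects a non-trivial fraction of real cassettes as
ambiguous.  Zero-mismatch pairs are flagged ambiguous, not errors:
orientation is undefined for identical copies.

## Boundary refinement

Discovery trimming leaves boundaries accurate to a handful of nucleotides.
`refine_boundaries()` re-estimates them under an explicit probabilistic
model.  Each aligned column falls into one of five categories — match at a
TR adenine, match elsewhere, mismatch at a TR adenine, mismatch whose VR
base is adenine, mismatch with no adenine — and is scored with the log
likelihood ratio of "homologous with A-to-N mutagenesis" (adenine fraction
0.27, per-adenine substitution probability 0.7, non-adenine substitution
0.02) versus "unrelated flanks" (independent AT-rich bases, chance match
probability 0.2725).  Under this model a mismatch at a TR adenine is
almost uninformative (LLR ~ -0.15) while a mismatch with no adenine is
strong evidence against homology (LLR ~ -3.4): this asymmetry is what
makes DGR boundaries recoverable at all, since a mutated leading adenine
does not truncate the repeat.

The cumulative LLR defines a posterior over boundary positions.  Because
the VR is part of the target gene's reading frame (cassette repeats are
counted in codons), candidate boundaries are restricted to the target-gene
codon grid whenever the VR lies inside a called ORF.  The reported 5'
boundary maximises the posterior mass of candidates within one codon
(+/- 3 nt), plus a small tie-break term (0.05 x the candidate's own
posterior atom) that resolves the near-ties inherent to overlapping
windows toward the exact boundary.  The 3' boundary does not use the
posterior at all when an IMH is present: it is set to the end of the
rightmost exact-match run of at least `imh_min_len` columns,
floor-snapped to the codon grid.  Overshooting that anchor requires six
or more consecutive chance matches in unrelated flanks (probability
~0.0004), so the 3' end is essentially exact; the 5' end is intrinsically
fuzzier, and its residual error (about 2% of simulated cassettes miss by
more than 3 nt) is close to the Bayes limit of the column model —
when the flank happens to open with chance matches interleaved with
adenine-involved mismatches, no estimator can tell it from repeat.

## IMH, RT, assembly and classification

`detect_imh()` defines IMH operationally as the maximal exactly-matching
3' suffix of the refined alignment, reported at >= 10 nt; the `identical`
flag records whether the extracted IMH and IMH* strings are equal (the
definition makes them equal unless `N` columns intervene; the flag is
recorded rather than enforced because the literature describes IMH* both
as identical and as diverged).  `detect_rt()` flags ORFs of 150-900 aa
whose translation contains the canonical RT catalytic pattern x-x-D-D
(first position Y/L/F/V/I/M), or — when a reference panel is supplied —
ORFs aligning to an RT reference at >= 40 bits (BLOSUM62 local alignment;
bit scores use the ungapped Karlin-Altschul constants as an
approximation).  The motif alone is weakly specific (~20% of random
350-aa proteins contain it), which is why cassette assembly never assigns
the target-gene ORF itself as the RT and why the cohort screen prefers
reference mode.

`assemble_cassette()` ties the elements together: the target gene is the
ORF whose 3' end contains or abuts the VR (within 50 nt of the stop), the
RT is the nearest RT-labelled ORF within 5 kb of the TR, and each cassette
is scored `identity x adenine_bias x (1 if IMH else 0.5)`.
`classify_architecture()` applies the completeness rule — `complete`
requires full-length target gene, VR, IMH, TR, IMH* and full-length RT;
`absent` means no element; everything else is `incomplete` — and writes
the architecture string 5' to 3' in genomic order, with truncated genes in
primes (`tg'-VR-rt'`).  A gene is "truncated" when its ORF is shorter than
60% of its reference protein; without a reference, any called ORF counts
as full-length.

## Mutagenesis statistics and exact diversity

`compare_vr_tr()` classifies the mismatches of a gap-free VR/TR alignment
into A-to-N (TR base adenine) and non-A-to-N; the two counts always sum to
the Hamming distance.  `diversity()` computes the theoretical sequence
space opened by retrohoming: with `A` adenines free to become any base,
`4^A` DNA sequences are reachable — computed in exact arbitrary-precision
arithmetic, since `4^28 = 72,057,594,037,927,936` already exceeds exact
double precision.  Protein diversity multiplies, over codons, the number
of distinct translation outcomes reachable by substituting that codon's
adenines; codons vary independently, so the product is exact.  Stop-codon
handling is a genuine convention choice: by default variant codons that
translate to a stop are excluded before counting, and both conventions are
always computed so either can be compared.  Orders of magnitude are
`round(log10(x))`, which renders `4^28` as the familiar "~10^17".
`diversity_bruteforce()` enumerates all `4^A` variants explicitly (capped
at 10 adenines) and is kept strictly independent of the analytic path; the
two are cross-checked on random repeats in the test suite.

`build_logo()` computes per-column amino-acid frequencies over the 20
standard residues (gaps and non-standard symbols excluded from the counts)
and information content `R = log2(20) - H` bits, without small-sample
correction by default — the convention of standard sequence-logo tools —
so an invariant column scores `log2(20) ~ 4.32` bits and a uniform column
scores 0.

## The cohort screen

`screen_cohort()` reproduces the comparative workflow: locate the TNP
anchor gene by translated local alignment of a reference protein against
all six reading frames, extract ~7.5 kb downstream (genomes without the
anchor are screened whole and flagged `unanchored` rather than dropped),
run the full detection chain in the region, and classify.  Two
reference-based fallbacks handle degraded cassettes that the repeat finder
cannot see: target-gene presence/truncation from the coverage of a
reference tail-collar-fiber protein, and VR/TR presence from nucleotide
local alignment against a reference TR (a hit overlapping the target
gene's 3' end is a VR, elsewhere a TR).  Summaries tabulate per-class
counts and integer percentages with round-half-up — the rule that maps
15/91 to 16% and 66/91 to 73%; the computed percentage for 10/91 is 11%,
and the package reports computed values only.

## The synthetic-data generator

`generate_genome_with_cassette()` emulates the statistical structure the
detector assumes: an i.i.d. AT-rich background (GC 0.35), and planted in
order TNP, target gene (486 aa, VR as its last 35 codons), intergenic TR,
RT (350 aa with the x-x-D-D motif), HP and IHF genes.  The TR has adenine
fraction 0.27 placed codon-structured (enriched at codon positions 1-2,
where A-to-N changes the protein — the observed pattern in real
cassettes); the VR substitutes each non-IMH adenine with probability 0.7
uniformly to C/G/T, each other position with probability 0.02, never
touches the 14 nt IMH suffix, and resamples any substitution that would
create an in-frame stop (the VR is translated).  Planted genes use ATG
starts, TAA stops, stop-free interiors, and an in-frame stop guard
immediately upstream so the ORF caller reports exactly the planted
interval.  Truncated-gene variants end in a premature stop so that a
planted "truncated" gene can never read through into background and
masquerade as full-length.  `generate_cohort()` shares one ancestral
template (anchors, target gene, TR) across all genomes while each genome
draws its own background, codon usage and VR substitutions — mirroring a
phage genus whose VRs are homologous but individually diversified, and
making reference-based screening and cross-genome logos meaningful.

What the generator does **not** emulate: gapped repeat alignments (real
VR/TR pairs are modelled gap-free, as in the documented cassette),
homologous repeat flanks, realistic codon usage or higher-order background
composition, sequencing or assembly error, and genome rearrangements.
Passing the planted-truth tests therefore demonstrates correctness of the
detection logic under the cassette model, not performance on arbitrary
real contigs.

`simulate_reference_cassette()` is a deterministic fixture whose planted
cassette carries, by construction, the exact headline statistics of the
deposited crAssphage cassette: 35 TR codons containing 28 adenines, 21
A-to-N plus 2 non-A-to-N substitutions in the VR, a shared exact 14 nt
IMH, a 486 aa target protein and a 98,458 bp genome.  Its TR places
adenines in pairs at codon positions 1-2 (so the exact protein diversity,
15^14 ~ 2.9e16, lands in the 10^16 regime while DNA diversity is 4^28 ~
10^17), and one non-A-to-N substitution sits immediately 5' of the IMH so
the exact-suffix definition yields exactly 14 nt.  All sequence context is
synthetic; only these printed summary statistics are modelled on the real
cassette.

## Problem sizes, determinism and limitations

All randomness flows through an internal seeded-RNG scope, so every
generator output is a pure function of its spec and every detection run is
deterministic; identical inputs produce byte-identical reports.  The test
suite and the acceptance script use 30 kb genomes for planted-recovery
batteries (50 genomes) and a 91-genome cohort at 30 kb with a 7.5 kb
screened region — sizes at which the full chain exercises every code path
while a complete run stays in the minutes range.  Known limitations:
inverted repeat pairs are discovered and flagged but not boundary-refined;
the gap-free alignment model will fragment repeat pairs containing true
indels; anchor scanning keeps one best hit per label; and protein bit
scores reuse ungapped Karlin-Altschul constants for lightly gapped
alignments.
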