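---
title: "Detecting CRISPR-induced minor variants in tiled-amplicon data: models and choices"
author: "ampedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CRISPR-induced minor variants in tiled-amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Transient CRISPR-Cas9 targeting of a replicating baculovirus genome
edits only a minority of genome copies, so the repair indels live at
1–10% frequency inside a heterogeneous pool. `ampedit` models the
detection task as four composable stages — read placement, alignment
hygiene, quality-aware calling, replicate concordance — plus two
interpretation layers: CRISPR edit-window attribution and cross-passage
conservation. This vignette records the model assumptions, the
parameters that matter, and the design decisions taken where several
choices were defensible.

## Variant representation

Indels use the anchor-base convention of mpileup-lineage callers: a
deletion `-SEQ` at position *p* deletes the `nchar(SEQ)` reference bases
*after* *p* (`REF` is the base at *p* itself), and an insertion `+SEQ`
inserts after *p*. This falls naturally out of CIGAR walking (the anchor
is the aligned base 5′ of the gap) and makes the bundled nested deletion
series at 107,199–107,204 mutually consistent with the planted
protospacer sequences; representations are made canonical by maximal 5′
shifting (`left_normalize_indels()`), so replicate intersection and
conservation matching can use exact key equality with no positional
tolerance.

## The fixture genome

`build_reference()` plants every guide's protospacer+PAM exactly once in
a 120 kb random background, anchored so that the gp64+131 estimated
indel window starts at 107,222; all antisense sites then follow the
offset arithmetic `start(+131) − start(+X) = X − 131`. The edit-window
rule is uniform — the six anchor positions for 1–5 bp deletions 3–4 bp
upstream of the PAM, i.e. protospacer positions 13–18 — and reproduces
every antisense window. The sense-strand gp64-160 site is the one
exception: its declared window (107,199–107,204) sits 1 bp off the rule,
so the targets table carries it as an explicit override while
`predict_edit_window()` stays rule-based. The gp64-160 protospacer
placement itself is anchored from its deletion alleles (`CTCCAC` at
107,200–107,205 equals spacer positions 13–18), which also makes all
five nested deletion alleles left-canonical.

Nine hr (homologous repeat) arrays are laid down as AT-rich tandem
repeats: six long arrays (≥ 150 bp, 30 bp unit × 6) that act as the
mutation hotspots, three short ones (24 bp) that stay quiet. Their
coordinates are structural fixture choices, not measured values; all
region logic is coordinate-agnostic. Reference context for the 14
conserved variants outside the hrs (SNP reference alleles, two insertion
anchors, a 20 bp deletion run in *egt* and a 3 bp run in *AcOrf-91*) is
planted so those records are internally consistent and left-canonical.

## Read simulation

Fragments are whole amplicons (primer to primer); the read pair is the
first/last `read_length` bases, so reads begin at primer starts exactly
as amplicon sequencing does. Per amplicon, fragments are drawn until the
*mean insert coverage* (read bases inside the insert / insert length)
reaches the scenario depth; with the default 1 kb amplicons and 2×300 bp
reads this puts ~688 spanning reads on every position inside a read
window at nominal 400×. `read_length` defaults to 300 (MiSeq v3
geometry): with 250 bp reads the fragment geometry would leave a 500 bp
dead zone in the middle of every 1 kb amplicon and several target
positions would be unsequencable, so 300 is the coherent default for
this amplicon length.

Each fragment's haplotype is drawn independently with the scenario
frequencies; variants whose affected reference intervals overlap (the
nested gp64-160 series) are treated as mutually exclusive repair
outcomes via one multinomial draw per overlap cluster — overlapping
deletions on a single haplotype would be unrepresentable downstream.
Per-base Phred qualities come from a truncated normal (mean 32, sd 3,
bounds 2–41) and substitutions are realized at `10^(-Q/10)` (~6×10⁻⁴
per base); indel sequencing errors default to 10⁻⁵ per base so spiked
indels stay cleanly separated from noise at desk scale. All randomness
flows from one seed per technical replicate; identical seeds give
byte-identical FASTQ.

What the simulator does *not* emulate: PCR chimeras, primer-mismatch
dropout (a deletion destroying a primer site would suppress that
haplotype's amplicon in reality), tagmentation artifacts, batch quality
drift, or strand bias. Passing tests therefore demonstrate correctness
of the pipeline's bookkeeping and statistics under idealized noise, not
robustness to amplification pathology.

## Alignment and filters

Amplicon assignment matches each mate's 5′ 22-mer against the scheme's
primers within edit distance 2 (exact matches short-circuit); zero or
tied matches leave the pair unassigned, and MAPQ is binary 60/0 because
graded mapper-style MAPQ is meaningless when the amplicon of origin is
either known or not. Alignment is banded affine-gap (match +2, mismatch
−4, gap open −6, extend −1; a gap of length L costs `open + L·ext`),
global in the read and free at the window ends; the band (default 64,
working rule: twice the longest expected indel) is centred on the
diagonal implied by the primer start. Scores were verified against an
independent unbanded affine aligner on random instances.

Filters follow samtools semantics: flag mask 2308 (= 4 + 256 + 2048)
and `MAPQ ≥ 10` (keep-if-≥, boundary tested); primer clipping converts
primer-overlapping aligned bases at the read ends to soft clips
(assigned reads clip only against their own amplicon's primers, so a
deep read spanning a neighbour's primer site keeps those genuine
template bases; unassigned reads clip conservatively against any
end-overlapping primer); `--filter-len 200` is interpreted as keep if
the post-clip aligned query length is ≥ 200, matching the
minimum-kept-length semantics of the underlying tools.

## Calling and the error model

Spanning depth has no quality gate (depth is physical coverage, which
keeps the nested deletion alleles on a common denominator); substitution
support requires Phred ≥ 20; deletions are exempt — no base exists at
the event — and record the mean of the two flanking read bases, the
closest observable. The expected error count is
`E = round(total_dp · 10^(−q̄/10))` (round half up, floored at 0), and
the p-value is the one-sided Fisher's exact test of
`[[alt_dp, total_dp−alt_dp], [E, total_dp−E]]`, checked exhaustively
against direct hypergeometric tail summation. Emission requires
`alt_freq ≥ 1%`; truth requires `p ≤ 0.05` (inclusive) in *both*
replicates, with conservative merging (mean frequency, maximum p,
all-replicates pass) — the replicate-merge statistics are this package's
choice, recorded in the output, since concordance tools do not specify
them.

## Detection limits near the calling floor

At nominal 400× (≈ 688 spanning reads per covered position) the 1%
floor demands ≥ 7 supporting reads per replicate. For a true 1.43%
variant that is a Binomial(688, 0.0143) tail: P(called) ≈ 0.86 per
replicate, ≈ 0.74 for both. Duplicate-concordance detection of variants
within ~0.5 percentage points of the floor is therefore intrinsically
unreliable at this depth — the package's stochastic test suite asserts
a 95% recovery bar per spiked deletion and that bar is not attainable
for the 1.43% allele, which the suite reports honestly. Frequencies of
detected variants are unbiased (verified at 3000×, recovered 4.57% for
a 4.51% spike).

## Problem sizes used

Simulation-backed tests and the acceptance script restrict read
generation to the amplicons overlapping each scenario's variants (1–2 of
the 134 amplicons; geometry, depth 400×, duplicate replicates and every
threshold unchanged). Untouched amplicons contribute nothing to the
measured quantities, so this is a pure problem-size choice; a full-genome
run is a single flag away (`region = NULL`).

## Known limitations

* The conservation fixture reproduces the *bookkeeping* (141 stock
  variants, 97 carried over, 14 conserved outside hrs) with synthetic
  positions inside the fixture's hr arrays; only the 14 off-hr variants
  carry meaningful coordinates.
* Off-target scanning is Hamming + PAM presence only — no CFD/MIT-style
  position weighting, by design.
* The dual-target (two simultaneous cuts) excision products are not
  modeled; the corresponding scenario cells carry no spiked variants.
* SAM text is the interchange format; BAM is intentionally out of scope.
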