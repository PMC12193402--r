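# ampedit

Tiled-amplicon minor-variant detection and CRISPR-Cas9 edit attribution
for large dsDNA viral genomes.

## The problem

When a replicating viral genome — here a recombinant baculovirus
expression vector (rBEV, an AcMNPV-derived ~120–134 kb dsDNA genome) — is
targeted transiently by CRISPR-Cas9 during infection, only a minority of
genomes acquire edits. The repair indels (1–5 bp, anchored 3–4 bp
upstream of the PAM) therefore never reach consensus: they appear as
*minor species* at 1–10% frequency in a heterogeneous pool of genomes.
Detecting them requires deep tiled-amplicon sequencing, strict alignment
hygiene (primer clipping, mapping-quality and length filters), a
quality-aware error model, and technical-replicate concordance. The same
machinery also answers two population-genetic questions: which variants
in the AT-rich homologous-repeat (hr) mutation hotspots are *conserved*
across viral passages, and whether the guide RNAs have plausible
off-target sites.

`ampedit` implements that pipeline end to end, together with a
deterministic synthetic-data generator (reference genome with planted
protospacers, hr repeat arrays, two-pool tiled primer scheme, paired-end
reads with spiked indel haplotypes) so that every stage is testable
without any external data.

## The method

For each candidate allele at a pileup column the caller records the
supporting depth `alt_dp` (substitution support gated at Phred ≥ 20;
deletions carry no base quality and use the mean flanking quality), the
physical spanning depth `total_dp` (deletion-spanning reads included),
and the mean supporting quality `q̄`. The expected error count at that
column is

    E = round( total_dp · 10^(−q̄/10) )

and the allele is scored with a one-sided Fisher's exact test on the
2×2 table

    [ alt_dp        total_dp − alt_dp ]
    [ E             total_dp − E      ]

A variant is emitted if `alt_freq = alt_dp / total_dp ≥ 1%`, is a **true
mutation** if `p ≤ 0.05`, and must be called in **both** technical
replicates (exact `(region, pos, ref, alt)` key match after indel
left-normalization) to survive. Upstream, reads are assigned to their
amplicon by primer-prefix matching, aligned with a banded affine-gap
aligner (global in the read, local in the amplicon window), indels are
left-normalized, records failing `MAPQ ≥ 10` or carrying SAM flag bits
2308 (unmapped / secondary / supplementary) are dropped, primer-aligned
bases are soft-clipped, and reads shorter than 200 aligned bases after
clipping are removed.

On the CRISPR side, `predict_edit_window()` turns a located
protospacer+PAM into the 6 bp window of anchor positions reachable by
1–5 bp repair indels 3–4 bp upstream of the PAM (protospacer positions
13–18); `scan_off_targets()` slides the 20-mer spacer over both strands
counting Hamming mismatches and checking NGG presence.
`compare_to_stock()` labels post-assay variants as conserved-from-stock,
control-shared or unique, and reports the percentage of stock variants
carried over.

## Worked example

Build the fixture, simulate the bundled gp64+378 cell-pellet scenario
(a 1 bp deletion spiked at 4.51% haplotype frequency, 400× in technical
duplicate), and run the full pipeline:

```r
library(ampedit)

ref     <- build_reference()                       # 120 kb synthetic rBEV-like genome
sch     <- design_tiling(ref$genome)               # 134 amplicons, 1 kb, two pools
windows <- edit_windows(ref$genome, ref$targets)   # estimated indel windows

sc  <- deletion_scenarios()[["gp64+378.cell_pellet"]]
res <- run_scenario(ref$genome, sch, sc, region = c(106975, 106981))
match_on_target(res$true, windows)
```

which prints (seed-fixed):

```
     POS REF ALT ALT_DP   ALT_FREQ TOTAL_DP         PVAL PASS TARGET_LABEL   TARGET
1 106975   G  -T   36.5 0.05305233      688 6.741955e-10 TRUE    on_target gp64+378
```

— the spiked deletion is recovered at its exact anchor position
(106,975, allele `-T`), at 5.31% merged frequency (spiked 4.51%, within
binomial error at this depth), passes the error model (`PVAL` ≪ 0.05),
and falls inside the predicted gp64+378 edit window (106,975–106,980).
The conservation worked example:

```r
fx <- fixture_conservation_tables(ref)
compare_to_stock(fx$ti, fx$stock, fx$controls)
#> <conservation> 97/141 stock variants carried over (68.8%)
#> conserved_from_stock       control_shared               unique
#>                   97                   19                   44
```

A thin command-line front end over the same functions ships in
`inst/scripts/ampedit` (subcommands `simulate`, `align`, `clip-filter`,
`call`, `filter-replicates`, `predict-windows`, `offtarget`, `conserve`,
`run`).

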