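---
title: "Detecting a germline-restricted chromosome from paired soma/germline long reads: methods and design notes"
author: "grcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GRC detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical procedure `grcscan` implements,
the assumptions behind it, the choices made where the design was
genuinely open, and what the built-in synthetic data can and cannot tell
you about real data.

## The detection model

A germline-restricted chromosome (GRC) is present in germline cells
(haploid, and only in a subset of cells of a testis sample) and absent
from soma. Its sequence derives from A-chromosome material with point
divergence on the order of a few percent. When germline reads are mapped
*permissively* (allowing ~10% divergence and secondary alignments) onto a
somatic reference, GRC-derived reads align to the homologous A-chromosome
regions and show their diverged bases as mismatches. Three consequences
drive the pipeline:

1. **Site level.** At a position inside a GRC-homologous region, the
   germline pileup contains the GRC allele at roughly the GRC's
   cell-fraction depth, while the soma pileup does not contain it at all.
   Ordinary heterozygous sites, by contrast, show both alleles in *both*
   samples (same individual), and sequencing errors are mostly pruned by
   the depth-1 rule. An allele present in the germline allele set but not
   the soma set is *germline-specific*; the converse is *soma-specific*.
2. **Window level.** GRC homology is regional, so germline-specific
   alleles cluster. Over fixed 25-kb windows with at least 20 SNVs,
   `relspec = (Σ germline-specific − Σ soma-specific) / n_SNVs`
   is near the per-site specific-allele rate: close to 1 inside
   GRC-homologous regions (nearly every SNV there is a diverged site
   carrying exactly one germline-specific allele) and close to 0 in the
   background, where SNVs are shared heterozygous sites. The distribution
   is bimodal and the top fraction of windows is selected by rank.
3. **Read level.** A germline read of ~18 kb crossing a 1%-diverged
   region spans ~180 diverged sites, so true GRC reads carry large
   numbers of germline-specific alleles and are recoverable essentially
   without loss.

### Assumptions

* Soma and germline samples come from the same individual (shared
  heterozygosity; anything germline-specific is GRC or error).
* Substitution-dominated divergence; the pipeline's statistics are
  SNV-based and indels are ignored throughout.
* HiFi-accuracy reads: no base-quality filtering is performed (a
  mapping-quality floor is available, default 0, since the permissive
  mapping is intentional).
* Depth filters assume sequencing at tens-fold coverage; the defaults
  (soma ≥ 15, germline ≥ 45) are half the median depths of the design
  this package targets (soma ~30×, germline ~88×) and can be recomputed
  from the data with `"auto"`.

## Stage-by-stage choices

**Pileup and SNV calling** (`count_alleles()`, `call_snv_sites()`).
Counting uses primary alignments only, via the standard htslib pileup
engine. "Depth" is the total read count at the site in that sample;
singleton alleles still count toward depth but are pruned from the
allele *sets* before any set operation. Pruning is symmetric in both
samples — the conservative reading, exposed as `ignore_singletons`. A
site qualifies as an SNV when the pruned union of alleles across both
samples has ≥ 2 members; this is reference-agnostic, because specificity,
not reference state, is what downstream stages consume. Multi-allelic
sites are kept and flagged, and each specific allele contributes one
count per site regardless of its depth (the window statistic is an
allele count, not depth-weighted).

**Windows and selection** (`make_windows()`, `window_relspec()`,
`select_top_windows()`). Windows are a fixed 25-kb tiling (a partial
terminal window is kept and is eligible if it meets the SNV minimum — no
length normalization is needed because relspec is per-SNV). Selection
takes `k = max(1, floor(top_fraction × n_eligible))` windows by relspec
rank, with ties broken by the germline-specific sum and then genomic
order, so the output is invariant to input row order. Windows without a
positive germline-specific excess are never selected; when no window has
`relspec > 0` the function raises a typed condition
(`grcscan_no_selection`) rather than returning an arbitrary set — the
correct outcome for a sample without a GRC. A rank-based cut is used
rather than a threshold at the distribution's antimode; the antimode
variant would behave identically whenever the two modes separate.

**Read extraction** (`extract_reads()`). A germline read is extracted
when its primary alignment overlaps a selected window and its aligned
base equals a germline-specific allele at `min_specific` or more sites.
One vote per read: secondary/supplementary alignments are ignored. The
package default is `min_specific = 1` (the weakest reading of "reads
with germline-specific variants"). For error-bearing data a higher
threshold is advisable for two quantifiable reasons: (i) an A-chromosome
read spanning *d* diverged sites carries an error matching the
germline-specific allele with probability ≈ `d × error_rate / 3`
(≈ 3% per read at d = 180, e = 5e-4); and (ii) two reads sharing the
same error at one position create a depth-2 germline-specific site whose
two carrier reads each gain one carried allele — with ~9 errors per read
at ~110× germline depth, each candidate read acquires
Binomial(9, ≈ 0.02) such spurious alleles, so ~1% of background reads
reach 2. The recovery analyses in this package therefore use
`min_specific = 3`, which suppresses both channels while leaving true
carriers (≈ 180 alleles) untouched.

**Coverage validation and copy number** (`window_coverage()`,
`coverage_summary()`, `estimate_copy_number()`, `size_estimates()`).
This stage models the *stringent* re-mapping of both read sets against
the combined assembly (A-chromosomes + GRC contigs). The normalization
factor is the median over A-chromosome windows of the per-window
germline/soma depth ratio — note this is not identical to the ratio of
the two depth medians; the per-window median is what is implemented, and
windows with zero soma depth are excluded from it (and reported).
Corrected coverage subtracts `soma × factor` from the raw germline
coverage, removing the cross-mapping component under the assumption that
cross-mapping scales with sequencing effort; negative values are clamped
to 0 and flagged, and a zero median corrected coverage is a hard error
(degenerate normalization). Copy number truncates to an integer via
floor. The truncation rule is silent about windows between 0.5 and 1
copy: by default these count once in the copy-aware length (they contain
sequence; `round_half_up_single = FALSE` gives the bare floor), while
windows with zero corrected coverage contribute nothing. N50 uses the
convention that an exact half-total tie resolves toward the larger
contig set (`n50(c(100, 50, 40, 10))` is 50).

**Paralog report** (`pair_paralogs()`, `compare_architecture()`,
`copy_number_correlation()`, `expression_summary()`). Paralogs are gene
models sharing a symbol across compartments; a symbol's gene-level "copy
number" is its count of distinct gene models in a compartment —
deliberately a different concept, with a different name, from the
coverage-based window copy number above. Isoform length is spliced
length (sum of exon blocks), not genomic span. The architecture tests
are paired two-sided Wilcoxon signed-rank tests on per-symbol medians
(the reading consistent with "subtracting the respective median
values"); pooling all isoforms instead would mix within-symbol and
between-symbol variation and is not offered as a default. The exact null
distribution is used up to 25 non-zero differences, the normal
approximation above; zero differences are dropped, and fewer than one
informative pair skips the test with a warning rather than fabricating a
p-value. Expression sums TPM over isoforms per symbol × compartment ×
sex, floors sums at 0.1 (the pseudo-count that keeps ratios of
unexpressed genes at 1) before fold-changes, and flags symbols at
≥ 10-fold GRC excess in at least one sex.

## The synthetic data: what it emulates, and what it does not

`simulate_dataset()` generates the *detection* conditions: a multi-contig
A-chromosome reference (default 5 × 1 Mb), a GRC built from scattered
donor segments (default 200 kb in 8 segments) with exactly
`round(divergence × length)` substitutions per segment (default 1%,
never back to the reference base), shared heterozygosity at `1e-3` per
base so the shared-allele class is genuinely exercised, HiFi-like reads
(18 kb ± 3 kb; substitution errors at `5e-4`, reflecting median HiFi
accuracy around Q33), soma at 30×, germline at 88× on A-chromosomes and
24× per GRC copy, and a planted 5-copy segment. Alignments are emitted
directly at the reads' true loci (GRC reads at their donor's homologous
coordinates) with single match-run CIGARs and consistent NM/MD tags.
Design simplifications, each chosen to isolate the statistics from
alignment semantics:

* substitution-only mutation and error model — no indels, no
  homopolymer artifacts, trivial CIGARs;
* reads sampled wholly within donor segments, so every alignment is one
  ungapped block (no clipping);
* all reads forward-strand — no statistic in scope depends on
  orientation;
* donor segments snap to a placement grid equal to the analysis window
  (25 kb), so window-level truth labels are unambiguous: a window either
  is or is not a donor window, with no sliver overlaps;
* read ids are assigned after shuffling and encode nothing about origin.

Passing the recovery checks on this generator therefore demonstrates the
statistical machinery — filtering, specificity classification, window
ranking, carrier detection, coverage arithmetic — under the intended
coverage and divergence structure. It does *not* demonstrate robustness
to real-world mapping artifacts: repeats, indel errors, clipped or
split alignments, reference bias, or GC-coverage waves. Those enter
through the upstream mapper and are outside this package's scope.

`simulate_validation_dataset()` generates the *validation* conditions —
the combined-assembly re-mapping — as coverage structure only: the GRC
assembly sequence is synthetic (uniform random), since coverage
arithmetic is independent of homology. Read counts are plateau-calibrated
(the plateau away from contig ends equals the configured depth, which is
what depth medians report), and reads of the extra copies of the
multicopy region are drawn with overhang across the region boundary, the
way reads from a collapsed tandem array pile onto its single assembled
copy — making the in-region depth exactly `copies × depth` with
transition shoulders outside.

`simulate_annotation()` plants, on a configurable number of shared
symbols (default 83, the study scale), a systematic 30% GRC isoform
shortening, copy numbers correlated through a shared latent rate, one
20-fold GRC-overexpressed symbol and one truncated symbol. Unplanted
symbols have GRC/A-chromosome expression multipliers bounded in
(0.2, 2.5) with sex jitter in (0.85, 1.2), so no unplanted symbol can
reach the 10-fold flag — which is what makes "all planted flags and no
others" a meaningful test.

## Evaluation choices and problem sizes

The recovery analyses (`evaluate_detection()`, `evaluate_validation()`)
run at deliberately scaled-down sizes: a 5-Mb reference with a 200-kb
GRC for detection, and a 1-Mb A-chromosome set with a 4-Mb GRC assembly
(40-window multicopy region) for validation. Two evaluation parameters
deserve explanation:

* **Selection fraction.** On the scaled genome the GRC-homologous share
  of windows is ~4%, twenty times the ~1% of a full-size genome, so the
  evaluation selects at the truth fraction
  (`(n_true + 0.5) / n_eligible`; the half window guards `floor()`
  against floating-point noise). The study constant `top_fraction =
  0.01` remains the package default — at genome scale the two coincide.
* **Validation region size.** A 25-kb window mean of 18-kb reads is
  intrinsically noisy (relative SD ≈ 17% at 24×, ≈ 8% at 120×), so a
  single window can never support a half-copy-accurate estimate. The
  planted region spans 40 windows and its copy number is summarized by
  the median over them (SE ≈ 0.16 copies by the variance arithmetic
  above); the normalization median is taken over 160 GRC windows.

All generators take a mandatory integer seed; every simulation quantity
derives from it, and regenerating with the same configuration is
byte-identical. Stage order, parameters (including auto-derived
thresholds), input checksums and stage counts are recorded in the
pipeline manifest; the pipeline itself is deterministic, so rerunning an
identical configuration reproduces identical outputs.

## Known limitations

* Indels, structural variation, and transposable-element content are not
  modeled; real GRC assemblies are repeat-rich and the copy-number table
  only *reports* collapsed regions, it does not resolve them.
* The cell-type composition of the germline sample is abstracted into a
  single scalar GRC depth (`grc_cell_fraction_depth`); no attempt is
  made to model ploidy by cell type.
* The pileup is in-memory per sample; for full-genome HiFi BAMs a
  chromosome-at-a-time invocation is the intended usage pattern.
* Gene symbols are taken as given; protein-database assignment,
  GO enrichment, and ortholog detection are out of scope.
* Wilcoxon exactness is only claimed for tie-free differences at n ≤ 25;
  with heavy ties the normal approximation is used (with continuity
  correction), as in the reference implementation.
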