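---
title: "The smMIP targeted-sequencing workflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The smMIP targeted-sequencing workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipkit)
```

# Scope and model

Single-molecule molecular inversion probes (smMIPs) capture a targeted
genomic interval between two hybridising arms; gap-fill polymerisation
and ligation circularise the probe, and a degenerate molecular tag
records the identity of each captured molecule so that PCR duplicates
can be collapsed before any quantitative step. mipkit implements the
full desk-side counterpart of such an assay: panel design, a capture
simulator with ground truth, tag-aware read processing, coverage QC, a
pileup genotype caller, concordance scoring, and the clinical
annotation arithmetic used when reporting variants (HGVS codon
numbering and mature-peptide renumbering, dominant segregation,
frequency filtering, cohort summaries).

Throughout the package, coordinates are 0-based half-open; they become
1-based only in the VCF writer and the HGVS helpers. This single
convention is deliberate: every off-by-one class of bug we guard
against in tests lives at the emitters, not in the core.

# Panel design

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pad_bp` | 25 | bp | pad each target so exon–intron boundaries are captured |
| `ext_arm_len_range` | 16–20 | nt | extension arm search range |
| `lig_arm_len_range` | 20–24 | nt | ligation arm search range |
| `gap_fill_len` | 112 | nt | insert length; must be jointly covered by two 100 nt reads after arm/tag removal |
| `tag_len` | 8 | nt | 65,536 tag space; collisions are rare at the per-probe molecule counts used here and are recorded in the simulator's ledger |
| `max_oligo_len` | 150 | nt | single-microarray synthesis constraint |

The padding, the 150-mer bound and the amplification primer sequences
(mipPrep1F/mipPrep1R, both ending in the EarI recognition site
`CTCTTC`) are assay constants; the arm-length ranges, gap-fill length
and tag length are not dictated by the assay description and follow
common smMIP practice. All are overridable through `design_params()`.

## Tiling and arm choice

Tiling is greedy left-to-right with a fixed gap-fill length; the last
probe of each region is shifted left so that the union of gap fills
covers every padded base (an invariant the test-suite checks against a
brute-force per-base mask). We deliberately do not double-tile or
alternate strands: single-strand tiling is the simplest scheme that
satisfies the coverage invariant, and all probes are emitted on the
plus strand.

Arms are scored by `|GC − 0.5|` summed over the two arms, lower being
better. A melting-temperature model would be the laboratory-grade
alternative; the GC proxy is deterministic, dependency-free, and
monotone in the same quantity for arms of this length. Arms containing
`N` or leaving the contig are rejected; a region where no valid arm
pair exists is a design failure that names the offending region.

## Oligo assembly and EarI release

Synthesis oligos are `primer_F + lig_arm + backbone_left + N×8 +
backbone_right + ext_arm + rc(primer_R)`. EarI cuts one nucleotide
3' of `CTCTTC` on the top strand and, for bottom-strand sites (a
`GAAGAG` occurrence on the top strand), four nucleotides 5' of the
occurrence. `digest_ear1()` applies exactly this geometry and returns
top-strand fragments that partition the input. A consequence worth
stating explicitly: with the primers directly abutting the probe body,
digestion transfers 1 nt of the ligation arm and 4 nt of the extension
arm to the primer-side fragments. The released body therefore contains
the backbone, the tag block and the arms *minus those margins*; the
test-suite asserts precisely this, rather than pretending the arms
survive intact.

# The capture simulator

The simulator is first-class, tested code: it is the package's source
of ground truth. `plant_variants()` applies VCF-style specs to build a
diploid sample (heterozygous variants on haplotype 1 only), and
`simulate_capture()` draws, per probe, a fixed number of molecules
**alternately** from the two haplotypes, assigns each an i.i.d. random
tag and a PCR duplicate count distributed 1 + Geometric (one-parameter
and heavy-tailed — a reasonable stand-in for amplification jackpots),
and emits paired 100 bp reads: read 1 is extension arm + insert; read
2 is tag + reverse complement of (insert + ligation arm). Substitution
errors are applied i.i.d. per base at `base_error_rate`; quality
strings are constant Phred 30, because the caller consumes a scalar
error rate.

Defaults (`sim_config()`): 50 molecules per probe, duplication mean 2,
base error 0.001, read length 100, all seeded. The alternating
haplotype draw makes the alt fraction at a het site essentially exact
rather than Binomial; the balance test in the suite uses the
4-standard-deviation binomial envelope, which the alternating scheme
satisfies trivially.

What the simulator does **not** emulate — and hence what passing tests
do not show about real data: indel sequencing errors, per-probe capture
efficiency variation and GC bias, arm-hybridisation failure over
variant bases, chimeric molecules, and realistic quality profiles.
Results on simulated data are a correctness check of the pipeline's
logic, not a performance claim about any particular assay.

# Read processing

Assignment replaces genome-wide alignment: for a known panel, matching
both arm prefixes (read 1 against extension arms; read 2, after the
8 nt tag, against reverse-complemented ligation arms) identifies the
probe directly. The budget is one substitution per arm by default,
implemented exactly (dictionary of all Hamming-≤1 neighbours), with a
brute-force scan for larger budgets. A pair matching more than one
probe is `ambiguous`, matching none `no_match`; both are values, not
errors. Indels in arms are not tolerated — arms are short and an indel
would make the trim point ambiguous.

Deduplication groups by (probe, tag). Exact grouping is the default;
the directional Hamming-1 rule (merge a tag into a neighbour with at
least twice its count) is available for tag-error-tolerant collapsing
and is verified against an all-pairs oracle. Consensus takes the
per-position majority with ties as `N`; the two mate fragments are then
joined into a single insert by scanning candidate insert lengths within
±10 nt of the reference span and choosing the length whose implied
overlap disagrees least (ties resolved toward the reference length,
then the shorter insert; conflicting overlap bases become `N`).

# Coverage QC

Depth is unique-molecule depth: each molecule adds one to every padded
target base its gap fill covers. Arms are excluded — only gap-fill
bases are sequenced inserts. A sample passes when at least 80% of
targeted bases reach 8× (both bounds inclusive); the fraction at 40×
and the median are reported alongside. The median over an even number
of bases is defined as the lower central value, so the statistic is
always an attained integer depth. Exons are flagged when their mean
depth is strictly below 10 or no base is covered. Whether the pass rule
should be assessed on padded or unpadded bases is genuinely
underdetermined; padded is the default here (it is the domain the panel
was designed to cover) and the exon table accepts any region set.

# Variant calling

## Alignment

Each consensus insert is aligned globally to its probe's reference
window under match 0 / mismatch 1 / gap 1. Equal-length inserts with at
most two mismatches shortcut the DP (a gapped alignment of equal-length
strings costs at least 2, so the substitution-only alignment is
optimal). The general case uses a Gotoh-style DP whose gap-opening term
is infinitesimal (10⁻⁶): the integer optimum is exactly the stated
unit-cost optimum — verified against exhaustive enumeration for all
short string pairs — while ties among cost-equal paths resolve in
favour of contiguous, leftmost gaps. This matters in practice: under
pure unit costs a 10 nt deletion fragments into several co-optimal
scattered gaps whenever an interstitial base coincidentally matches,
which destroys indel recovery. The traceback preference order
(diagonal, then reference gap, then insert gap; extend a gap before
reopening) is fixed, so CIGARs are byte-stable.

## Pileup and genotype model

Each molecule contributes at most one observation per reference
position. Deletions contribute a deletion allele at their anchor (the
preceding base), insertions likewise; observations of `N` carry no
evidence and are dropped. With per-observation error `e` (default
0.01), the three diploid hypotheses have per-observation likelihoods
`1 − e` / `e/3` (homozygotes) and `(1 − e)/2 + e/6` (heterozygote,
for each of the two alleles), a uniform prior, and
`GQ = −10·log₁₀(1 − posterior)`. Calls are emitted at depth ≥ 8 —
the depth gate used for reporting throughout the package — and
GQ ≥ 20. GQ 20 is a declared default, not an assay constant. Because
the caller sees consensus molecules, its depth is single-molecule
depth, matching the nonduplicate-read convention of the QC stage.

Indels up to 10 nt are detected through the per-probe global alignment;
there is no haplotype assembly. Variant records are left-normalized
before VCF emission, and `compare_to_truth()` normalizes both call and
truth sets before matching, comparing genotypes as unordered allele
multisets. Because concordance "over all genotyped positions" and
"over variant sites" answer different questions, the report carries
both denominators.

# Numerical and degenerate-input choices

- Percentages in cohort summaries round half away from zero (59% for
  30/51), matching clinical table conventions; base R's `round()`
  rounds half to even and is not used there.
- Zero assessable truth variants yields `NA` sensitivity, not an error.
- An empty target domain, a zero-length exon, all-untested pedigrees
  and malformed allele frequencies are input errors with named causes.
- Tag collisions are not prevented; they occur at the birthday rate and
  are visible in the ledger, so the dedup oracle can account for them.
- All randomness flows from explicit integer seeds; the pipeline
  derives per-stage seeds as `seed + stage index` so stages are
  independently reproducible, and re-running a config reproduces every
  output checksum.

# Problem sizes

The demonstration scale used by the heavier tests is a 2-contig,
24-exon panel (600 bp exons, ~144 probes) carrying 300 SNVs and 20
indels, processed at 25 (noise-free) or 40 (0.5% base error) molecules
per probe — a deliberate scale-down of a clinical panel that keeps a
full run in the order of a minute while preserving every structural
feature (multi-probe exons, probe overlap at region ends, het/hom
mixtures, indels near — but not across — gap-fill margins). The
headline real-assay coverage figures of such panels depend on actual
instrument data and are intentionally not claimed by any test here.

# Known limitations

- Arm uniqueness is enforced only within the panel (duplicate arm
  pairs are a panel error); there is no genome-wide paralog screen, so
  paralogous captures (a real concern for, e.g., the GH1/GH2/CSH
  cluster) are out of scope.
- Only substitution errors are simulated and only substitutions are
  tolerated in arms.
- The caller is single-sample; there is no joint calling, no VQSR-like
  filtering, and no annotation-database lookup beyond the generic
  allele-frequency filter.
- Segregation checking implements the autosomal dominant expectation
  only; other models error as unsupported rather than guessing.
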