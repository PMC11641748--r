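---
title: "Dual-window AEE analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-window AEE analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualwindow)
```

## The statistic and its windows

Every read is aligned globally to the reference amplicon and classified as
modified or unmodified within a quantification window centered on the
predicted Cas9 cut site. The alleged editing efficiency for window width
$w$ is

$$\mathrm{AEE}(w) = \frac{n_\text{modified}(w)}{n_\text{modified}(w) + n_\text{unmodified}(w)},$$

with unalignable reads discarded from the denominator. "Alleged" is the
operative word: the statistic counts any insertion, deletion or
substitution inside the window, whether it came from Cas9 or from the
genome itself.

The window is interpreted as a **total width** $w$ centered on the
inter-base cut coordinate: the half-open reference interval
$[c - w/2,\; c + w/2)$, clipped to the amplicon. For $w = 2$ that is one
base on each side of the cut; for $w = 20$, ten bases each side. This
reading makes the narrow/wide contrast meaningful (a cut-site indel
registers in both; variation at offset $-8$ only in the wide window) and
matches how cut-centered windows are specified in the popular amplicon
tools. The cut site is fixed at 3 bp 5′ of the PAM (`cut_offset = 17` from
the protospacer 5′ end) — the canonical blunt SpCas9 cut; it is a
parameter of `guide_spec()` for nucleases that differ.

Classification rules, applied to the left-normalized events of a read:

* an **insertion** counts iff its anchor lies strictly inside the window
  interval;
* a **deletion** counts iff its reference interval overlaps the window
  (half-open interval arithmetic);
* a **substitution** counts iff its position lies in the window, unless
  either base is `N` (an `N` is missing data, not an edit).

Because the two windows are nested and evaluated on the same aligned read
partition, $\mathrm{AEE}(2) \le \mathrm{AEE}(20)$ holds on every read set;
the implementation asserts this on every run. The discrepancy is reported
in percentage points, $\Delta = 100\,(\mathrm{AEE}(20) -
\mathrm{AEE}(2))$.

## Alignment

The aligner is a compiled Needleman–Wunsch/Gotoh global alignment with
affine gaps. Scoring defaults: match $+2$, mismatch $-1$, gap open $-6$
(the opening penalty includes the first gapped base), gap extension $-1$.
These are conventional amplicon-alignment values chosen so that a 10-nt
NHEJ deletion (cost 15) is still vastly preferred over 10 scattered
mismatches (cost 30 relative to matches), while unrelated sequence falls
below the identity floor. A read is discarded when fewer than 60 % of its
alignment columns are identities; random sequence aligns near 40–50 %
identity under these scores, genuine NHEJ alleles above 90 %.

Score-equivalent indel placements are resolved by shifting every indel to
its leftmost equivalent position against the reference (the usual
variant-normalization convention). This makes the window test
deterministic: without it, the same 1-nt deletion in a homopolymer could
fall inside or outside the narrow window depending on aligner tie-breaks.
In tests the aligner's scores are checked exactly against an independent
dynamic-programming implementation (`Biostrings::pairwiseAlignment` with
the matching gap convention) on instances up to 60 nt.

## Threshold, grouping and statistics

The discrepancy threshold is derived from positive-control samples — loci
where editing is real and any narrow/wide discrepancy reflects benign
variation plus error: `derive_threshold()` takes the largest control
$\Delta$ and rounds to the nearest integer percentage point (the published
positive-control pair 40.97 %/51.09 % yields $10.12 \to 10$ pp). Rounding
to whole points treats the threshold as a reporting convention rather than
a fitted parameter; the raw maximum is available by setting `digits`.
A zero threshold is refused as degenerate. Grouping is
boundary-inclusive: $\Delta \le$ threshold is concordant, consistent with
the threshold being an upper bound on benign discrepancy.

AEE proportions are arcsine-square-root transformed
($\arcsin\sqrt{p}$) before parametric comparison. Homogeneity of variance
uses the mean-centered Levene $W$ — the one-way ANOVA $F$ on absolute
deviations from group means — which errors when the absolute residuals
have no within-group spread (the statistic is undefined there, not zero).
The window comparison is a repeated-measures design in which each sgRNA
contributes exactly two measurements, so the within-subject one-way
RM-ANOVA reduces to its two-level special case: $F = t^2$ of the paired
$t$ on the transformed pairs, $p$ from $F(1, n-1)$. The equivalence to the
general `aov(y ~ window + Error(subject))` route is asserted in tests to
$10^{-9}$ relative tolerance. A two-factor mixed design with the
concordant/discordant grouping as a between-subject factor would also be
defensible; the per-group paired test was chosen because the grouping is
itself derived from the same window contrast being tested, which makes a
between-factor interpretation circular.

## The artifact classifier

`classify_locus()` applies ordered rules to the sgRNA-free control
dual-window result and the control/treated allele tables (reads collapsed
by their rendered sequence over a ±20 nt span around the cut; deletions
rendered as `-`, insertions as lowercase bases at their anchor):

1. **NO_ARTIFACT** — control $\Delta \le$ threshold and control
   $\mathrm{AEE}(2) \le$ noise floor.
2. **REPEAT** — control shows narrow-window "editing" with no sgRNA
   present, or at least two distinct modified allele families with
   indel-like differences. Repeats take precedence over the homolog rule
   because narrow-window false positives are their distinguishing signal —
   co-amplified paralogs carry indel-like divergence that can land
   anywhere, including on the cut.
3. **DIVERGENT_HOMOLOG** — exactly one substitution-only control allele
   above the major-allele floor whose spanning sequence reappears in the
   treated sample at a matching frequency. Amplicon data cannot establish
   *where* the second haplotype resides (sex chromosome or autosomal
   divergent locus); the label asserts the allele pattern only.
4. **SNP** — control's modified alleles are substitution-only, each below
   the major-allele floor, collectively above the noise floor.
5. **UNCLASSIFIED** otherwise.

Parameters, all in `classifier_params()`:

| parameter | default | meaning |
|---|---|---|
| `noise_floor` | 0.02 | allele/AEE frequency separating sequencing error from genetic variation |
| `major_floor` | 0.10 | frequency above which a substitution-only allele is a "major" haplotype |
| `freq_tol` | 0.10 | control/treated allele frequency match tolerance (10 pp) |
| `min_allele_freq` | 0.005 | alleles below this are ignored (single-read error alleles) |

The noise floor sits well above the per-window error signal at the default
error rate (a 0.1 % per-base error yields ≈ 0.2 % narrow-window AEE) and
well below real variation frequencies (a heterozygous carrier contributes
≥ 25 % in expectation at even modest population frequency). The rules are
functions of allele content only; permuting table rows cannot change a
label.

Two ambiguities are inherent and documented rather than hidden. A *single*
SNP carried at high frequency is indistinguishable from a divergent
haplotype by allele pattern — both produce one major substitution-only
control allele mirrored in the treated sample — and is labelled
`DIVERGENT_HOMOLOG`; the SNP rule targets the many-minor-alleles signature
that several independent carriers produce. And the homolog/treated
frequency match assumes editing removes at most `freq_tol` worth of the
haplotype's unmodified allele; at very high editing rates the match can
fail and the locus falls to `UNCLASSIFIED`.

`corrected_efficiency()` recomputes the treated modified fraction after
excluding alleles whose spanning sequence occurs in the control above the
noise floor. It never exceeds the uncorrected AEE. Known limitation: at
loci where many segregating SNPs fragment the control into combination
alleles individually *below* the noise floor, those combinations are not
excluded and the correction is partial — the classifier label (`SNP`) is
the reliable signal there, and the narrow-window AEE the better efficiency
estimate.

## GUIDE-seq-style off-target calling

The desk-scale caller finds dsODN-tagged reads (tag matched in both
orientations within a mismatch budget, via `vmatchPattern`), extracts the
genomic flank adjacent to the tag junction, maps it with exact k-mer seeds
(k = 12, `max_mismatches + 1` non-overlapping seeds, so the pigeonhole
principle guarantees every placement within the budget is seeded) verified
by Hamming distance on both strands, clusters junctions within 10 nt into
integration sites (≥ 2 distinct reads; multi-mapping reads are dropped so
each read supports at most one site), and scores each site by the best
NGG-adjacent placement of the protospacer within ±25 nt, minimizing
protospacer mismatches with ties going to the placement whose predicted
cut lies closest to the junction. Sites with zero mismatches and an NGG
PAM are on-target; everything else is reported with its mismatch
positions. Because the denominator of an "off-target fraction of total
reads" is ambiguous, the report emits both: off-target reads over all
sequenced reads and over tagged reads.

Deliberately out of scope: UMI consolidation (the simulator emits unique
molecules, so distinct-read counting is exact here; on real libraries it
overcounts PCR duplicates), adapter chemistry, and demultiplexing.

## What the simulators emulate — and what they do not

`simulate_reads()` draws each read's template from the mixture
{primary, homolog, paralog₁…}, flags it edited with probability $e$,
applies SNP-carrier substitutions (primary template only), one NHEJ indel
at the cut for edited reads, and uniform substitution error. Ground truth
is emitted per read. The indel spectrum default — 80 % deletions with
truncated-geometric(0.5) lengths 1–10, 20 % insertions of 1–3 nt —
produces the deletion-dominated, short-indel allele tables typical of
NHEJ. Indel placements are chosen so that their *left-normalized* form
still covers the cut: without this, an indel planted in repeated context
canonicalizes away from the narrow window and the simulated rate is not
recoverable even in principle. Insertions get a final base differing from
the base 5′ of the anchor for the same reason.

The single merged-read model (every read spans the whole amplicon) stands
in for merged paired-end sequencing; the analysis unit is the
reconstructed amplicon sequence. No quality scores, PCR chimeras, indel
sequencing errors, or coverage variation are modelled — passing tests
demonstrate correctness of the quantification and classification logic
under the stated read model, not robustness to those real-data artifacts.
The GUIDE-seq simulator plants protospacer sites with chosen mismatch
counts (PAM kept NGG) and emits junction reads `flank + tag` in random
sequencing orientation; background reads are plain genomic fragments.
The expression simulator draws log-normal expression means,
negative-binomial counts over six replicates, and editing efficiencies
with a Gaussian-copula rank correlation to expression
($\rho_\text{Pearson} = 2\sin(\pi\rho_s/6)$), so the planted Spearman
correlation is exact in population.

## Expression normalization

Counts are normalized by median-of-ratios size factors (per-gene geometric
mean reference over replicates, computed on all-positive genes) and
transformed as $\log_2(x/s_j + 1)$, averaged over replicates. This is a
declared stand-in for a regularized log transform: the shrinkage component
is monotone in the counts at the depths simulated here, and the downstream
statistic is a rank correlation, which is invariant to monotone
differences. Size factors are validated against the DESeq2 estimator in
tests. The Spearman correlation uses average ranks for ties and the
$t$-approximation p-value with $n - 2$ df; gene matching is by explicit
identifier.

## Numerical conventions and degenerate inputs

* All coordinates are 0-based, half-open; cut sites are inter-base.
  Human-facing renderings are 1-based.
* Alignment DP scores are integer-valued doubles; traceback equality
  comparisons are exact. Traceback tie preference (diagonal, then
  deletion, then insertion) is irrelevant after left-normalization.
* Zero aligned reads, empty control sets, empty flanks, all-zero count
  tables, zero-variance ranks and constant Levene residuals are errors,
  not silent NAs. Identical paired vectors in the RM comparison return
  $F = 0, p = 1$ (a defined, not degenerate, outcome).
* Seeds: every simulator takes an integer seed and restores the caller's
  RNG state; identical seeds give byte-identical outputs, including
  written FASTA/FASTQ.

## Problem sizes

The bundled checks use sizes chosen to make binomial noise small relative
to the tolerances they assert: 10,000 reads for ±1.5 pp rate recovery,
4,000 reads for the ±2–2.5 pp signature checks, 100 seeded scenarios for
the window-nesting property, 200 loci × 400 reads for the ≥ 95 %
classifier-recovery bound, 20 seeded GUIDE-seq runs for exact site
recovery, and 224 loci × 200 reads for the threshold-grouping fraction.
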