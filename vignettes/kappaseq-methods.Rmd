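---
title: "Methods: from Igk repertoire reads to rearrangement models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Igk repertoire reads to rearrangement models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappaseq)
```

`kappaseq` turns paired-end repertoire reads from the mouse Igκ locus into
per-gene rearrangement statistics and random-forest models of what predicts
rearrangement. This vignette explains the model assumptions, the parameters
that matter, the synthetic-data generator used for validation, and the
design choices taken where the procedure was genuinely open.

## The locus model

A `kappa_ref` holds a genome slice, the Vκ/Jκ annotation, and a registry of
3′-identical Vκ gene pairs. Coordinates are 0-based half-open in memory and
on disk (BED-style TSV); 1-based coordinates appear only in human-readable
output. Orientation is encoded biologically — `deletional` (same
transcriptional orientation as the Jκ–Cκ cluster, so rearrangement excises
the intervening DNA) versus `inversional` — rather than as +/− strand, so a
synthetic locus needs no chromosome context. The slice is oriented with the
Jκ cluster transcribed left-to-right at its right end, which makes
deletional Vκ genes plus-strand.

Three curated corrections are supported as an override table rather than
hard-coded edits: an orientation flip (Vκ8-23-1), an RSS interval
replacement (Vκ4-60), and reclassification of four IMGT non-pseudogenes
(Vκ8-18, Vκ1-35, Vκ14-126, Vκ1-131). The exact replacement RSS coordinates
depend on the user's annotation build, so `igk_default_overrides()` emits
the orientation/functionality rows and leaves RSS coordinates to the user.

The locus is split into Jκ-proximal and Jκ-distal halves at the midpoint of
the genomic span between the most proximal and most distal Vκ gene. For the
real annotation this division falls between Vκ13-76 and Vκ4-77, and when
both names are present the split is pinned there so that boundary is exact;
synthetic loci use the midpoint rule directly.

RIC scores (RSS quality) are consumed as an annotation column. The
published scoring algorithm is not reimplemented: the analyses here use the
score, they do not define it.

## Read preparation

Quality trimming removes the trailing run of 3′ bases with Phred ≤ 20,
reading the published "Phred > 20" strictly: a base at exactly Q20 is
trimmed. If either mate would lose more than 50 bases the entire pair is
discarded — a pair-level rule, because a heavily clipped mate signals a
failed cluster rather than a trimmed adapter.

Merging is an in-house seed-and-extend overlap scan (exact 16-mer seed of
the reverse-complemented mate against mate 1, full scan fallback), with
defaults `min_overlap = 20` bp and mismatch fraction ≤ 0.1. The external
merger used originally runs with unstated defaults, so these two parameters
are documented package choices; on error-free data any designed overlap of
at least `min_overlap` merges exactly. At a mismatching overlap column the
higher-quality base wins and the merged quality is the column maximum.

## V and J assignment

V assignment aligns the merged read against every Vκ reference in V-sense
via an exact k-mer seed (k = 20, staggered offsets so isolated mismatches
cannot mask a gene) and extends over the full read/reference overlap;
leading and trailing mismatch runs are excluded and identity is
matches/aligned-columns. The published contract is the two thresholds —
minimum 150 aligned V bases and minimum 95% identity — and both behave as
exact step functions (property-tested at 149/150 bases and at 7 vs 8
mismatches in 150 bp). "Read length of 150 bp" is interpreted as aligned V
length, consistent with the treatment of gene pairs identical over their 3′
150 bp. Ties on (identity, aligned length) are broken lexicographically and
flagged ambiguous rather than dropped, because ambiguous pair reads are
later re-divided by reallocation. Alignment is gap-free: the generator and
the chemistry produce substitution-type disagreement only, and indel
support would blur the step-function contract the thresholds define.

gDNA Jκ assignment does not trust the PCR primer found on the read, since
Jκ primers cross-amplify neighbouring products. The exon sequence upstream
of the primer site is compared against all four Jκ exons, excluding the
most Vκ-proximal 1 nt (primary primer set) or 6 nt (alternate, further-
downstream set) because junction formation may have eaten them; the
comparison additionally slides over the allowed junctional-loss shifts so a
trimmed exon still matches in register. The best match (fraction ≥ 0.9 over
≥ 8 informative bases) wins; reads matching no exon are counted as
unassigned-J in QC. RNA reads contain the full exon, which is located
exactly and extended leftwards to resolve junction-side loss.

Productivity is frame-based: a call is productive iff the net junctional
offset — V-side loss plus J-side loss minus non-templated insertion — is
divisible by 3 and no in-frame stop codon occurs in the sequenced region,
scanning the V reading frame through the junction to the end of the Jκ
exon. Calls missing either assignment are `indeterminate`. Because V-side
and J-side junction coordinates are estimated independently, a base that
happens to match both references shifts both estimates coherently and the
net offset is invariant to the ambiguity.

## Deduplication and pair reallocation

The dedup key is the 6N adapter UMI for both chemistries plus the V read
start for gDNA (shear points are random; two reads sharing UMI and start
are one fragment). UMIs are matched exactly — the chemistry uses the 6N as
an identifier, not a barcode to error-correct — and the assigned (gene, Jκ)
is always part of the key so molecules from different genes never collapse,
a conservative choice the original per-gene read handling implies but does
not state. The first read in stable input order is retained; dedup is
idempotent. With random 6N UMIs the residual risk is key collision, whose
expected count follows the birthday bound `m²/2K` per gene × Jκ cell; the
test suite checks observed losses against that estimate.

For the registered 3′-identical pairs, the pooled pair total is reliable
but its split is not. Among pair reads long enough to cover the
discriminating upstream tag, the tag-hit ratio a:b re-divides the pooled
total T as `T·a/(a+b)` and `T·b/(a+b)`. Fractional counts are propagated as
reals so the pair total is conserved exactly; rounding happens only in
reports. A pair with no tag-covering reads is left unadjusted with a
warning. Each member keeps its own Jκ profile; a member with no reads of
its own inherits the pair's pooled profile. The discriminating strings are
user-supplied in the pair registry (the published strings live in
supplementary material), and the registry is verified against the genome on
load: the 3′ 150 bp must be identical, and each tag must occur in exactly
one member.

## Repertoire statistics

Pooled frequencies are summed counts over summed totals across biological
replicates, matching the definition used for the regression response;
per-replicate vectors are available for ratio tests. Active genes are
classified with ≥ 15 reads per million pooled reads for deeply sequenced
pre-B samples, applied to pooled counts, and an absolute ≥ 1 read for
shallow pro-B samples. The threshold is monotone by construction.

The gDNA/RNA divergence filter flags a gene only if the arithmetic mean of
its per-replicate frequency ratios is ≥ 2-fold and every individual
replicate is ≥ 1.5-fold in the same direction; genes lacking reads in any
replicate of either table are excluded, and pseudogenes can be dropped for
functional-only analyses. Swapping the two tables swaps flag directions
exactly. Where a zero frequency must enter a ratio (genotype comparisons),
it is replaced by the frequency equivalent of one read (1/total) and the
ratio is flagged as an underrepresentation; genes at zero in both
repertoires are skipped.

Per-gene Jκ-usage profiles are restricted to genes with ≥ 5 reads in every
replicate, below which a four-way percentage profile is noise.

## Feature windows and models

Each gene gets four non-overlapping windows in its own orientation:
promoter (500 bp upstream of leader-1 start + leader exon + intron,
~665 bp for the synthetic locus geometry), RSS (coding + 500 bp downstream;
800 bp for a 300 bp coding region), and 2.5 kb upstream/downstream flanks.
Window signal is coverage-weighted overlap (value × bp) scaled to a
10-million-tag depth, consumed from plain bedGraph plus a declared
total-tag count — reproducing tag-directory normalisation arithmetically
without an aligner dependency. Signals are linear in coverage and inversely
proportional to declared depth.

The feature matrix is {track × window} columns plus two genetic features
(RIC score, distance to Jκ1). With 29 ChIP + 5 RNA tracks this yields
4·34 + 2 = 138 columns; the published analysis used a slightly reduced set
(132 + 2) without stating which window columns were dropped, so the matrix
computes all windows and accepts a `mask` to reproduce any reduced set.
Pre-B-response analyses use all tracks (both stages); pro-B analyses use
pro-B tracks only.

Models are random forests: 10-fold cross-validation with every gene tested
exactly once, 5,000 trees per fold by default. For classification, the
per-split candidate count is tuned on the training folds only via an
out-of-bag grid {√p/2, √p, 2√p}; regression uses the p/3 default.
Performance is accuracy (fraction correct over all test sets) or RMSE over
all test predictions. Variable importance (mean decrease in Gini index /
node purity) is averaged across the ten training-fold forests — whether the
original analysis averaged over folds or refit on all data is unstated, and
fold-averaging keeps every importance estimate honest with respect to
held-out data. Recursive feature elimination takes the top-20 features by
importance and evaluates cross-validated models over nested VI-ranked
subsets (sizes 20…1), selecting the smallest subset within one standard
error of the best; exhaustive search over all 2²⁰ subsets is what "all
possible combinations" would cost and is deliberately not the default
behaviour, as the nested procedure is what the referenced elimination
routine computes.

## The synthetic-data generator

The generator defines the validation conditions; its defaults are fixed,
not tuned. It emulates: per-gene × per-Jκ rearrangement frequencies
(log-normal gene weights crossed with Jκ usage 0.4/0.2/0.2/0.2, matching
the observed ~40% Jκ1 dominance); junctional trimming with V-side loss
uniform on {0,1,2} so the three reading-frame classes are equiprobable and
the expected non-productive fraction is exactly 2/3; random shear starts
(the 500–1,000 bp sonication range guarantees the fragment spans the
junction and primer, so the amplicon runs from the shear point to the Jκ
primer, and the shear point is uniform over positions leaving ≥ 150 V bp —
every emitted read is assignable, which the end-to-end recovery tests
require); 6N UMIs; geometric PCR re-sampling (`pcr_dup_rate`); Jκ primer
cross-amplification (`cross_prime_rate`); NMD suppression of non-productive
transcripts (`nmd_survival`, RNA only); per-gene promoter strength (RNA
only); and planted log-linear track effects (`log f = a + b·signal +
noise`, realised in the designated track's RSS window with all other
windows and tracks independent noise). V and J references are generated
stop-free in frame, so in-frame junctions are never spuriously
non-productive; premature stops can be injected explicitly
(`stop_injection_rate`). J-side trimming and junctional insertions exist as
parameters (`j_trim_max`, `n_insert_max`) but default to 0: with V-side
trimming alone, frame classes are still equiprobable and in-frame junctions
keep clean codon boundaries, which makes generator truth and caller output
agree exactly rather than up to chance chimeric-codon stops.

Read names encode (molecule id, gene, Jκ, productivity) so oracle tests
can score any stage; the pipeline never parses them. Base qualities are
constant Phred 35 unless errors are injected, decoupling trimming tests
from assignment tests. Identical seeds give byte-identical FASTQ.

What the generator does not emulate — realistic Illumina error profiles,
chimeric reads, allelic exclusion, receptor editing dynamics, genuine
chromatin-track autocorrelation — bounds what passing tests show: they
demonstrate that the pipeline's rules are implemented exactly and that
parameter recovery holds under the stated noise model, not that the rules
are optimal for real sequencer artefacts.

## Validation problem sizes

The test suite exercises: 100,000-junction productivity simulations
(non-productive fraction within 1 percentage point of 67%); a full
100,000-molecule gDNA pipeline run with 30% PCR duplication and 10%
cross-priming (per-gene frequency recovery within 3 binomial SE after pair
reallocation, ≥ 99% cross-priming correction, dedup equal to the
distinct-key count and within the birthday bound of the molecule count);
and planted-effect recovery across 10 seeds with 34 tracks on a 60-gene
locus, where the planted RSS-window feature ranks first in regression
importance and the RFE curve plateaus by subset size 3. The RF validation
runs use 500/200 trees per fold rather than the 5,000-tree analysis
default: importance rankings of a strongly planted effect are insensitive
to tree count, and these sizes are the package's chosen validation scale.

## Known limitations

- The aligner is gap-free by design; indel-bearing reads fall below the
  identity threshold instead of being rescued.
- UMI collisions are not error-corrected; at very deep per-gene coverage
  the birthday bound, not sequencing depth, limits molecule counting.
- The published per-sample read table and GEO coverage tracks are external
  inputs: analyses that depend on them (published active-gene counts,
  divergence-gene lists, real variable-importance rankings) can only be
  reproduced when the user supplies those files.
- Significance testing between groups (t-tests on bar graphs) is out of
  scope; the package reports paired values and leaves inference to the
  user.
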