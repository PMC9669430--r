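---
title: "lncflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lncflow identifies long noncoding RNAs from assembled transcripts, calls
differential expression between two groups, and integrates the
differentially expressed lncRNAs (DELs) with nearby differentially
expressed mRNAs (DEMs). This vignette records the package's models and the
reasoning behind every design choice that was genuinely open.

## Discovery model

**Filtering.** A candidate transcript is removed when (a) its structure is
an exact re-discovery of a known coding transcript, or (b) its spliced
length is below 200 nt, strict. "Exact re-discovery" means identical
chromosome, strand and intron chain for multi-exon models — terminal exon
ends are allowed to differ, since assemblers routinely truncate UTRs — and
exact interval equality for single-exon models, where no junctions exist to
compare. Exact matching is deliberately conservative: a candidate differing
in any junction is treated as novel and retained for scoring. A candidate
on a chromosome absent from the reference is retained with a flag and a
warning rather than dropped, because the more likely cause is a naming
mismatch, which the user should see.

**Coding potential.** Trained coding-potential classifiers are deliberately
not reimplemented. Instead the package uses a transparent two-feature
composite with the same intent: a transcript is *coding* iff its longest
ATG→stop open reading frame (stop included; exhaustive three-frame scan;
ties broken by smallest start) reaches `orf_min = 300` nt, or its Fickett
TESTCODE score reaches `fickett_cut = 0.95` while the ORF covers at least
`cov_min = 0.5` of the transcript. The TESTCODE statistic is computed from
the published position/composition lookup tables and weights; 0.95 is the
classic coding threshold of that scale, and 300 nt (100 codons) is the
conventional ORF cut used in lncRNA cataloguing. All three thresholds are
exposed as arguments, because they are working conventions, not laws.

**Positional classes.** Each retained noncoding transcript receives exactly
one class under a fixed precedence: exonic sense overlap (any exon overlaps
a same-strand coding exon), then antisense (opposite-strand exon overlap),
then intronic (entirely inside one intron of a coding transcript, either
strand), then intergenic. A transcript can satisfy several definitions at
once; a fixed precedence makes the classification total, exclusive and
deterministic. Promoter- and UTR-associated subclasses are not emitted —
they would require TSS/UTR annotations finer than the pipeline's inputs.

## Expression and differential expression

FPKM is computed with library sizes taken as the column sums of the
provided matrix, keeping the pipeline self-contained; per-sample
correlations are Pearson on log2(FPKM + 1), the community default for QC
heatmaps, with the pseudocount avoiding log 0.

The default per-feature test is a **pooled-variance (Student) two-sample
t-test** on log2(FPKM + 1). With three replicates per group — the design
this pipeline targets — the Welch/Satterthwaite correction is markedly
conservative (its measured size at nominal 0.05 is about 0.036 even on
exactly normal data), while the pooled t is exactly sized under the
log-scale normal working model; pooling is appropriate here because both
groups share a single negative-binomial dispersion, so their log-scale
variances are equal under the null. The `nb_wald` alternative (Wald test on
the log ratio of group means, moment-estimated dispersion) exists for
designs without replication. Fold changes are
`log2((mean2 + c)/(mean1 + c))` on the FPKM scale with pseudocount `c = 1`,
bounding the fold change of zero-count features. FDR is Benjamini–Hochberg
(the standard referent where only "FDR" is specified), and calls require
both q < 0.05 and |log2FC| ≥ 1 (fold change 2) by default — the field's
modal thresholds, both configurable. Features with all-zero counts are
flagged and never called.

## Integration and enrichment

**Cis targets.** A gene is a cis target of a lncRNA when their genomic
spans overlap (gap 0) or the minimal boundary-to-boundary distance between
the closed intervals is strictly below 100 kb, strand-agnostic. The
relation (upstream/downstream) is reported in the gene's own orientation.
The distance definition uses whole spans rather than TSS/TES points: the
span-based gap is never larger than any point-based distance, making the
window inclusive under annotation uncertainty.

**Precursor homology.** DELs are scanned against a miRNA-precursor
database with Smith–Waterman local alignment (match +2, mismatch −1, linear
gap −2) — nucleotide-level, since both lncRNAs and precursors are nucleic
acids. A hit requires identity ≥ 0.9 and subject coverage ≥ 0.9, so a
verbatim embedded precursor scores 1.0/1.0 while unrelated sequence cannot
pass. Tie-breaking is deterministic (best cell with the lowest end
coordinates; traceback prefers substitution over a subject gap over a query
gap), so results are reproducible across platforms. The DP core is
implemented in C++ for speed; tests verify it against a memoised-recursion
oracle and against Biostrings scores.

**Networks.** An edge connects a DEL to every DEM whose gene is among its
cis targets; concordance compares call directions only ("same expression
trends"), not magnitudes. Because one gene can pair with several DELs, the
edge count is at least the distinct cis-gene∩DEM count — the structural
property the workflow is expected to exhibit.

**Enrichment.** Over-representation is the upper hypergeometric tail
P(X ≥ k) with the background defaulting to the features tested for
differential expression — the defensible expressed-gene background —
followed by BH adjustment across tested terms. Terms left empty after
intersection with the background are skipped with a notice; `k = 0` terms
are reported with p = 1 (exactly P(X ≥ 0)). Top-k selection sorts by
p-value with lexicographic term-id tie-breaks for determinism.

## The synthetic-data generator

The generator emulates the study conditions end to end: a 3-chromosome,
500-kb-per-chromosome genome carrying 60 three-exon coding genes on
alternating strands; an assembly containing exact known-mRNA re-discoveries
of every gene, five sub-200-nt fragments, three coding contaminants with a
planted 600-nt ORF, and 25 true lncRNAs — 6 each of the exonic-sense,
antisense and intronic classes plus 7 intergenic, of which five are planted
at exact gaps (1, 5, 20, 50 and 99.999 kb) from an anchor gene, one forms a
planted discordant pair, and one sits > 100 kb from every gene. Counts are
negative-binomial (`var = m + αm²`) for two groups of three samples,
mirroring the three-animal two-coat-colour design.

Choices the study leaves open, fixed here once and documented:

* **Dispersion `α = 0.02`** — a generic value for homogeneous cultured-cell
  replicates; property tests that specify other conditions (e.g. 0.05 or
  0.1) set them explicitly.
* **Planted |log2FC| = 3, low-state mean U(200, 600)** — the planted
  effects are meant to be unambiguous at n = 3, so truth-recovery checks
  hold by construction; the drawn mean is the *low* expression state of the
  feature (down-regulated features start at the scaled-up state), keeping
  both states clear of the counting-noise floor. The package's
  recovery-rate property test uses |log2FC| = 2 with dispersion 0.05 — a
  deliberately harder setting — and requires ≥ 90% recovery.
* **Ten high-abundance background genes (mean 20,000)** — real libraries
  concentrate much of their mass in a handful of dominant transcripts;
  without that mass, library-size normalisation in a small feature set is
  visibly distorted by the planted fold changes themselves (a composition
  bias that would shrink every "up" fold change).
* **lncRNA bodies are ATG-free** (motif-scrubbed random sequence), and each
  locus is re-drawn — bounded, under the same seed stream — if its
  assembled transcript would score coding; this keeps planted noncoding
  labels exact rather than merely probable. Overlap-class lncRNAs inherit
  their overlap segment from the host gene, so the re-draw applies to the
  designed remainder.
* **Precursors** are 80-nt random sequences embedded verbatim in the first
  nine differentially expressed lncRNAs (configurable), plus six unembedded
  decoys in the database.

Everything is a pure function of the configuration: the same seed produces
byte-identical GTF/FASTA/TSV files. What the generator does *not* emulate:
splice-isoform complexity (one transcript per locus; in particular, most
planted lncRNAs are single-exon), read-level noise, alignment or assembly
artefacts, GC/length biases, and realistic dispersion heterogeneity across
features. Passing recovery tests therefore demonstrate the pipeline's
logic, not robustness to assembler noise or to borderline coding potential.

## Numerical and degenerate-input conventions

Coordinates are 1-based closed (GTF convention) everywhere. The FPKM
conservation identity is tested to 1e-12 relative tolerance. A sample with
zero total counts is an explicit error naming the sample; a zero-variance
sample yields missing correlations rather than a crash; a degenerate test
row (both groups constant) gets p = 1 when means agree. The full pipeline
fans one global seed out to per-stage derived seeds, so toggling stages
does not shift downstream randomness; re-running a pipeline with the same
configuration reproduces byte-identical outputs, verified by manifest
checksums.

## Problem sizes used by the test-suite

The bundled checks run at desk scale by design: oracle-equivalence suites
use 200+ random instances per primitive (sequences ≤ 300 nt, alignments ≤
50 nt, cis scans over 500 random loci); truth recovery runs on the default
dataset above; null calibration uses 20 seeds × 2,000 features at 3 vs 3,
checking that the per-feature type-I error at p < 0.05 stays within three
Monte-Carlo standard errors of 0.05 and that BH discoveries under the
global null keep the empirical false-discovery proportion at or below the
nominal level.

## Known limitations

The coding-potential composite is a stand-in with the same *intent* as
trained classifiers, not a reconstruction of them; borderline transcripts
(ORF near 300 nt, TESTCODE near 0.95) will disagree with any particular
tool. The nb_wald test uses a moment dispersion estimate without shrinkage
and is anti-conservative at very small means. Cis-target prediction is
purely positional; it does not use expression correlation, and trans
targets are out of scope. The enrichment module assumes the gene-set file
uses the same gene identifiers as the annotation.
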