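---
title: "Methods: pan-genome gene-family evolution analysis with panfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome gene-family evolution analysis with panfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

panfam analyses the evolution of a gene family — the motivating case is the
UDP-glycosyltransferase (UGT) family of the tea plant — across a
multi-genome ("pan-genome") collection. This vignette documents the models
and procedures each stage implements, the parameters that matter and their
defaults, what the synthetic data generator does and does not emulate, and
the design choices made where the methodology was genuinely open.

## Family identification

Candidate genes enter through two filters applied in either order (the
filters commute, which the test suite checks):

* **Domain filter.** A gene is kept when it has at least one domain hit
  (HMMER domtblout-style input) with independent E-value at most `1e-5`.
* **Identity filter.** A kept candidate must show best global-alignment
  identity **strictly greater than 50%** against a set of reference family
  proteins (for UGTs, the *Arabidopsis* set). Identity is computed from a
  Needleman–Wunsch global alignment with BLOSUM62 scores and affine gaps
  (opening 10, extension 0.5); the denominator counts aligned columns
  excluding terminal-gap runs, so length differences at the ends do not
  dilute identity. The filtering literature rarely states these alignment
  parameters; these are conventional values and are exposed as arguments.

Two further annotations are made per protein:

* **PSPG typing.** A protein is *typical* when its best 44-residue window
  scores at least 60% of the maximal attainable score against a
  position-weight model of the Plant Secondary Product Glycosyltransferase
  (PSPG) box; otherwise *atypical*. A default consensus model ships with
  the package (`inst/extdata/pspg_model.tsv`); both the model and the
  cutoff are user-replaceable. Proteins shorter than the motif width are
  atypical by definition (with a warning).
* **Group assignment.** Rather than placing each protein in a maximum-
  likelihood phylogeny, panfam assigns the group label (A–Q) of the
  highest-identity labelled reference, breaking ties toward the
  lexicographically smallest label. Nearest-reference assignment is
  deterministic and testable, and for well-separated reference groups
  agrees with tree placement.

Internally, the many-candidates-versus-one-reference identity computation
uses the aligner's match/mismatch/indel counters rather than materialising
gapped alignment strings; the test suite verifies this fast path equals
the definitional string-based computation.

## Orthogroup occupancy and categories

The backbone is the orthogroup × genome copy-count matrix built from an
OrthoFinder-style `Orthogroups.tsv` restricted to family genes. With
occupancy = number of genomes holding at least one copy and `n` genomes in
total, the category rule is:

| category    | occupancy                      |
|-------------|--------------------------------|
| core        | `n`                            |
| soft-core   | `ceiling(0.9 n)` … `n − 1`     |
| dispensable | 2 … `ceiling(0.9 n) − 1`       |
| private     | 1                              |

With `n = 22` this yields soft-core occupancies 20–21 and dispensable
2–19. A percentage-based reading of the dispensable band ("2%–90%") is
sometimes quoted alongside these counts but is inconsistent with them
(2% of 22 is below one genome); panfam implements the count-based rule,
using `ceiling` for the 90% boundary (0.9 × 22 = 19.8 → 20). A
single-genome collection is degenerate (every orthogroup would be both
core and private); panfam reports core and warns.

Pan/core saturation curves are computed over random genome orderings:
pan(k) is the union and core(k) the intersection of orthogroup sets over
the first k genomes of an ordering. The default is 100 permutations under
a recorded seed; an exact curve over all orderings can be requested by
passing the permutations explicitly. Monotonicity holds per ordering, not
just in the mean, and is tested per ordering.

## Duplication-mode classification

Intra-genome homologous pairs (similarity-table pairs above E ≤ 1e-10 and
identity ≥ 30%, both exposed) are classified by a priority cascade,
mirroring the DupGen_finder convention:

1. **WGD** — the pair is an anchor of an intra-genome collinear block;
2. **TD** (tandem) — same chromosome, gene-rank distance ≤ 1;
3. **PD** (proximal) — same chromosome, rank distance ≤ 10;
4. **TRD** (transposed) — exactly one gene of the pair lies in a collinear
   block against an outgroup genome (the ancestral locus);
5. **DSD** (dispersed) — none of the above.

Ranks are ordinal gene positions per chromosome (sorted by start, ties by
end then id). Collinear blocks come from an internal dynamic-programming
chainer: within a chromosome pair, a block is a chain of anchors with
strictly increasing ranks on one side, strictly monotone ranks (either
orientation) on the other, adjacent gaps ≤ 25 ranks on both sides, and at
least 5 anchors. The longest chain is extracted, removed, and the search
repeated. These thresholds (min block 5, max gap 25, tandem gap 1,
proximal gap 10) follow MCScanX-style practice and are all flags. The
chainer is validated against exhaustive search on anchor sets of up to 12
anchors.

A gene participating in several pairs may carry different modes in
different pairs; per-gene summaries take the highest-priority mode.
Pair counts are over unordered unique pairs.

## Ka/Ks estimation (NG86)

Homologous CDS pairs are aligned protein-first (BLOSUM62 global
alignment), back-translated codon-wise, and codon columns containing a gap
are masked (dropped pairwise, not end-trimmed). The estimator is
Nei–Gojobori (1986):

* Per codon, the synonymous site count S is the fraction of the nine
  single-nucleotide changes that are synonymous (divided by 3, summed over
  positions); N = 3 − S; changes into stop codons count as nonsynonymous.
  Site totals are averaged over the two sequences.
* Observed differences per codon are averaged with equal weight over all
  minimal mutational pathways that avoid stop codons; if every pathway
  passes through a stop, all pathways are used.
* Proportions are corrected with the Jukes–Cantor formula
  d = −(3/4)·ln(1 − 4p/3), undefined for p ≥ 3/4.

The ratio is NA when Ks = 0 or a correction is undefined, with distinct
reason codes (`ks_zero`, `correction_undefined`, `no_columns`). Selection
classes: positive (ratio > 1), purifying (< 1), neutral (= 1), NA
propagated. Per-orthogroup distributions take every unordered cross-genome
pair within an orthogroup (an orthogroup in exactly two genomes with one
gene each yields exactly one value); intra-genome pairs are the
duplication module's business and are skipped here. NG86 was chosen as the
single estimation method because it is deterministic, closed-form and
oracle-checkable against enumeration; maximum-likelihood codon models are
out of scope.

## Structural variants and expression association

VCF records carrying FORMAT `GT:DP` are depth-filtered: a genome's
genotype is retained only when DP ≥ 20 (inclusive), and variants with no
retained carrier are dropped. Typing is by allele length (alt > ref:
insertion; alt < ref: deletion; equal: other). The reference span of a
variant is `[pos, pos + max(ref_len − 1, 0)]`, so an insertion occupies
its single anchor base. A gene's window is its span ± 2 kb (floored at
position 1), and gene-level presence in a genome means at least one
retained overlapping variant is carried by that genome (any non-reference
genotype counts; the input data do not distinguish heterozygote dosage).

Association between presence and expression across genomes is the Pearson
correlation with a two-sided p-value from the t distribution on n − 2
degrees of freedom. For a binary grouping this is the point-biserial
correlation, whose p-value is identical to the equal-variance two-sample
t-test — the package's test suite asserts this identity to 1e-10, which
ties the correlation-based screen to group-comparison plots of the same
data. Significance is α = 0.05 without multiple-testing correction, which
mirrors the screening convention this pipeline reproduces; a
Benjamini–Hochberg adjusted column can be derived from the reported
p-values when a corrected analysis is wanted.

Promoters are the 2000 bases immediately 5′ of the gene start (minus-
strand genes: 3′ of the gene end, reverse-complemented), truncated with a
warning at contig edges, anchored at the gene feature rather than a
transcript. Cis-element comparison counts IUPAC motif occurrences on both
strands with position-level deduplication (a palindromic motif counts once
per site), ranks elements by combined abundance across the two promoter
sets, keeps the top 20, and rolls up growth/hormone/stress categories
when the motif table provides them. A default table of common plant
promoter elements ships with the package; it is a convenience input, not
a curated database.

## Expression: TPM, profiles, dosage

TPM is computed as rate = count/length(kb), TPM = rate/Σrate × 10⁶ per
sample, so every non-degenerate sample column sums to one million (checked
at relative tolerance 1e-6) and per-sample scaling of counts cancels. Gene
length is the union of exon intervals from the GFF3. Replicates are
aggregated by arithmetic mean; heatmap-style exports use log2(TPM + 1).

The dosage analysis correlates per-genome family gene counts with
log2(total family TPM + 1) per tissue — total-then-log, with the
pseudocount handling genomes with zero dosage; the pseudocount is a flag.
The dosage correlation and the SV association use one shared correlation
kernel, so identical inputs give bit-identical statistics.

## The synthetic pan-genome generator

Because the original 22 tea genomes are not redistributable, every stage
is exercised against a generator whose ground truth is known. Defaults
(chosen once as a realistic desk-scale study design; they are the study
conditions, not tuning knobs):

* 10 genomes × 3 chromosomes; 36 orthogroups: 12 core, 4 soft-core
  (occupancy 9), 16 dispensable (occupancy 2–8, copy range 1–2 outside
  the focal genome), 4 private; 120-codon genes (single exon).
* Sequences evolve by a continuous-time codon process: single-nucleotide
  changes at rate 1/3 per unit branch length when synonymous, ω/3 when
  nonsynonymous, and zero into stop codons — a Jukes–Cantor-like per-site
  process with one nonsynonymous scaling knob, the simplest process with
  a controllable dN/dS. Group references (17 labelled groups) sit at
  branch 0.05 above orthogroup ancestors; gene copies at 0.05 + 0.06. Per-
  orthogroup ω is drawn from {0.2, 0.5, 1}: a mostly-purifying family,
  matching the empirical finding that positive selection is the rare
  class, and keeping protein identity within the >50% filter band. (The
  steeper grid {0.2, 1, 2} is used where the estimator itself is
  validated, via `simulate_codon_pair`, which has no identity-filter
  constraint.)
* Typical members carry the exact 44-residue PSPG consensus (protected
  from substitutions — motif conservation); atypical orthogroups have the
  motif region degraded by random codon replacement at rate 0.7, far
  below the PWM cutoff yet identifiable as family members.
* 13 planted duplication events in the focal genome: 5 WGD pairs laid out
  as one parallel collinear block across chromosomes 1 and 2, 2 tandem
  (adjacent ranks), 2 proximal (rank distance 3), 2 transposed and 2
  dispersed. An outgroup genome carries orthologs of a 5-gene window of
  chromosome 1 in conserved order, so exactly the transposed sources are
  outgroup-anchored. Three chromosomes are the minimum layout in which
  the scattered transposed/dispersed copies land on a chromosome pair
  with fewer than 5 anchors and therefore cannot chain into a spurious
  block at the default chaining thresholds.
* Structural variants (default 30, half overlapping gene ± 2 kb windows)
  get carrier subsets of non-reference genomes and per-genome depths with
  a configurable fraction below 20 to exercise the filter. Three
  effect-SVs shift the overlapped orthogroup's expression additively
  (default +300 TPM units) in carriers that survive the depth filter.
  Counts are negative-binomial (dispersion 0.1) around TPM targets, with
  150 background genes per genome so that family TPM is a minor fraction
  of each library and compositional distortion of planted effects stays
  small. Samples cover bud and young leaf for every genome, the remaining
  four tissues and drought/salt young-leaf samples for the focal genome.
  Setting `couple_dosage = FALSE` rescales baselines so per-genome family
  dosage decouples from gene count (a null configuration for the dosage
  correlation).
* Similarity tables are emitted schematically (fixed identity/E-value per
  homolog pair) — they are synthetic stand-ins for BLAST output
  sufficient to drive anchor chaining and pair selection, not simulated
  alignment scores.

Everything is seeded; identical configuration and seed give byte-identical
written bundles. What the generator does **not** emulate: realistic
chromosome-scale sequence composition, transposable elements, intron
structure, read-level noise, orthology-inference errors (the orthogroup
table is true by construction), and alignment-score distributions.
Passing recovery tests therefore demonstrates the correctness of the
downstream logic, not robustness to upstream annotation or clustering
errors in real data.

## Statistical calibration harness

The association test's operating characteristics are measured with
`simulate_sv_association`, which draws presence and negative-binomial
expression per gene directly (the same process the bundle plants, without
sequence scaffolding): type-I error at 1000 genes × 20 genomes stays
within 0.05 + 2·SE under a zero effect, and a +400 shift on one gene at
20 genomes is detected at p < 0.05. Estimator recovery uses 100 replicate
codon pairs of 300 codons at pairwise divergence 0.3 per ω value; the
ω = 1 mean must land within ±0.15 and the grid must be rank-ordered.
These problem sizes keep the complete test suite in the low minutes on a
single core while leaving the statistical margins wide.

## Numerical and degenerate-input conventions

* Percent shares in reports are rounded half-up to one decimal.
* Ties: rank ties break by end then id; chain-DP ties toward the earliest
  anchor and parallel orientation; group-label ties toward the smaller
  label; family naming orders by occupancy, then copies, then id.
* NA is a first-class outcome for Ka/Ks (with reason codes) and for
  associations with constant presence or fewer than three genomes.
* All seeded routines save and restore the caller's RNG state.

## Limitations

Group assignment is nearest-reference, not phylogenetic placement; TRD
detection depends on outgroup collinearity and inherits its failure
modes; the identity filter's >50% rule is applied to full-length global
identity (the alternative, local-hit identity, is not implemented);
family-only expression matrices make family TPM a compositional quantity
unless background genes are present. The paper-scale result (thousands of
genes across 22 genomes) is reproducible in structure but not in numbers
without the original genome data.
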