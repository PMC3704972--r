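---
title: "Methods: a genome-wide CDPK family survey, stage by stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genome-wide CDPK family survey, stage by stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpkfam)
```

## The problem

Calcium-dependent protein kinases (CDPKs) are plant calcium sensors with a
stereotyped four-part architecture: an N-terminal variable region, a Ser/Thr
kinase catalytic domain, an autoinhibitory junction, and a calmodulin-like
domain carrying up to four EF-hand calcium-binding loops. Genome-wide
surveys of this family follow a well-worn recipe: find every candidate by
domain architecture, predict N-terminal acylation, build a
neighbor-joining (NJ) phylogeny and sort members into subfamily groups,
detect duplicated gene pairs and classify them as tandem or segmental,
compare exon–intron structures within groups, and quantify expression by
qRT-PCR (ΔΔCt) and clustering. `cdpkfam` implements that recipe as tested,
reusable functions, and ships a 40-member maize family characteristics
table as a packaged fixture so the desk-scale parts of the survey can be
audited directly.

## Family identification from domain architecture

`scan_kinase_domain()` does not use profile HMMs; it looks for the three
invariant catalytic anchors of a Ser/Thr kinase in order — a VAIK-like
ATP-positioning motif (`[LIVMF]x[LIVMF]K`), the catalytic HRD, and the
Mg-binding DFG — with 10–120 residues between consecutive anchors. The
spacing bounds are generous around real kinase geometry (the VAIK–HRD and
HRD–DFG separations in protein kinases are typically ~60–100 and ~20–30
residues) and exist to reject chance co-occurrence, not to measure domain
extent precisely.

`scan_ef_hands()` matches the canonical 13-residue EF-hand loop with a
PROSITE PS00018-style residue-class pattern, taking greedy leftmost
non-overlapping matches — deterministic, and consistent with the tandem
arrangement of real EF hands. `classify_family_member()` then applies the
architectural definition: a kinase domain N-terminal to 1–4 EF hands.
Kinase-only proteins with zero EF hands (the CRK-like architecture) are
deliberately excluded from the family.

`predict_acylation()` uses a PS00008-style N-myristoylation rule anchored
at the initiator Met: Gly at position 2, position 3 outside
{E,D,R,K,H,P,F,Y,W}, position 6 in {S,T,A,G,C,N}, position 7 ≠ P. The
simpler "Gly-2 only" rule is not sufficient: several family-table entries
begin MG yet are annotated myristoylation-negative, and the full rule is
the standard completion that reproduces all 40 packaged calls (17 positive)
with zero discordance. Palmitoylation is evaluated only among myristoylated
proteins: at least one Cys at positions 3–5 (15 positive in the packaged
table). Protein-level motif coordinates are 1-based inclusive, the R and
Biostrings convention.

## Alignment, distances and the NJ tree

Pairwise global alignment (`global_align()`) is Needleman–Wunsch with
affine gaps, delegated to `Biostrings::pairwiseAlignment` with BLOSUM62,
gap open 10 and gap extension 0.5 — standard desk defaults; the survey
recipe never prints its alignment parameters, so these are package
defaults, not claims. From an alignment, `pairwise_stats()` defines

* coverage = residue–residue columns / length of the longer sequence, and
* identity = matches / residue–residue columns (gap-excluded denominator).

Distances for tree building are p-distances, `1 − identity`
(`p_distance_matrix()`). A Poisson or other correction would also be
defensible; p-distance is the package's fixed choice and only affects
branch lengths, not the additive-case topology guarantees the tests check.

`neighbor_joining()` is the classical Saitou–Nei agglomeration: join the
pair minimising `Q(i,j) = (n−2) d(i,j) − Σ_k d(i,k) − Σ_k d(j,k)`, with
standard branch-length formulas and distance updates. Numerical choices:

* ties in Q are broken by the lexicographically smallest sorted label pair
  (an internal node inherits the smallest leaf label beneath it), which
  makes output independent of input order;
* negative branch-length estimates are clamped to 0, the convention of
  mainstream tree software;
* matrices asymmetric beyond 1e-8 are rejected rather than silently
  symmetrised.

On additive matrices NJ provably recovers the generating topology and
branch lengths; the test suite checks this for random 4- and 5-leaf
additive matrices and checks topological agreement with an independent NJ
implementation (`ape::nj`) on 100 random matrices up to n = 8.

`bootstrap_supports()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and scores each internal bipartition of
the point-estimate tree by the percentage of replicates containing it.
Bipartitions are compared as canonical label sets, so supports are
invariant to leaf input order. Bootstrapping requires aligned rows of equal
length; when sequences are unaligned the pipeline builds the tree without
supports and says so, rather than fabricating a pseudo-alignment.

`assign_groups()` labels each query leaf by the smallest bipartition side
containing it and at least one reference, provided all references on that
side belong to one group; mixed evidence yields `unassigned`. Group labels
come entirely from user-supplied references (e.g. published subfamily
memberships); nothing is hard-coded.

## Duplication detection

`find_duplications()` applies three criteria: alignment coverage of the
longer gene strictly above 0.80, gap-excluded identity strictly above 0.80,
and one event per cluster of tightly linked genes. "Strictly above"
implements a ">80%" rule literally. The identity denominator is the
aligned (gap-excluded) region — the conventional reading when a threshold
is quoted "over the aligned region".

`classify_event()` calls a passing pair tandem when both genes share a
chromosome with at most `tandem_max_intervening` annotated genes between
them (default 5), segmental otherwise. No universal tandem definition
exists; the threshold is an exposed parameter, not a scientific claim.
Tightly linked passing genes are collapsed by union–find, keeping the
single event between the two genomically closest members, so a k-gene
tandem array yields one event rather than choose(k, 2).

## Gene structure

Genomic intervals are stored 0-based half-open internally and converted
exactly once at the GFF3 boundary (GFF is 1-based inclusive); the
conversion is its own inverse and is pinned by tests. Intron phase after
coding segment k is the cumulative CDS length through segment k modulo 3,
computed in transcript orientation, so mirrored minus-strand models give
identical phase strings. CDS totals not divisible by 3 produce a warning
flag rather than an error — real annotations contain such models. The
packaged characteristics table treats printed CDS lengths as including the
stop codon; the relation `aa = cds/3 − 1` holds on all 40 rows, which is
the consistency sweep the tests enforce.

## Expression

`ddct_fold_change()` implements the plain ΔΔCt method: arithmetic mean of
replicate Ct values first (the conventional reading; the method's sources
do not specify mean-vs-median), then
`ΔCt(s) = Ct(target,s) − Ct(reference,s)`,
`ΔΔCt = ΔCt(sample) − ΔCt(calibrator)`, fold `= 2^(−ΔΔCt)` with PCR
efficiency fixed at 2 and no efficiency correction. The calibrator is
always an explicit argument — stress-course experiments differ in whether
the calibrator is t = 0 or a tissue-matched control, so defaulting would
hide a scientific decision. `log2(fold)` equals `−ΔΔCt` to machine
precision, and fold is strictly decreasing in the target's sample Ct; both
are asserted property-style in the tests.

`hierarchical_cluster()` is agglomerative clustering with Euclidean
distance and complete linkage (`stats::hclust`), the combination used by
the classic Cluster 3.0 workflow this emulates. Complete-linkage merge
heights are monotone non-decreasing and the function asserts this on every
run. Clustering operates on unscaled values; any display scaling is left
to the caller.

## The synthetic-data generator

No public accession provides this survey's inputs, so `synthetic_data`
makes the study's *structure* reproducible: the default
`generator_config()` plants a 40-member family in groups of 17/11/9/3
across 10 chromosomes, with 10 segmental and 4 tandem duplicate pairs at
target identity 0.90 and 60 background genes — the shape of the original
dataset at desk scale.

Design decisions that keep ground truth exact:

* Filler and substitution alphabets exclude Asp and Glu. The EF-hand
  pattern needs D at loop position 1 and D/E at position 12, and the
  HRD/DFG anchors need D, so motifs exist exactly where planted; family
  membership ground truth is deterministic, not probabilistic.
* Duplicates substitute a fixed, rounded number of free (non-motif) sites,
  so realized alignment identity equals the target almost exactly; motif
  positions are never mutated, keeping the copy a family member.
* Within-group divergence defaults to 0.20 (pairwise within-group identity
  ≈ 0.70, typical of kinase subfamilies and safely separated from the 0.80
  duplication threshold); between-group divergence 0.45 puts between-group
  identity near 0.40. The group-recovery experiment instead uses
  within-group divergence 0.11 (identity ≈ 0.80), the separation at which
  that experiment is defined.
* All randomness flows from the single config seed through scoped RNG
  (`withr::with_seed`); a fixed seed yields byte-identical output files.

`generate_expression()` plants block-structured expression (per-block
condition means plus Gaussian noise, clamped at 0) and builds the Ct table
from the true folds — reference gene at constant Ct 20, target Ct offset by
`−log2(fold)` plus 0.05-cycle noise, three replicates — so ΔΔCt recovers
the configured folds exactly in expectation (mean relative error ~2–5% at
the default noise).

What the generator does *not* emulate: real codon usage, intron sequence
content, insertion/deletion divergence between family members (members are
substitution-only from a common ancestor, hence natively aligned — which is
also why the bootstrap stage can treat them as an alignment), microarray
probe effects, and biological correlation structure in expression noise.
Passing tests therefore demonstrate algorithmic correctness against known
truth, not performance on real genomes, where domain-architecture scans
face degenerate motifs and fragmented annotations.

## Problem sizes and runtime envelope

The shipped tests and acceptance script run the full pipeline at the
study's native scale (100 genes, 40 family members, ~360-residue proteins),
100 random NJ oracle comparisons at n ≤ 8, 10–50 bootstrap replicates in
smoke tests, and 12-gene expression simulations — sizes chosen so the whole
suite completes in about a minute while still exercising every stage
end-to-end. `bootstrap_supports()` scales as O(replicates × n² × L) and
handles the conventional 1,000 replicates on a 40-taxon family in a few
minutes.

## Known limitations

* The kinase triad scan is a motif heuristic; highly degenerate kinases
  (or pseudokinases retaining the anchors) can be missed or falsely called.
  A profile-HMM stage is out of scope by design.
* EF-hand counts from the PS00018-style pattern can disagree with curated
  counts for degenerate loops; published per-protein EF counts are carried
  in the fixture but not re-derivable from octapeptides alone.
* p-distance underestimates multiple substitutions at high divergence;
  group assignment is robust to this at the separations tested, but branch
  lengths should not be read as evolutionary time.
* Duplication calling is pairwise; it does not infer synteny blocks or date
  events (no Ka/Ks).
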