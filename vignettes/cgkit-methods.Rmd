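---
title: "Models and methods in cgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

cgkit covers five connected analyses in the life cycle of a genome build:
synteny inference, map-guided scaffold ordering, k-mer genome surveys,
concordance QC, and pedigree/CNV diversity. This vignette explains each model,
its assumptions and tunable parameters, the numerical choices made where the
design was open, and what the synthetic-data generators do and do not emulate.

## Gene ranks as the synteny coordinate system

All synteny arithmetic runs in *rank space*: each gene's 0-based ordinal along
its chromosome, sorted by start coordinate (`geneIndex()`). Distances measured
in genes rather than base pairs make the chaining and duplicate-removal
windows insensitive to intergenic distance variation, which differs by orders
of magnitude between gene-dense and repeat-rich regions.

## Synteny: C-score, duplicate removal, chaining

A raw all-against-all hit table is noisy in two specific ways: E-values depend
on database size (so no fixed E-value cutoff transfers between comparisons),
and repeats produce large families of moderate-scoring hits. The C-score
addresses the first: each hit's score is divided by the best score achieved by
either of its genes in any hit, so values are comparable across searches and
the genome-wide best hit always scores exactly 1. The cutoff (default 0.7,
**inclusive** so that the documented default is meaningful at equality)
balances keeping orthologs against admitting shared paralogs.

Proximal duplicates address the second: for each gene, partner genes lying on
the same chromosome are clustered by single linkage at rank distance ≤ 10, and
only the best-scoring pair survives; ties break to the smaller partner rank so
output is deterministic.

Chaining is single-linkage clustering in rank space: two anchor pairs are
linked when they share a chromosome pair and their rank gaps are at most 20
genes on **both** genomes (the stricter of the two possible readings of a
distance cutoff; applying it to either genome alone would chain through
perpendicular block crossings). Clusters below 4 pairs are discarded. We chose
transitive single linkage over dynamic-programming collinear chaining because
it is the simplest rule consistent with a pure distance cutoff; a strict
collinearity post-filter (`strict = TRUE`) drops pairs off the block's
monotone trend — the longest monotone subsequence in the block's orientation —
for users who want collinear-only blocks. Block orientation is the sign of the
Spearman correlation of the pairs' ranks, "+" on ties or zero, again for
determinism. In self-comparisons the trivial self-diagonal (gene paired with
itself) is removed before chaining.

Synteny depth of a gene is the number of blocks whose rank span covers it; the
modal depth ratio string is "modal depth over genes of genome A : modal depth
over genes of genome B". Two descendants of a shared triplication show 3:3;
an unduplicated pair shows 1:1.

## Scaffold ordering and orientation

Ordering and orienting scaffolds against maps is NP-hard (it embeds the
traveling salesman problem), so a genetic algorithm searches the space of
(permutation, orientation-bitstring) pairs per chromosome. The objective had
to be chosen — the method literature names the GA and TSP framing without
printing a formula — and we optimize exactly the statistic the concordance
report displays:

fitness = Σ over maps m, linkage groups g of weight(m) · ρ(m,g) · n_markers(m,g)

with ρ the Spearman correlation between marker physical positions (cumulative
scaffold offsets plus 100 bp inter-scaffold gaps; flipped scaffolds use
length − position) and map locations. Weighting by marker count keeps one
noisy 3-marker map from overruling a 300-marker map of equal weight. A
constant vector has no rank order, so its ρ is defined as 0; single-marker
groups count as trivially concordant (ρ = 1, n = 1).

GA defaults: population 100, up to 500 generations with early stop after 50
stagnant generations, crossover probability 0.7 (order crossover on the
permutation, uniform crossover on per-scaffold orientation bits), mutation 0.2
(position swap; independent single-bit flip), elitism 1, seed 0. All are
function arguments. The search is seeded and fully reproducible; elitism
guarantees the reported fitness never falls below the best individual seen.
At ≤ 6 scaffolds the optimum is verified in tests against exhaustive
enumeration of all permutations × orientations. Reversing a whole chromosome
and flipping every orientation negates every ρ, so solutions are only defined
up to global reversal — acceptance checks accept either.

Scaffolds are assigned to the linkage group where they carry the greatest
weight-summed marker count (ties to the natural-sort-first group); multiple
maps that disagree are arbitrated by this weighted majority, a documented
choice since no arbitration rule is standard. Scaffolds with one marker are
anchored but unoriented (reported as such, orientation "+"); scaffolds with no
markers are left unplaced. AGP output uses fixed 100 bp spacer gaps
(component type U, gap type "map"); gap-length estimation is out of scope.

## K-mer spectrum models

The observed spectrum K_j — the number of distinct k-mers seen j times in the
reads — is modeled as a mixture over genome copy numbers c:

K_j = Σ_c G_c · NegativeBinomial(j; size = c·n, prob = p)

The size parameter scales with c so that the copy-c component peaks at c-fold
coverage, the only reading under which repeats produce the familiar
harmonically spaced shoulders. G_c (the number of distinct k-mers with genome
copy number c), n and p are estimated by alternating minimization of the L2
distance between observed and model spectra: given (n, p) the G_c have a
non-negative least squares solution (computed exactly); given G, (n, p) move
by L-BFGS-B on (log n, logit p). Updates are kept only when they improve the
objective, so the L2 trace is non-increasing; iteration stops at relative
improvement < 1e-6 or 200 rounds. Initialization puts the copy-1 mean at the
smoothed spectrum's main peak with variance twice the mean (p = 0.5,
n = peak). Multiplicities below the first local minimum of the smoothed
spectrum are treated as sequencing errors and excluded — standard practice;
with no descending error tail the whole spectrum is used. Genome size is
Σ c·G_c, repeat fraction Σ_{c≥2} c·G_c over genome size. The heterozygosity
proxy G_1/(G_1 + 2·G_2) and the ploidy call (modal c weighted by c·G_c, capped
at 4) are labelled heuristics: no explicit heterozygosity model is fitted.

The three-class alternative splits the multiplicity axis at the error valley
and classifies k-mers as haploid (below 0.75 × the main peak), diploid (up to
1.5 × the peak) or repeat (beyond), with genome size = total k-mer count above
the valley divided by peak coverage. It is cheaper and more robust but leaks
distribution tails across the fixed class boundaries and is ill-suited to
polyploids.

## Concordance QC

Linkage disequilibrium r² between marker pairs is computed from haplotype
frequencies, r² = (p_ab − p_a·p_b)² / (p_a(1−p_a)·p_b(1−p_b)), clipped to
[0, 1] for numerical safety; monomorphic markers are NaN and excluded from
display. Phased haplotype input uses direct counts with pairwise-complete
handling of missing calls; unphased dosages use the composite estimator
(squared Pearson correlation of dosages) — same formula, composite
frequencies, and the input mode is explicit. Along a correct assembly r² is
diagonal-dominant; the mean r² of every chromosome-pair block is reported so a
translocated segment shows up as a hot off-diagonal block. For display the
marker set is optionally thinned to 1000; statistics always use the full
matrix.

Hi-C contacts are accumulated into symmetric fixed-size bins (default 500 kb).
The per-chromosome diagonality score — the fraction of intra-chromosome
contact weight within ±1 bin of the diagonal — drops when a segment is
inverted or misjoined relative to the contact evidence.

## Pedigree gene-dropping

Founders (individuals with no recorded parents) are assumed non-inbred and
unrelated, each carrying `ploidy` unique allele labels. Each child draws
ploidy/2 alleles uniformly **with replacement** from each parent's ploidy
alleles — at ploidy 2 this is exactly Mendelian transmission; odd ploidies are
rejected because "half from each parent" is undefined. Over N replicates
(default 10,000), F is the mean fraction of the target's alleles appearing
more than once in a replicate (identical by descent), and founder parentage is
the mean fraction of target alleles tracing to that founder. Of the two
readings of "alleles appearing more than once" (per-allele multiplicity vs
per-replicate events) the per-allele-multiplicity reading is implemented; it
matches the classic recursive kinship computation on selfing (1/2), full-sib
(1/4), half-sib (1/8), backcross (1/4) and first-cousin (1/16) pedigrees
within Monte-Carlo error, which the tests verify against an independent
recursive oracle. PED rows with exactly one named parent are rejected (the
model assumes two progenitors or none); parents referenced but never declared
become implicit founders with a warning, since real PED files truncate
ancestry.

CNV landscapes normalize each variety's binned depth by its genome-wide
median — robust against large CNVs, though a CNV spanning close to half the
genome would still shift the median — and flag bins below 0.6 (loss) or above
1.4 (gain), both configurable.

## Synthetic data: what it does and does not emulate

The generators are pure functions of (parameters, seed) and write every format
the toolkit reads, with planted truth serialized alongside. The synteny
scenario evolves one ancestor into two genomes: shared polyploidy (each
ancestral chromosome in `copies` homologous copies in both genomes),
inversions, translocations and gene loss in genome B; ortholog hits score
~500, cross-copy homeologs 0.85 of that (so they survive the 0.7 C-score
cutoff, as real homeologs from a shared polyploidy should), decoys below
0.65 × the best (so the cutoff removes them). Map scenarios cut chromosomes
into 50–150 kb scaffolds, shuffle and flip them, and emit maps with cM
monotone in the true coordinate (≈4 cM/Mb); marker error swaps neighboring cM
values. Spectra are model spectra with optional Poisson bin noise and a
decaying error tail; depth tracks use Poisson noise around planted multiples.

None of this emulates real alignment score distributions, recombination-rate
variation along chromosomes, genotyping error structure, or GC/mappability
bias in depth. Passing tests therefore demonstrate that the algorithms
recover what their models assume — planted signals under the models' own
noise — not that those models capture every artifact of real data.

## Problem sizes and numerical notes

Tests and the acceptance script run at desk scale, chosen so the full suite
completes in well under a minute of compute: 60–200 ancestral genes, 4–8
scaffolds (exhaustive OO verification at 5), spectra of ~10⁶ k-mers at
coverage 20–60×, 50–60 markers × 200–500 haplotypes, N = 10,000 gene-dropping
replicates. Published genome-pair figures (e.g. grape–peach synteny counts)
require external genome downloads and aligner runs and are deliberately not
reproduced; the planted-triplication scenario recovering 3:3 is the
desk-scale surrogate. Spearman ρ values within 1e-10 of ±1 are snapped to the
exact endpoint so concordance reports print 1 rather than 1 − 2e-16;
C-score, r² and fitness computations otherwise use plain double arithmetic.
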