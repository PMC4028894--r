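---
title: "Methods: sex-specific RAD-Seq linkage maps in outbred full-sib families"
author: "radlinkmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific RAD-Seq linkage maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radlinkmap)
```

## The mapping problem

The package targets the two-family, two-parent full-sib design used for the
Atlantic salmon SalMap reference families: two unrelated pairs of wild
parents, each with ~46 offspring, genotyped at thousands of biallelic
RAD-Seq SNPs. Because the cross is outbred, no marker is informative in
every parent. A marker heterozygous in the dam and homozygous in the sire
(`aaXab`, writing the sire's genotype first) segregates only through female
meioses; `abXaa` only through male meioses; `abXab` through both, but with
heterozygous offspring uninformative about which parent transmitted which
allele. Maps are therefore built separately per parent — a pseudo-testcross —
and male and female maps share no markers, which shapes everything
downstream: recombination-rate comparisons must go through map lengths and
marker distributions, not matched marker pairs.

## Transmitted states and the multipoint model

For a focal heterozygous parent, each offspring genotype is reduced to which
parental allele was transmitted (0 = a, 1 = b, `NA` = missing or
uninformative). When the other parent is also heterozygous only homozygous
offspring reveal the transmitted allele; heterozygotes are recorded missing.
The textbook form of this reduction assumes a homozygous other parent; we
deliberately extend it to the both-heterozygous case because without it
`abXab` markers could contribute no two-point evidence at all,
and the anchor markers (multi-allelic microsatellites in the real study,
emulated here as markers segregating in all parents) could not bridge
linkage groups across sexes. Map *ordering* still uses the sex-specific
markers only.

Along the true marker order, one parent's transmitted states form a
two-state Markov chain: the state flips across interval $k$ with
recombination probability $r_k$, with no interference (the Haldane model,
matching the mapping function used for distances). Observed states are
noiseless, so for each meiosis the likelihood factorises over *gaps* between
consecutive observed markers; a gap spanning intervals $s..e$ mismatches
with probability $\tfrac12\!\left(1 - \prod_{k=s}^{e}(1 - 2r_k)\right)$.
The per-interval $r_k$ are maximised by EM on these gap records; with
complete data one EM step lands exactly on $r_k = R_k/N$ and the
log-likelihood equals the sum of per-interval binomial terms plus the
$\log_{10}\tfrac12$ prior for each meiosis's first transmitted allele — the
closed form the unit tests check against. Each reported likelihood is the
profile likelihood over the interval fractions, which is how linkage-mapping
programs in this tradition score candidate orders.

## Two-point estimation and grouping

For a pair of markers scored in the same parent, with $N$ jointly observed
meioses and $R$ mismatches under the better phase ($R \le N/2$),
$\hat r = R/N$ and
$\mathrm{LOD} = (N-R)\log_{10} 2(1-\hat r) + R\log_{10} 2\hat r$, the
$\log_{10}$ likelihood ratio against free recombination. The estimate is
invariant to relabelling either marker's alleles (phase symmetry); the
chosen phase is reported. LODs for the same pair from different parents add,
as their meioses are independent.

Grouping is anchor-seeded: every linkage group starts from at least one
marker of known group, and unassigned markers join a group when their best
LOD to any member reaches the current threshold for exactly one group,
repeating to closure before the threshold descends. The published procedure
names only the endpoints of the schedule (40 down to 4); we default to
$\{40, 20, 10, 6, 4\}$, exposed as configuration. Markers exceeding a
threshold for two or more groups are flagged conflicting and never
force-assigned; lowering the final threshold can only add assignments, never
remove them (a property test).

## Ordering, ripple, trimming

`orderMarkers()` orders the `nInit = 5` markers with most non-missing states
exhaustively (likelihood is reversal-symmetric, so permutations are
evaluated modulo reversal), then inserts the remaining markers one at a time
at their maximum-likelihood position. Two refinements of the insertion
heuristic proved necessary and are the package's own design choices. First,
the insertion *sequence* is linkage-guided — always the unplaced marker with
the strongest two-point LOD to the markers already placed — so the growing
order stays contiguous instead of attaching distant markers to arbitrary
ends. Second, a final 2-opt segment-reversal polish repairs mis-oriented
blocks: the five seed markers can lie far apart, their relative order is
then estimated from near-unlinked pairs, and every later placement
conditions on that seed, a failure mode that neither insertion nor a
window-limited ripple can undo. In 40-offspring probes the polish converts
rare catastrophic orderings (Kendall tau ≈ 0.3) into correct ones while
leaving good orders untouched.

A marker whose best position beats the runner-up by less than `thres = 4`
log10 units is placed at the best position but flagged ambiguous — reported,
never dropped. `rippleOrder()` slides a window (default 7) along the order,
scores all window permutations by the full multipoint likelihood, adopts
strictly better permutations, and flags markers that move in any
alternative within 4 log10 units; we adopt "accept strictly better, flag
within-4" since the published description does not say whether within-LOD
alternatives are accepted. Positions accumulate Haldane distances
$d = -50\ln(1-2r)$, to 0.01 cM internally and one decimal in rendered maps.
Ties between orders break toward the lexicographically smaller order, and a
built map is returned in its lexicographically smaller orientation, making
runs deterministic.

Genotyping errors masquerade as double recombinants and drift to map ends;
terminal markers whose gap exceeds 30 cM (male) / 20 cM (female) are removed
repeatedly from both ends and positions re-zeroed. Internal gaps are never
touched.

## Sex differences

Map-length ratios are reported as 1:x to one decimal; a male map whose
markers all cluster at 0 cM has no defined ratio and is excluded from
overall sums. For marker clustering, the shorter parental map is split into
5 cM intervals using the convention floor(L/5)+1 — chosen to reproduce the
worked example in which an 85 cM map yields 18 intervals, where plain L/5
would give 17; whether the published 85 was rounded from a longer map cannot
be determined, so the convention is recorded as ours. A map too short for
more than five such intervals is split into exactly five equal ones. The
longer map is split into the same number of equal intervals; markers on an
interior edge count toward the higher interval. The five most populated
intervals per map are averaged by rank across groups and families per sex.
No significance testing is attached — the comparison is descriptive, as in
the source tradition.

## Comparative genomics

Hit tables are plain BLAST-tabular data frames. Role-specific E-value cuts
(1e-30 RAD loci, 1e-80 PE contigs against genome contigs; 1e-5 against
genes) are applied; gene hits keep only the two most significant per query
(E-value ascending, bitscore descending, target id — a deterministic top-2),
and queries aligning to more than two genome contigs are dropped entirely as
likely repeats. Genome contigs inherit the set of linkage groups of the
markers hitting them; sets of size ≥ 2 are homeology records, whose counts
partition the multi-group contigs (an invariant test). Gene association is
two-stage — a SNP's own flanking contig, or a genome contig on the SNP's own
linkage group — with stage 2 a superset of stage 1. Synteny assignment
requires a dominant outgroup group with at least twice the deduplicated
RAD-locus count of every other, in every parent with any counts (parents
with none are vacuously consistent); an exact two-way tie in which both
groups dominate all the rest assigns both. The comparative stages count a
marker for a parent when it is assigned to a group and heterozygous in that
parent, since gene-carrying markers segregating in all parents sit on no
single sex-specific map.

## The synthetic-data generator

`simulateStudy()` is first-class, tested code, and its defaults are the
study conditions: 2 families × 46 offspring, 29 linkage groups × 275 markers
(~8,000 SNPs), female group length 97 cM and male 75 cM (matching the
published overall lengths of ~2,800 and ~2,200 cM), segregation-type
probabilities giving roughly the published counts of sex-specific markers,
parent read depth 30× versus offspring 8×, calls gated at 6 reads, 17% PSV
markers (the published ratio of PSV removals to discovered SNPs), a 0.5%
genotyping error rate and 4 anchors per group (116 anchors over 29 groups in
the study).

Mechanisms, in order: parental genotypes from per-family segregation types
with random phases; offspring via simulated meioses — crossover counts
Poisson(L/100), female positions uniform, male positions from the mixture
$\tfrac12 B(1, 1+b) + \tfrac12 B(1+b, 1)$ scaled to the group, a simple
symmetric U-shaped density that reduces to uniform at $b = 0$ (the
literature establishes telomere-biased male crossovers but quantifies no
density, so the concentration $b$, default 5, is a free parameter, not an
estimate); PSV markers overwrite calls with heterozygotes at rate 0.85,
chosen to sit detectably above the 0.70 filter threshold; errors replace
calls uniformly at random; depths are Poisson around a per-individual
log-normal mean (sdlog 0.5), reproducing the spread of call rate with
coverage, and sub-threshold depths become no-calls — which also yields the
parental-call rule's missing pattern naturally. Alignment tables place each
marker's flanking contig on its true genome contig (three markers per
contig), add partner-group hits to a configured fraction of each homeologous
pair's contigs, and allocate gene hits on the all-parent-informative markers
so that each group's designated outgroup group dominates ≥ 2:1 — or ties
exactly for designated ambiguous groups.

What the generator does *not* emulate: read-level data, restriction-site
sequence content, locus dropout from polymorphic cut sites, depth
correlation along chromosomes, segregation distortion, or genotyping error
that correlates with depth. Passing tests therefore show the analysis
correct under Mendelian transmission with MCAR-by-depth missingness — not
robustness to every artefact of real RAD data.

## Numerical choices, problem sizes, limitations

EM on the gap records converges to 1e-7 (200 iterations cap) for reported
maps; order search uses 2e-4/60, since only likelihood differences well
above these scales decide placements. Intervals spanned by no meiosis get
$r = 0.5$ (no information) and are capped at 0.4999 when rendered as
distances, leaving them to the terminal trimmer. Degenerate inputs are
defined rather than special-cased: zero-length maps put all markers in
interval 1; duplicate markers sit at 0 cM adjacent to their twin with input
order preserved; fully unlinked marker sets are ordered but flagged
ambiguous throughout.

The validation suite runs at sizes a single CPU handles comfortably while
keeping the estimators in their intended regime: order recovery uses
30-marker, 100 cM groups with 40 offspring and 10% missingness over 50
replicates; grouping uses 4 groups × 50 markers with two 40-offspring
families (segregation types restricted to informative ones there, since a
marker uninformative in both families carries no linkage information and no
method could assign it); the clustering contrast uses 20 simulated genomes.
The ripple's factorial window cost (7! per window position) confines the
default window to small groups; the pipeline exposes it but the bundled
analyses rely on the insertion-plus-polish search, which attains the same
recovery in a fraction of the time.

Known limitations: no interference models (Kosambi), no joint sex-averaged
maps, no integration of external anchor positions into the output maps, and
homeology/synteny conclusions inherit whatever fragmentation the reference
contigs have — a chimeric contig would fabricate a homeology here exactly as
it would in the real analysis.
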