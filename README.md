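# radlinkmap

Sex-specific SNP linkage maps from RAD-Seq genotypes in outbred full-sib
families, modelled on the Atlantic salmon (*Salmo salar*) SalMap reference
families (Br5/Br6). The package is aimed at geneticists building linkage maps
from genotyping-by-sequencing data in species without dense genotyping
arrays — in particular salmonids, where a recent whole-genome duplication
leaves paralogous sequence variants (PSVs) masquerading as SNPs and where
males and females recombine very differently.

## What it computes

**Quality control.** A fixed cascade mirroring standard RAD-Seq practice:
SNPs missing in more than half the individuals are removed; individuals
genotyped at fewer than 25% of SNPs are removed; SNPs with heterozygosity
above 70% across all families are removed as putative PSVs; SNPs with two or
more Mendelian errors are discarded and single errors are masked; individuals
with more than 200 Mendelian errors are removed. Every step is recorded in an
auditable `FilterLedger` whose row-to-row conservation is enforced by the
class validity.

**Two-point linkage and grouping.** In an outbred full-sib cross each
marker is informative only through the parent(s) in which it is heterozygous
(segregation types written sire-first: `aaXab` female-segregating, `abXaa`
male-segregating, `abXab` both). Offspring genotypes are reduced to
transmitted-haplotype indicators per parent; for a marker pair with N
jointly scored meioses and R mismatches under the better phase,

    r̂ = R / N,    LOD = (N − R)·log10(2(1 − r̂)) + R·log10(2·r̂)

with the r̂ = 0 limit N·log10 2. Markers join linkage groups seeded by
anchor markers of known group, at a stepwise LOD schedule descending from 40
to 4; markers exceeding a threshold for two groups are flagged conflicting
rather than force-assigned.

**Ordering and map distances.** Along the true order, one parent's
transmitted states form a two-state Markov chain that switches with each
interval's recombination probability (no interference). The multipoint
likelihood sums out missing states exactly — because observations are
noiseless the likelihood factorises over gaps between consecutive observed
markers, with composite recombination fraction
(1 − Π(1 − 2rₖ))/2 — and per-interval rₖ are estimated by EM. Orders are
searched by exhaustively permuting the five most informative markers,
inserting the remaining markers at their maximum-likelihood positions
(taking at each step the marker most strongly linked to those already
placed), and repairing mis-oriented blocks with a segment-reversal polish; a
sliding-window ripple (`rippleOrder`, window 7) verifies the order.
Distances accumulate through the Haldane map function d = −50·ln(1 − 2r).
Terminal markers separated from their neighbour by more than 30 cM (male) or
20 cM (female) are trimmed as likely genotyping artefacts.

**Heterochiasmy.** Female:male recombination is compared through map-length
ratios (reported as 1:x to one decimal) and through marker-clustering
interval profiles: the shorter parental map is split into 5 cM intervals
(floor(L/5)+1 of them; at least five), the longer map into the same number
of equal intervals, and the five most populated intervals per map are
averaged across groups and families per sex. Telomere-biased male crossovers
concentrate male markers into one or two dense intervals.

**Comparative genomics.** BLAST-tabular hit tables are filtered by role
(E ≤ 1e-30 RAD loci, 1e-80 PE contigs, 1e-5 genes; top two gene hits per
query; queries hitting more than two genome contigs dropped). Reference
genome contigs inherit the linkage groups of the markers aligning to them;
contigs assigned to two or more groups mark homeologies from the salmonid
genome duplication. Mapped SNPs are gene-associated in two stages (own
flanking contig, or a same-group genome contig), and each linkage group is
assigned to the outgroup (stickleback-like) linkage group holding at least
twice the gene-associated loci of any other, consistently in every parent,
with exact two-way ties assigning both.

**Synthetic studies.** `simConfig()`/`simulateStudy()` generate full
studies with known truth: Mendelian transmission through simulated meioses
(Poisson crossover counts; female placement uniform, male placement from a
U-shaped Beta mixture whose concentration at the telomeres is tunable),
coverage-gated genotype calls (per-individual log-normal mean depth, Poisson
per-genotype depth), PSV contamination, injected genotyping errors, anchor
markers, and alignment tables with configured homeolog blocks and synteny
design — including designated ambiguous (tied) groups.

## Worked example

```r
library(radlinkmap)
cfg <- pipelineConfig(
  sim = simConfig(n_families = 2, n_offspring = 40, n_groups = 3,
                  markers_per_group = 40,
                  group_length_female = 90, group_length_male = 70,
                  psv_fraction = 0.15, genotype_error_rate = 0.003,
                  mean_depth_offspring = 12, n_anchors_per_group = 4,
                  homeolog_block_fraction = 0.3,
                  ambiguous_outgroup_groups = 3L, seed = 7),
  lodSchedule = c(20, 10, 6, 4), seed = 7)
res <- runPipeline(cfg, "demo_out")
#> [simulate] families=2 offspring=40 groups=3 markers/group=40
#> [qc] 120 -> 107 SNPs, 84 -> 84 individuals
#> [group] 97/107 markers assigned (0 conflicts)
#> [order] 12 parental maps built
#> [sexdiff] 10 interval profiles
#> [compgen] 42 contigs assigned, 1 homeologous sets, 3 synteny assignments
```

The QC ledger shows 12 of the 18 planted PSVs surviving to the
heterozygosity step being removed there and one further SNP lost to
Mendelian errors:

```r
res$qc$ledger
#> FilterLedger: 5 step(s); start 120 SNPs, 84 individuals
#>                           step snps_eliminated snps_remaining ...
#>         missing_genotypes_snps               0            120
#>  missing_genotypes_individuals               0            120
#>     excess_heterozygosity_psvs              12            108
#>          mendelian_errors_snps               1            107
#>   mendelian_errors_individuals               0            107
```

One of the twelve per-parent maps, and the homeology/synteny recovery —
groups 1 and 2 were simulated as a homeologous pair sharing 30% of their
contigs, and group 3 was designed as an exact tie between two outgroup
groups:

```r
res$maps[["fam1.mother.1"]]
#> ParentalMap: fam1_mother (female), group 1: 8 markers, 101.7 cM (8 ambiguous)

res$compgen$homeologies$records[, 1:3]
#>   groups n_groups shared_contigs
#> 1    1/2        2              4

res$compgen$synteny
#>   group outgroup   status
#> 1     1      OG1 assigned
#> 2     2      OG2 assigned
#> 3     3  OG3/OG4 assigned
```

The interval profiles reproduce the characteristic clustering contrast: with
only 40 meioses per parent the per-map percentages are noisy, but averaged
over many simulated genomes male maps concentrate markedly more markers into
their top interval than female maps (see the sex-difference tests and the
methods vignette).

With the published whole-study map lengths, the same ratio operation used
per group gives the familiar overall values:

```r
mapLengthRatio(2807, 2170)   # family Br5 -> 1.3
mapLengthRatio(2358, 1426)   # family Br6 -> 1.7
splitIntervals(85, 5)$n      # shorter 85 cM map -> 18 intervals of 5 cM
```

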