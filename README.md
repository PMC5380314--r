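# recessmap

Homozygosity mapping and variant prioritisation for recessive disease
loci in livestock populations with a founder effect.

## The problem

A fully penetrant recessive defect spreading from one heavily used sire
leaves a characteristic footprint: every affected animal is homozygous
for the same ancestral chromosome segment, inherited identical by
descent through both parents. `recessmap` implements the desk side of
the standard study design built on that footprint, for geneticists
working on Mendelian defects in cattle and similar managed populations:

* **Homozygosity mapping** from SNP-array genotypes of an
  affected/control cohort. For each marker the scan reports the
  affected genotype counts (n1, n2, n3), the control allele-1 frequency
  f1 — with exact extremes reported as 0.1 and 0.9 so the null
  likelihood stays finite — and a likelihood-ratio statistic

  lrt = 2 [ sup_p ℓ(p) − ℓ(f1) ],  ℓ(p) = n1 log p² + n2 log 2p(1−p) + n3 log (1−p)²,

  the trinomial Hardy–Weinberg genotype likelihood of the affected
  counts, maximised over the allele frequency against a null pinned at
  the control frequency. Maximal runs of markers at which all affected
  share a homozygous allele become ranked `HomozygosityInterval`s, each
  carrying both its marker span and the search envelope up to the
  flanking discordant markers.
* **A five-step prioritisation cascade** over whole-genome variant
  calls from a sequenced quartet (two affected, one obligate carrier,
  one wild type): mapped interval → perfect recessive genotype pattern
  → not in the known-variant list → not on the genotyping chip →
  nonsynonymous coding consequence (standard genetic code, strand-aware
  CDS projection, compact HGVS labels), with candidates ranked by
  unknown-ID status and cross-species conservation.
* **An indirect carrier test**: the disease-associated marker haplotype
  derived from the mapped interval, classifying animals from unphased
  chip calls as affected-genotype / carrier / non-carrier / ambiguous.
* **A gene-drop simulator** reproducing the study's structure — a
  carrier founder sire, Haldane recombination, chip-like founder
  haplotypes, a cohort of 12 affected + 123 controls on a 3,000-marker
  100 Mb chromosome, and a quartet variant table with an implanted
  causal missense variant — so the whole pipeline is testable with no
  external data.

File formats go through the field's standard containers: PED/MAP chip
genotypes, VCF 4.2 variant calls (read via `vcfR`), GFF3 gene models
(via `rtracklayer`) and FASTA genomes (via `Biostrings`).

## Worked example

Simulate a complete study, map the locus, and prioritise variants:

```r
library(recessmap)

sim <- simulateStudy(simConfig(seed = 42))
gm  <- chipGenotypes(simPhased(sim), simMap(sim),
                     idsWithStatus(cohortPhenotypes(sim),
                                   c("affected", "control")))
stats <- scanMarkers(gm, cohortPhenotypes(sim))
top   <- detectIntervals(stats, min_markers = 5)[[1]]
top
#> HomozygosityInterval 7:81,111,060-85,798,491 (4.69 Mb), 155 markers, score 3752.8
#>   search envelope: 81,058,434-85,991,001

report <- runCascade(quartetVariants(sim), top, quartetPhenotypes(sim),
                     known_ids = NULL, chip_positions = chipSites(sim),
                     models = geneModels(sim))
report
#> Filtering steps  No. polymorphisms
#> Polymorphisms in the homozygous interval 113
#> Polymorphisms homozygous in affected cattle, but absent in WT    22
#> Polymorphisms absent from known-variant database 17
#> Polymorphisms absent from SNP chip   15
#> Non-synonymous coding polymorphisms  1

cascadeCandidates(report)[, c("pos", "ref", "alt", "gene",
                              "consequence", "hgvs_c", "hgvs_p")]
#>       pos ref alt    gene consequence   hgvs_c  hgvs_p
#> 1 8.5e+07   C   T GENE000    missense c.376C>T p.R126C

simTruth(sim)$causal_pos
#> [1] 8.5e+07
```

The top-ranked homozygous interval (all 12 affected homozygous for the
shared haplotype over 155 consecutive markers) contains the true causal
position; the cascade narrows 113 in-interval variants down to a single
candidate — the implanted causal missense variant, recovered with its
correct coding-position (c.376C>T) and protein (p.R126C) labels. A
carrier test follows directly:

```r
sig <- deriveSignature(gm, top, affectedIds(cohortPhenotypes(sim)))
sig
#> HaplotypeSignature: 155 markers on 7 (81,111,060-85,798,491), min_informative = 124
calls <- classifyAnimals(gm, sig)
```

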