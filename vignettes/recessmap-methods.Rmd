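---
title: "Mapping a founder recessive defect: methods and design choices"
author: "recessmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a founder recessive defect: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recessmap)
```

# The problem

Fully penetrant recessive defects surface in livestock populations when a
heavily used sire carries a new deleterious allele: artificial insemination
lets one bull contribute a large fraction of a breed, and a few generations
later carrier-by-carrier matings produce clusters of affected calves. All
affected animals then carry two copies of one ancestral chromosome segment
— they are autozygous (identical by descent) around the causal variant.
`recessmap` implements the complete desk side of such a study:

1. **Homozygosity mapping** from SNP-array genotypes of affected and
   control animals, localising the shared homozygous interval;
2. a **variant prioritisation cascade** over whole-genome variant calls
   from a small sequenced family (two affected, one obligate carrier, one
   wild type), with coding-consequence annotation;
3. design of a **haplotype-based indirect carrier test** for selection
   against the defect;
4. a **gene-drop simulator** that reproduces the statistical structure of
   the study design so that every stage can be validated without any
   external data.

# Homozygosity mapping

## Per-marker statistics

For each chip marker the scan records, over the affected cohort, the
counts `n1` (homozygous for map allele 1), `n2` (heterozygous) and `n3`
(homozygous for allele 2); missing genotypes are excluded from all three.
The control cohort provides the allele-1 frequency

$$f_1 = \frac{2\,\mathrm{hom}_1 + \mathrm{het}}{2\,n_{\text{typed}}}.$$

An exact frequency of 0 is *reported* as 0.1 and an exact 1 as 0.9; all
intermediate values pass through unchanged. The substitution matters for
the statistic below: at $f_1 \in \{0, 1\}$ the null log-likelihood of any
discordant genotype is $-\infty$, so a single affected homozygote at a
fixed marker would otherwise dominate the scan. Only the exact extremes
are touched, and only at the reporting/statistic boundary — raw
frequencies are never altered elsewhere.

## The likelihood-ratio statistic

The affected genotype counts are modelled as a trinomial draw from
Hardy–Weinberg proportions at an unknown allele-1 frequency $p$:

$$\ell(p) = n_1 \log p^2 + n_2 \log 2p(1-p) + n_3 \log (1-p)^2 ,$$

with zero-count terms contributing 0 regardless of $p$. The statistic is

$$\mathrm{lrt} = 2\left[\sup_{p \in [0,1]} \ell(p) - \ell(f_1)\right],$$

i.e. the alternative maximises the same likelihood (the supremum is
attained at the affected-sample frequency $\hat p = (2n_1+n_2)/2n$, also
on the boundary) while the null pins $p$ at the clamped control
frequency. The statistic is nonnegative, zero exactly when
$\hat p = f_1$, and for a fully homozygous affected cohort
($n_2 = n_3 = 0$) reduces to $2 n_1 \log (1/f_1^2)$, strictly decreasing
in $f_1$ — markers where the shared allele is rare in controls score
highest. The implementation uses the closed-form maximiser; the test
suite checks it against an independent grid-search maximisation (step
$10^{-4}$) to $10^{-6}$ on 1,000 random configurations. The statistic is
used descriptively to rank and localise, not as a calibrated
significance test; no genome-wide multiple-testing correction is
attempted.

Markers with fewer than 90% of affected animals typed, or with no typed
control, are dropped from the scan (and hence from interval detection)
with a warning. Controls are only required to be unaffected — carriers
among them are expected and handled, since the statistic makes no
carrier-free assumption.

## Interval detection and boundary conventions

A qualifying marker is one at which every typed affected animal is
homozygous *and* all affected share the same allele (`n2 = 0` and one of
`n1`/`n3` zero, at least one typed). Intervals are maximal runs of at
least `min_markers` consecutive qualifying markers (default 5, guarding
against single-marker artifacts; the threshold is a package choice).
Runs are ranked by score — the sum of member LRT values — with ties
broken by marker count, then leftmost position.

Two spans are reported per interval:

* the **marker span** (`start_bp`–`end_bp`): the outermost qualifying
  markers, a conservative lower bound on the shared segment;
* the **search envelope** (`searchRegion()`): extending to just inside
  the flanking discordant markers. The true recombination breakpoints
  that delimit the shared segment are unobserved and lie somewhere in
  the gap between the last concordant and the first discordant marker,
  so any variant search over the mapped region must use the envelope —
  with a marker spacing of tens of kilobases, a causal variant can
  otherwise sit just outside the innermost marker and be discarded at
  the first cascade step. `filterRegion()` therefore filters on the
  envelope; when an interval carries no flank information (e.g. a
  hand-constructed one) the envelope falls back to the marker span.

# The prioritisation cascade

`runCascade()` applies five ordered filters to the quartet variant
table, recording the count after each:

1. **interval** — position inside the mapped interval's search envelope;
2. **genotype_pattern** — perfect genotype/phenotype correspondence:
   affected homozygous for the alternate allele, wild type homozygous
   reference, carrier heterozygous. The check is role-driven: designs
   without a sequenced carrier or wild type degrade gracefully. By
   default a missing genotype in a required animal removes the record
   (`allow_missing = TRUE` relaxes this per animal);
3. **not_in_known_ids** — the record's identifier is not in the known
   variant list. The list is an explicit input (or "any assigned ID"
   when none is supplied), keeping the pipeline hermetic — there are no
   live database queries;
4. **not_on_chip** — the position is not a genotyping-array site.
   Matching is positional only, not allele-aware;
5. **nonsynonymous** — consequence annotation classifies the record as
   missense, nonsense or stop-lost. Splice-region effects are *not*
   modelled; indels and other unsupported records are classified
   "other" and never survive this step.

Steps 3 and 4 are independent set subtractions: swapping them changes
the intermediate counts but never the surviving set (both facts are
asserted in the tests). Final candidates are ranked unknown-ID first,
then by a cross-species conservation score when one is supplied — the
fraction of non-gap sequences in a protein alignment column carrying the
majority residue, ties resolved toward the reference sequence.

## Consequence annotation

Annotation projects a genomic SNV into transcript coordinates
(strand-aware; on the minus strand the coding base is the complement and
coding positions count from the transcript 5' end), retrieves the codon
from the model's stored CDS and applies the standard genetic code
(vertebrate nuclear table; the mitochondrial code is out of scope for a
nuclear gene). Positions inside a gene span but outside CDS exons are
intronic; positions in no model are intergenic; when models overlap, the
first containing transcript wins (models are expected to be
non-overlapping). If the supplied reference allele disagrees with the
model CDS base a warning is emitted and the model sequence is trusted.
HGVS output is deliberately minimal (`c.376C>T`, `p.R126C` style); no
full HGVS grammar is attempted. A small helper, `inFrameIndelAa()`,
performs the length arithmetic of in-frame complex indels (e.g. a 15 bp
insertion with a 3 bp deletion across two codons yields a six-residue
replacement segment).

# The indirect carrier test

`deriveSignature()` turns the mapped interval into a marker panel: the
risk allele at each signature marker is the interval's shared allele.
Classification of a new animal uses unphased chip genotypes only — no
statistical phasing — because affected animals are homozygous by design,
making the risk haplotype directly readable, and a diagnostic lab works
from plain chip calls. Over the non-missing signature markers:

* homozygous-risk everywhere → `affected_genotype`;
* no non-risk homozygote and at least one heterozygote → `carrier`;
* a non-risk homozygote anywhere → `non_carrier` (one such marker
  excludes an intact risk haplotype);
* fewer than `min_informative` non-missing markers (default 80% of the
  panel) → `ambiguous`.

The test is *indirect*: an animal carrying the marker haplotype without
the causal allele (a recombinant), or a non-carrier whose two haplotypes
jointly cover the risk alleles at every marker, is misclassified by
construction. The test suite asserts this boundary explicitly — on
noise-free simulated animals every discordant call is traceable to such
a haplotype, and all other animals classify perfectly. This limitation
is why such tests are eventually replaced by a direct mutation assay.
Genotyping error can be injected through `applyGenotypingError()`; the
error process is coupled across error rates at a fixed seed (perturbed
calls at a smaller rate are a subset of those at a larger one), so
degradation is monotone and testable.

# The gene-drop simulator

## Pedigree and transmission

`buildPedigree()` grows a discrete-generation population: generation-0
founders, a configurable number of unrelated immigrant founders entering
each later generation, each dam producing a Poisson number of offspring
per generation, and one generation-0 sire designated as the carrier
founder. That sire is sampled as the sire of each mating with
probability `founder_sire_usage_fraction` in every generation
(artificial insemination keeps a popular bull in service for years) and
takes no other matings, so his share equals the configured fraction.
Affected individuals (two causal copies; penetrance is fixed at 1 with
no phenocopies) do not reproduce.

Transmission follows a Haldane map: crossover counts per transmitted
gamete are Poisson with mean `recomb_rate × chromosome length` (1 cM/Mb
over 100 Mb = 1 Morgan by default), breakpoints uniform, no
interference, sex-averaged. The crossover mosaics of every gamete are
sampled *during pedigree construction* and stored; the causal genotype
of each individual follows from the mosaic at the causal position. Any
locus set can later be projected through the recorded mosaics
(`geneDrop()`, variant emission), which guarantees that breeding
decisions conditioned on the causal genotype stay consistent with
inheritance, and that the causal allele always travels with the
founder's surrounding haplotype except where crossovers occurred. One
master seed is split into named substreams (map, pedigree, founder
haplotypes, cohort, genes, variants, error) so stages re-run
independently and byte-identically.

## Founder haplotypes and variants

Chip-marker allele-1 frequencies are drawn from Beta(2, 2) —
mid-frequency, chip-like SNPs — and founder haplotypes are sampled with
a first-order Markov adjacency copy (probability 0.3) that induces
background linkage disequilibrium; this keeps chance homozygosity runs
present but short of the genuine identical-by-descent signal. Background
variant frequencies are drawn from Beta(1, 3) (rare-skewed, like
sequencing variants). A configured fraction of background variants is
placed inside CDS exons with alternate alleles engineered, via the
genetic code, to hit a configured nonsynonymous fraction; each
background variant is independently tagged with a dbSNP-like identifier
and as a chip site. The causal gene is a single-exon 1,260 bp CDS
(420 codons) positioned so that the causal variant falls on coding
position 376 — the first base of an arginine codon at codon 126, where
the implanted C>T creates the missense change the cascade must recover.
Only sites with at least one alternate call in the sequenced quartet are
emitted, like a real joint call set.

## Default parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `n_generations` | 8 | depth of the drop; the founder sits 3–8 generations above the cases |
| `n_founder_males` / `n_founder_females` | 8 / 60 | generation-0 breeding nucleus |
| `founders_per_generation` | 6 | immigrant founders per generation (keeps diversity) |
| `litter_mean` | 2.2 | offspring per dam per generation (Poisson); mild growth |
| `founder_sire_usage_fraction` | 0.25 | see below |
| `chrom_length` / `n_chip_markers` | 100 Mb / 3,000 | one chromosome at 50K-chip marker density, scaled down |
| `recomb_rate` | 1 cM/Mb | standard mammalian sex-averaged rate |
| `allele_freq_beta` | (2, 2) | chip SNP frequency spectrum |
| `ld_copy_prob` | 0.3 | background LD between adjacent markers |
| `causal_pos` | 85 Mb | towards the distal chromosome end |
| `n_background_variants` | 5,000 | quartet variant table size |
| `known_id_probability` | 0.4 | fraction of background variants with database IDs |
| `chip_overlap_probability` | 0.3 | fraction of background variants that are array sites |
| `fraction_coding` / `fraction_nonsynonymous` | 0.05 / 0.4 | coding share of background variants; nonsynonymous share of those |
| `genotyping_error` | 0 | per-call error, off by default |
| `n_affected` / `n_controls` | 12 / 123 | the study cohort sizes |

A real founder sire of this kind contributed about 6% of his breed — a
breed of tens of thousands of animals. At the simulator's desk scale
(≈1,500–2,000 animals) a 6% sire cannot produce a twelve-calf affected
cohort at all; the usage fraction is scaled up to 0.25 so that the
*expected number of affected animals* matches the study design at this
population size. This is a deliberate, fixed scaling choice, not a free
dial. The true breed demography (effective size, generation interval) is
not reported for such populations; the remaining defaults are
plausibility choices and labelled as such.

## What the simulator does and does not emulate

It reproduces the features the pipeline's statistics rest on: a single
founder origin of the causal allele, identity-by-descent sharing that
shrinks with recombination history, chip-like allele frequencies with
mild LD, a Mendelian quartet with the diagnostic genotype pattern, and
database/chip tagging of background variants. It does **not** emulate
coalescent founder-haplotype structure, selection against carriers,
genotyping error beyond a single per-call rate (default 0), phenocopies
or incomplete penetrance, multi-chromosome genomes, or realistic
gene/intron architecture. Passing tests therefore demonstrate that the
algorithms are correct under the stated model — they do not certify
performance on real 50K data, where map errors, clustered markers and
population structure add noise the model omits.

# Numerical and degenerate-input conventions

* Frequency clamping applies only at exactly 0 and exactly 1.
* `lrt` is floored at 0 to absorb floating-point residue around the
  null; `f1` outside (0, 1) is a domain error — clamping must happen
  upstream.
* A marker with no typed control is skipped with a warning; a scan
  without affected (or without controls) is a configuration error.
* Interval ranking ties: score, then marker count, then leftmost
  position. Conservation ties: the reference sequence's residue.
* Classification precedence: the informativeness check precedes all
  genotype rules; a non-risk homozygote dominates carrier evidence.
* Empty variant tables, empty interval lists and zero-candidate
  cascades are valid results, not errors.

# Validation problem sizes

The shipped test suite validates the pipeline at the scaled study
design: 100 independent replicates for interval recovery (top-ranked
interval's search envelope must contain the causal position in at least
95), 100 quartet variant tables for the cascade contract (counts
nonincreasing, equal to brute-force recounts, causal variant always
among the final candidates), ten seeds for Mendelian consistency, and
one default-scale study for carrier-test soundness and I/O round trips.
These sizes are the package's chosen validation budget; all expected
values come from independent oracles (grid search, exhaustive window
enumeration, plain recounts, the genetic code) computed alongside.

# Known limitations

* The likelihood-ratio statistic's exact form in the original in-house
  mapping software is not published; the trinomial form here is chosen
  because it uses exactly the scan's columns (`n1`, `n2`, `n3`, `f1`)
  and explains the extreme-frequency substitution. Absolute statistic
  values should not be compared across implementations.
* Splice-site and regulatory consequences are not annotated; a causal
  variant of those classes would be filtered out at the last cascade
  step.
* The carrier test is haplotype-based and inherits the indirect-test
  blind spots demonstrated in its tests.
* Chip-site exclusion is positional; a new allele at a known array
  position would be (correctly, per the design's intent) discarded.
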