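# Prioritisation cascade, consequence annotation and conservation score.

toyInterval <- function(start = 1000, end = 2000, chrom = "7") {
  new("HomozygosityInterval", chrom = chrom, start_bp = start,
      end_bp = end, marker_ids = c("M1", "M2"),
      shared_allele = c(1L, 1L), score = 10)
}

test_that("region filtering keeps inclusive boundaries", {
  vt <- toyVariantTable(pos = c(999, 1000, 1500, 2000, 2001),
                        geno = rep(c(2, 2, 1, 0), 5))
  out <- filterRegion(vt, toyInterval())
  expect_equal(variantInfo(out)$pos, c(1000, 1500, 2000))
  other <- toyVariantTable(pos = 1500, geno = c(2, 2, 1, 0), chrom = "8")
  expect_equal(nVariants(filterRegion(other, toyInterval())), 0L)
})

test_that("genotype-pattern filtering enforces the recessive model", {
  roles <- quartetRoles()
  keep <- toyVariantTable(pos = 100, geno = c(2, 2, 1, 0))
  expect_equal(nVariants(filterGenotypePattern(keep, roles)), 1L)
  het_aff <- toyVariantTable(pos = 100, geno = c(2, 1, 1, 0))
  expect_equal(nVariants(filterGenotypePattern(het_aff, roles)), 0L)
  hom_car <- toyVariantTable(pos = 100, geno = c(2, 2, 2, 0))
  expect_equal(nVariants(filterGenotypePattern(hom_car, roles)), 0L)
  # missing-genotype policy on a required animal
  miss_car <- toyVariantTable(pos = 100, geno = c(2, 2, NA, 0))
  expect_equal(nVariants(filterGenotypePattern(miss_car, roles)), 0L)
  expect_equal(nVariants(filterGenotypePattern(miss_car, roles,
                                               allow_missing = TRUE)), 1L)
  # degraded designs without carrier/WT still run
  aff_only <- PhenotypeTable(c("A1", "A2"), "affected")
  expect_equal(nVariants(filterGenotypePattern(keep, aff_only)), 1L)
  no_aff <- PhenotypeTable(c("CAR", "WT"), c("carrier", "wild_type"))
  expect_error(filterGenotypePattern(keep, no_aff),
               "configuration error")
})

test_that("known-ID and chip sub-steps record separate counts and commute
           on the final set", {
  vt <- toyVariantTable(pos = c(100, 200, 300, 400),
                        geno = rep(c(2, 2, 1, 0), 4),
                        id = c("rs123", NA, NA, "rs999"),
                        chip = c(TRUE, TRUE, FALSE, FALSE))
  chip_pos <- data.frame(chrom = "7", pos = c(100, 200, 400))
  out <- filterKnown(vt, known_ids = c("rs123", "rs999"),
                     chip_positions = chip_pos)
  expect_equal(out$n_after_known, 2L)      # rs123, rs999 removed
  expect_equal(out$n_after_chip, 1L)       # pos 200 removed
  expect_equal(variantInfo(out$variants)$pos, 300)
  # known_ids = NULL treats any assigned identifier as known
  out2 <- filterKnown(vt, known_ids = NULL, chip_positions = chip_pos)
  expect_equal(out2$n_after_known, 2L)
  # swapping the two sub-steps changes the intermediate count but not the
  # surviving set
  key <- paste(variantInfo(vt)$chrom, variantInfo(vt)$pos)
  on_chip <- key %in% paste(chip_pos$chrom, chip_pos$pos)
  v1 <- vt@variants[!on_chip, , drop = FALSE]
  n_chip_first <- nrow(v1)
  swapped <- v1[is.na(v1$id), , drop = FALSE]
  expect_false(n_chip_first == out$n_after_known)
  expect_equal(swapped$pos, variantInfo(out$variants)$pos)
})

test_that("annotation reproduces the worked missense examples", {
  m <- fixtureTranscript(codon_index = 126, codon = "CGC")
  pos376 <- m@exon_starts + 375
  cons <- annotateConsequence(list(chrom = "7", pos = pos376, ref = "C",
                                   alt = "T"), list(m))
  expect_equal(cons@cds_pos, 376L)
  expect_equal(cons@codon_index, 126L)
  expect_equal(cons@codon_offset, 0L)
  expect_equal(cons@consequence_class, "missense")
  expect_equal(c(cons@ref_aa, cons@alt_aa), c("R", "C"))
  expect_equal(cons@hgvs_c, "c.376C>T")
  expect_equal(cons@hgvs_p, "p.R126C")

  # AAA with an A>G at codon offset 1 gives AGA: K -> R
  m2 <- fixtureTranscript(codon_index = 10, codon = "AAA", n_codons = 20)
  posK <- m2@exon_starts + (3 * 10 - 2) + 1 - 1   # offset 1 in codon 10
  cons2 <- annotateConsequence(list(chrom = "7", pos = posK, ref = "A",
                                    alt = "G"), list(m2))
  expect_equal(cons2@codon_offset, 1L)
  expect_equal(cons2@consequence_class, "missense")
  expect_equal(c(cons2@ref_aa, cons2@alt_aa), c("K", "R"))
})

test_that("annotation classifies positions outside CDS and rejects
           indels", {
  m <- GeneModel("G1", "G1.t1", "7", "+", c(1001, 2001), c(1090, 2090),
                 paste(rep("ACGTGA", 30), collapse = ""))
  intronic <- annotateConsequence(list(chrom = "7", pos = 1500, ref = "A",
                                       alt = "C"), list(m))
  expect_equal(intronic@consequence_class, "intronic")
  expect_equal(intronic@gene, "G1")
  intergenic <- annotateConsequence(list(chrom = "7", pos = 5000,
                                         ref = "A", alt = "C"), list(m))
  expect_equal(intergenic@consequence_class, "intergenic")
  expect_error(annotateConsequence(list(chrom = "7", pos = 1001,
                                        ref = "AC", alt = "A"), list(m)),
               "unsupported-variant")
})

test_that("annotating the minus-strand representation gives the identical
           consequence", {
  cds <- "ATGCGCAAGTGGTAA"
  plus <- GeneModel("GP", "GP.t1", "7", "+", 201, 215, cds)
  minus <- GeneModel("GM", "GM.t1", "7", "-", 201, 215, cds)
  # coding position 4 (codon 2, CGC): genomic 204 on plus; on minus the
  # transcript runs right-to-left so the same coding base sits at
  # 215 - 3 = 212 and is complemented
  cp <- annotateConsequence(list(chrom = "7", pos = 204, ref = "C",
                                 alt = "T"), list(plus))
  cm <- annotateConsequence(list(chrom = "7", pos = 212, ref = "G",
                                 alt = "A"), list(minus))
  for (slot in c("consequence_class", "cds_pos", "codon_index",
                 "codon_offset", "ref_aa", "alt_aa", "hgvs_c", "hgvs_p"))
    expect_identical(methods::slot(cm, slot), methods::slot(cp, slot),
                     info = slot)
  expect_equal(cp@hgvs_p, "p.R2C")
})

test_that("classification agrees with the genetic code for every codon
           and every single-base change", {
  codons <- names(Biostrings::GENETIC_CODE)
  cds <- paste(codons, collapse = "")
  m <- GeneModel("ALL", "ALL.t1", "7", "+", 1, 192, cds)
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(codons)) {
    codon <- codons[k]
    ref_aa <- Biostrings::GENETIC_CODE[[codon]]
    for (off in 0:2) {
      pos <- 3 * (k - 1) + off + 1
      ref <- substr(codon, off + 1, off + 1)
      for (alt in setdiff(bases, ref)) {
        alt_codon <- codon
        substr(alt_codon, off + 1, off + 1) <- alt
        alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
        want <- if (ref_aa == alt_aa) "synonymous"
        else if (alt_aa == "*") "nonsense"
        else if (ref_aa == "*") "stop_lost"
        else "missense"
        got <- annotateConsequence(list(chrom = "7", pos = pos, ref = ref,
                                        alt = alt), list(m))
        if (got@consequence_class != want)
          fail(sprintf("codon %s offset %d alt %s: got %s, want %s",
                       codon, off, alt, got@consequence_class, want))
      }
    }
  }
  succeed()
})

test_that("in-frame indel arithmetic counts replacement residues", {
  # a 15 bp insertion with a 3 bp deletion across two codons -> 6 residues
  expect_equal(inFrameIndelAa(6, 15, 3), 6L)
  expect_equal(inFrameIndelAa(3, 0, 3), 0L)
  expect_error(inFrameIndelAa(6, 4, 3), "frameshifting")
  expect_error(inFrameIndelAa(5, 3, 3), "codon-aligned")
})

test_that("conservation score counts the majority residue among non-gap
           rows", {
  expect_equal(conservationScore(rep("AKA", 6), 2), 1.0)
  # 19 of 53 sequences share the majority residue
  aln <- c(rep("T", 19), rep("S", 15), rep("A", 10), rep("G", 9))
  expect_equal(conservationScore(aln, 1), 19 / 53, tolerance = 1e-12)
  # four distinct residues: tie broken toward the reference sequence
  expect_equal(conservationScore(c("K", "R", "T", "S"), 1), 0.25)
  expect_error(conservationScore(c("-", "-"), 1), "all-gap")
  # gapped rows are excluded from the denominator
  expect_equal(conservationScore(c("A", "A", "-", "C"), 1), 2 / 3,
               tolerance = 1e-12)
})

test_that("the cascade report renders the classic two-column layout", {
  rep_ <- new("CascadeReport",
              steps = data.frame(
                step = c("interval", "genotype_pattern",
                         "not_in_known_ids", "not_on_chip",
                         "nonsynonymous"),
                n_remaining = c(9025, 1594, 973, 678, 2),
                stringsAsFactors = FALSE),
              candidates = data.frame())
  lines <- formatCascadeReport(rep_)
  expect_length(lines, 6L)
  expect_equal(lines[1], "Filtering steps\tNo. polymorphisms")
  counts <- as.integer(sub(".*\t", "", lines[-1]))
  expect_equal(counts, c(9025, 1594, 973, 678, 2))
  expect_match(lines[2], "homozygous interval")
  expect_match(lines[6], "Non-synonymous coding")
})

test_that("cascade counts equal a brute-force recount and keep the causal
           variant on simulator output", {
  sim <- smallSim()
  vt <- quartetVariants(sim)
  top <- topInterval(sim)
  roles <- quartetPhenotypes(sim)
  chip <- chipSites(sim)
  models <- geneModels(sim)
  rep_ <- runCascade(vt, top, roles, known_ids = NULL,
                     chip_positions = chip, models = models)
  steps <- cascadeSteps(rep_)
  expect_identical(steps$step, c("interval", "genotype_pattern",
                                 "not_in_known_ids", "not_on_chip",
                                 "nonsynonymous"))
  expect_true(all(diff(steps$n_remaining) <= 0))
  expect_equal(steps$n_remaining,
               bruteCascadeCounts(vt, top, roles, chip, models))
  cand <- cascadeCandidates(rep_)
  expect_true(simTruth(sim)$causal_pos %in% cand$pos)
  expect_gte(nrow(cand), 1L)
  # region-filter survivor count equals a linear-scan oracle
  v <- variantInfo(vt)
  expect_equal(nVariants(filterRegion(vt, top)),
               sum(v$chrom == top@chrom & v$pos >= top@start_bp &
                     v$pos <= top@end_bp))
})

test_that("candidates rank unknown-ID first, then by conservation", {
  vt <- toyVariantTable(pos = c(100, 200, 300),
                        geno = rep(c(2, 2, 1, 0), 3),
                        ref = "C", alt = "T",
                        id = c("rs7", NA, NA))
  m <- list(
    GeneModel("GA", "GA.t1", "7", "+", 99, 110, "ACGCGCAAGTGG"),
    GeneModel("GB", "GB.t1", "7", "+", 199, 210, "ACGCGCAAGTGG"),
    GeneModel("GC", "GC.t1", "7", "+", 299, 310, "ACGCGCAAGTGG"))
  iv <- toyInterval(start = 1, end = 1000)
  cons <- c("7:100:C:T" = 0.2, "7:200:C:T" = 0.4, "7:300:C:T" = 0.9)
  rep_ <- runCascade(vt, iv, quartetRoles(), known_ids = character(0),
                     chip_positions = NULL, models = m,
                     conservation = cons)
  cand <- cascadeCandidates(rep_)
  expect_equal(cand$pos, c(300, 200, 100))
})
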