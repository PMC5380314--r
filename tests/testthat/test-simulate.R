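# Gene-drop simulator: pedigree structure, transmission, cohort selection
# and variant emission.

test_that("pedigree construction is deterministic and founder-anchored", {
  cfg <- smallConfig(seed = 7)
  p1 <- buildPedigree(cfg)
  p2 <- buildPedigree(cfg)
  expect_identical(p1@individuals, p2@individuals)
  expect_identical(p1@hap_causal, p2@hap_causal)

  ind <- p1@individuals
  founder <- attr(p1, "founder_id")
  # every causal allele descends from the single carrier founder: each
  # affected has the founder among its ancestors on both parental paths
  aff <- ind$id[ind$causal_genotype == 2]
  expect_gt(length(aff), 0)
  for (a in aff) {
    sire <- ind$sire[match(a, ind$id)]
    dam <- ind$dam[match(a, ind$id)]
    expect_true(founder %in%
                  c(sire, findCommonAncestors(p1, sire)))
    expect_true(founder %in%
                  c(dam, findCommonAncestors(p1, dam)))
  }
  # and the founder is a common ancestor of all affected jointly
  expect_true(founder %in% findCommonAncestors(p1, aff))
})

test_that("common-ancestor queries follow strict-ancestor semantics", {
  ind <- data.frame(id = c("S", "D", "C", "X"),
                    sire = c(NA, NA, "S", NA),
                    dam = c(NA, NA, "D", NA),
                    sex = c("M", "F", "F", "M"),
                    generation = c(0L, 0L, 1L, 0L),
                    causal_genotype = c(0, 0, 0, 0),
                    stringsAsFactors = FALSE)
  ped <- new("Pedigree", individuals = ind,
             gametes = vector("list", 4),
             hap_causal = matrix(FALSE, 4, 2), chrom_length = 1e6)
  expect_setequal(findCommonAncestors(ped, "C"), c("S", "D"))
  expect_length(findCommonAncestors(ped, c("S", "X")), 0)
  # a query member ancestral to all others is returned
  expect_setequal(findCommonAncestors(ped, c("S", "C")), "S")
  expect_error(findCommonAncestors(ped, "NOPE"), "lookup error")
})

test_that("a founder sire with zero usage transmits nothing", {
  cfg <- smallConfig(seed = 3, founder_sire_usage_fraction = 0)
  ped <- buildPedigree(cfg)
  ind <- ped@individuals
  expect_equal(sum(ind$causal_genotype > 0), 1L)  # the founder himself
  expect_equal(ind$id[ind$causal_genotype == 1], attr(ped, "founder_id"))
})

test_that("zero recombination copies a parental haplotype verbatim", {
  cfg <- smallConfig(seed = 5, recomb_rate = 0, n_chip_markers = 120L)
  sim <- simulateStudy(cfg, include_variants = FALSE)
  ph <- simPhased(sim)
  ind <- simPedigree(sim)@individuals
  H <- ph@haplotypes
  sire_i <- match(ind$sire, ind$id)
  dam_i <- match(ind$dam, ind$id)
  for (i in which(!is.na(sire_i))) {
    pat <- H[2 * i - 1, ]
    expect_true(identical(pat, H[2 * sire_i[i] - 1, ]) ||
                  identical(pat, H[2 * sire_i[i], ]))
    mat <- H[2 * i, ]
    expect_true(identical(mat, H[2 * dam_i[i] - 1, ]) ||
                  identical(mat, H[2 * dam_i[i], ]))
  }
})

test_that("transmission is Mendelian at every marker", {
  expect_equal(mendelianViolations(simPhased(smallSim())), 0L)
})

test_that("crossover counts follow the Haldane map mean", {
  set.seed(99)
  k <- replicate(10000,
                 length(recessmap:::.sampleGamete(1, 1e8)$breaks))
  expect_lt(abs(mean(k) - 1.0), 0.05)
})

test_that("affected cohort members share a homozygous run at the causal
           position", {
  sim <- smallSim()
  top <- topInterval(sim)
  causal <- simTruth(sim)$causal_pos
  expect_true(top@start_bp <= causal && top@end_bp >= causal)
})

test_that("cohort selection composes the study design", {
  sim <- smallSim()
  ped <- simPedigree(sim)
  ind <- ped@individuals
  cohort <- cohortPhenotypes(sim)@status
  expect_equal(sum(cohort$status == "affected"), 4L)
  expect_equal(sum(cohort$status == "control"), 20L)
  cg <- ind$causal_genotype[match(cohort$id, ind$id)]
  expect_true(all(cg[cohort$status == "affected"] == 2))
  expect_true(all(cg[cohort$status == "control"] < 2))

  q <- quartetPhenotypes(sim)@status
  expect_identical(q$status, c("affected", "affected", "carrier",
                               "wild_type"))
  qg <- ind$causal_genotype[match(q$id, ind$id)]
  expect_identical(qg, c(2, 2, 1, 0))

  s1 <- selectCohort(ped, 4, 20, seed = 11)
  s2 <- selectCohort(ped, 4, 20, seed = 11)
  expect_identical(s1$cohort@status, s2$cohort@status)
  expect_error(selectCohort(ped, 10000, 20, seed = 1),
               "simulation error.*affected")
})

test_that("variant emission honours degenerate tag probabilities and the
           causal contract", {
  cfg <- smallConfig(seed = 2, known_id_probability = 1,
                     chip_overlap_probability = 0)
  sim <- simulateStudy(cfg)
  v <- variantInfo(quartetVariants(sim))
  # every background variant carries an ID; only the causal one does not
  expect_equal(sum(is.na(v$id)), 1L)
  expect_equal(v$pos[is.na(v$id)], simTruth(sim)$causal_pos)
  expect_false(any(v$chip))
  # implanted causal genotypes in quartet order: 1/1, 1/1, 0/1, 0/0
  g <- variantGeno(quartetVariants(sim))[is.na(v$id), ]
  expect_equal(unname(g), c(2L, 2L, 1L, 0L))
})

test_that("re-running the generator at a fixed seed is byte-identical", {
  cfg <- smallConfig(seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSimulation(simulateStudy(cfg), d1, what = c("ped", "vcf"))
  writeSimulation(simulateStudy(cfg), d2, what = c("ped", "vcf"))
  for (f in c("cohort.ped", "cohort.map", "quartet.vcf"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})
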