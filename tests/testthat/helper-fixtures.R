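# Shared fixtures and independent oracles. Everything is generated in code;
# the heavier simulated studies are cached for the duration of a test run.

.fixtures <- new.env(parent = emptyenv())

# A reduced study configuration for unit tests (a sixth of the default
# marker density on a fifth of the chromosome; small cohort).
smallConfig <- function(seed = 1, ...) {
  base <- list(seed = seed, n_generations = 6L, n_founder_males = 4L,
               n_founder_females = 20L, founders_per_generation = 4L,
               founder_sire_usage_fraction = 0.4,
               n_chip_markers = 400L, chrom_length = 2e7,
               causal_pos = 1.5e7, n_background_variants = 400L,
               n_genes = 12L, n_affected = 4L, n_controls = 20L)
  do.call(simConfig, utils::modifyList(base, list(...)))
}

smallSim <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulateStudy(smallConfig())
  .fixtures$small
}

# The default-scale study at the study conditions (12 affected, 123
# controls, 3,000 markers on 100 Mb), built once.
defaultSim <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- simulateStudy(simConfig(seed = 42))
  .fixtures$default
}

cohortGenotypes <- function(sim) {
  chipGenotypes(simPhased(sim), simMap(sim),
                idsWithStatus(cohortPhenotypes(sim),
                              c("affected", "control")))
}

simScan <- function(sim) scanMarkers(cohortGenotypes(sim),
                                     cohortPhenotypes(sim))

topInterval <- function(sim) {
  st <- simScan(sim)
  detectIntervals(st, min_markers = 5)[[1]]
}

# Hand-built genotype fixtures ------------------------------------------

toyMap <- function(n, chrom = "1", allele1 = "A", allele2 = "G",
                   pos = seq_len(n) * 1000) {
  MarkerMap(data.frame(marker_id = sprintf("M%02d", seq_len(n)),
                       chrom = chrom, pos = pos,
                       allele1 = allele1, allele2 = allele2,
                       stringsAsFactors = FALSE))
}

toyGenotypes <- function(calls, map, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("I%02d", seq_len(nrow(calls)))
  dimnames(calls) <- list(ids, map@markers$marker_id)
  GenotypeMatrix(calls, map)
}

toyVariantTable <- function(pos, geno, chrom = "7", ref = "C", alt = "T",
                            id = NA_character_, chip = FALSE,
                            samples = c("A1", "A2", "CAR", "WT")) {
  n <- length(pos)
  geno <- matrix(as.integer(geno), nrow = n, byrow = TRUE,
                 dimnames = list(NULL, samples))
  VariantTable(data.frame(chrom = chrom, pos = pos,
                          ref = rep_len(ref, n), alt = rep_len(alt, n),
                          id = rep_len(id, n), chip = rep_len(chip, n),
                          stringsAsFactors = FALSE), geno)
}

quartetRoles <- function(samples = c("A1", "A2", "CAR", "WT")) {
  PhenotypeTable(samples, c("affected", "affected", "carrier",
                            "wild_type"))
}

# Independent oracles ---------------------------------------------------

# Grid-search maximisation of the trinomial genotype likelihood:
# a 1e-4 grid locates the supremum, then two local refinement passes
# polish it (pure function evaluations throughout — independent of the
# closed-form maximiser used by markerLrt, whose quadratic curvature
# near boundary estimates would otherwise dominate a single-pass grid).
gridLrt <- function(n1, n2, n3, f1, step = 1e-4) {
  llAt <- function(pv) {
    ll <- rep(0, length(pv))
    if (n1 > 0) ll <- ll + n1 * log(pv^2)
    if (n2 > 0) ll <- ll + n2 * log(2 * pv * (1 - pv))
    if (n3 > 0) ll <- ll + n3 * log((1 - pv)^2)
    ll
  }
  p <- seq(0, 1, by = step)
  for (pass in 1:3) {
    best <- p[which.max(llAt(p))]
    lo <- max(0, best - step); hi <- min(1, best + step)
    step <- (hi - lo) / 1000
    p <- seq(lo, hi, by = step)
  }
  2 * (max(llAt(p)) - llAt(f1))
}

# Exhaustive enumeration of maximal qualifying marker windows.
bruteIntervals <- function(stats, min_markers) {
  out <- list()
  for (ch in unique(stats$chrom)) {
    s <- stats[stats$chrom == ch, , drop = FALSE]
    q <- s$n2 == 0 & (s$n1 == 0 | s$n3 == 0) & (s$n1 + s$n3) >= 1
    n <- nrow(s)
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!all(q[i:j])) break
        maximal <- (i == 1 || !q[i - 1]) && (j == n || !q[j + 1])
        if (maximal && (j - i + 1) >= min_markers)
          out[[length(out) + 1L]] <- list(chrom = ch, start = s$pos[i],
                                          end = s$pos[j],
                                          score = sum(s$lrt[i:j]),
                                          n = j - i + 1)
      }
    }
  }
  out
}

# Plain data.frame recount of the cascade step survivors.
bruteCascadeCounts <- function(vt, interval, roles, chip_positions,
                               models) {
  v <- variantInfo(vt)
  g <- variantGeno(vt)
  region <- searchRegion(interval)
  in_iv <- v$chrom == interval@chrom & v$pos >= region[1] &
    v$pos <= region[2]
  v <- v[in_iv, , drop = FALSE]; g <- g[in_iv, , drop = FALSE]
  aff <- idsWithStatus(roles, "affected")
  wt <- idsWithStatus(roles, "wild_type")
  car <- idsWithStatus(roles, "carrier")
  pat <- rep(TRUE, nrow(v))
  for (s in aff) pat <- pat & !is.na(g[, s]) & g[, s] == 2
  for (s in wt) pat <- pat & !is.na(g[, s]) & g[, s] == 0
  for (s in car) pat <- pat & !is.na(g[, s]) & g[, s] == 1
  v <- v[pat, , drop = FALSE]; g <- g[pat, , drop = FALSE]
  n2 <- nrow(v)
  unk <- is.na(v$id)
  v <- v[unk, , drop = FALSE]
  n3 <- nrow(v)
  off <- !(paste(v$chrom, v$pos) %in%
             paste(chip_positions$chrom, chip_positions$pos))
  v <- v[off, , drop = FALSE]
  n4 <- nrow(v)
  nonsyn <- vapply(seq_len(nrow(v)), function(i) {
    a <- annotateConsequence(v[i, c("chrom", "pos", "ref", "alt")], models)
    a@consequence_class %in% c("missense", "nonsense", "stop_lost")
  }, logical(1))
  c(sum(in_iv), n2, n3, n4, sum(nonsyn))
}

# A single-exon plus-strand transcript fixture with a chosen codon placed
# at a chosen codon index (used for worked annotation examples).
fixtureTranscript <- function(codon_index = 126, codon = "CGC",
                              n_codons = 140, start = 1001,
                              chrom = "7", seed = 7) {
  set.seed(seed)
  cds <- sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE)
  cds[1:3] <- c("A", "T", "G")
  cds[(3 * codon_index - 2):(3 * codon_index)] <-
    strsplit(codon, "")[[1]]
  cds[(3 * n_codons - 2):(3 * n_codons)] <- c("T", "A", "A")
  GeneModel("FIXG", "FIXG.t1", chrom, "+", start,
            start + 3 * n_codons - 1, paste(cds, collapse = ""))
}
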