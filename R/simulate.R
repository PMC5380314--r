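## Gene-drop study simulator.
##
## A founder recessive mutation is introduced on one haplotype of a heavily
## used generation-0 sire and dropped through a discrete-generation cattle
## pedigree under Mendelian transmission with Haldane recombination (Poisson
## crossovers, no interference, sex-averaged map). Transmission mosaics are
## sampled once, at pedigree construction, so that breeding decisions that
## depend on the causal genotype (affected calves do not reproduce) stay
## consistent with inheritance; any locus set can later be projected through
## the recorded mosaics. One master seed is split into named substreams
## (map, pedigree, founder, cohort, genes, variants, error) so stages can be
## re-run independently and reproducibly.

.substream <- function(seed, name) {
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) %% 65521 * 7919 + h * 104729) %% 2147483629)
}

.complementBase <- function(x) chartr("ACGT", "TGCA", x)

#' Create a simulation configuration
#'
#' Returns a [SimulationConfig-class] with defaults that emulate the mapped
#' study at desk scale; any slot can be overridden by name.
#'
#' @param seed master seed (integer).
#' @param ... named overrides of [SimulationConfig-class] slots.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simConfig(seed = 42, n_chip_markers = 500L)
#' @export
simConfig <- function(seed = 42, ...) {
  defaults <- list(
    seed = 42L, n_generations = 8L, n_founder_males = 8L,
    n_founder_females = 60L, founders_per_generation = 6L,
    litter_mean = 2.2, founder_sire_usage_fraction = 0.25,
    chrom_name = "7", chrom_length = 1e8, n_chip_markers = 3000L,
    recomb_rate = 1, allele_freq_beta = c(2, 2), ld_copy_prob = 0.3,
    causal_pos = 85e6, n_background_variants = 5000L,
    known_id_probability = 0.4, chip_overlap_probability = 0.3,
    fraction_coding = 0.05, fraction_nonsynonymous = 0.4,
    variant_freq_beta = c(1, 3), n_genes = 60L, genotyping_error = 0,
    n_affected = 12L, n_controls = 123L)
  args <- list(...)
  args <- args[!duplicated(names(args), fromLast = TRUE)]
  args$seed <- seed
  bad <- setdiff(names(args), names(defaults))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  vals <- utils::modifyList(defaults, args)
  for (f in c("seed", "n_generations", "n_founder_males",
              "n_founder_females", "founders_per_generation",
              "n_chip_markers", "n_background_variants", "n_genes",
              "n_affected", "n_controls"))
    vals[[f]] <- as.integer(vals[[f]])
  do.call(new, c(list(Class = "SimulationConfig"), vals))
}

#' Simulate the chip marker map
#'
#' Places `n_chip_markers` markers uniformly on the simulated chromosome
#' with random distinct alleles and allele-1 frequencies drawn from the
#' configured Beta distribution (mid-frequency, chip-like SNPs by default).
#'
#' @param config a [SimulationConfig-class].
#' @return A list with `map` ([MarkerMap-class]) and `freq` (numeric vector
#'   of allele-1 founder frequencies, in map order).
#' @export
simMarkerMap <- function(config) {
  set.seed(.substream(config@seed, "map"))
  n <- config@n_chip_markers
  pos <- sort(sample.int(config@chrom_length, n))
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, n, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), character(1))
  map <- MarkerMap(data.frame(
    marker_id = sprintf("M%05d", seq_len(n)), chrom = config@chrom_name,
    pos = pos, allele1 = a1, allele2 = unname(a2),
    stringsAsFactors = FALSE))
  freq <- rbeta(n, config@allele_freq_beta[1], config@allele_freq_beta[2])
  ## map construction sorted by pos; marker_id assigned after sorting
  list(map = map, freq = freq)
}

## One gamete: Poisson crossover count on a Haldane map, uniform breakpoint
## positions, random starting parental haplotype.
.sampleGamete <- function(morgans, chrom_length) {
  k <- rpois(1, morgans)
  list(breaks = sort(runif(k, 0, chrom_length)),
       start = sample.int(2L, 1L))
}

## Which parental haplotype (1/2) a gamete copies at each position.
.gameteHapAt <- function(gamete, positions) {
  ((gamete$start - 1L + findInterval(positions, gamete$breaks)) %% 2L) + 1L
}

#' Build a founder-effect pedigree
#'
#' Simulates a discrete-generation pedigree in which one generation-0 sire
#' is a heterozygous carrier of the causal allele and sires a fixed fraction
#' of the matings of every subsequent generation (artificial insemination
#' keeps a popular bull in service across generations). Unrelated immigrant
#' founders enter each generation; affected individuals (two causal copies,
#' fully penetrant) do not reproduce. Transmission mosaics for every gamete
#' are sampled here and stored in the returned object.
#'
#' @param config a [SimulationConfig-class].
#' @return A [Pedigree-class]; all causal alleles in it descend from the
#'   single carrier founder.
#' @export
buildPedigree <- function(config) {
  if (config@n_generations < 2)
    stop("n_generations must be >= 2")
  set.seed(.substream(config@seed, "pedigree"))
  L <- config@chrom_length
  morgans <- config@recomb_rate * L / 1e8
  u <- config@founder_sire_usage_fraction

  id <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); gen <- integer(0)
  gam <- list(); hapc <- list()

  addInd <- function(i, s, d, sx, g, gm, hc) {
    id[[length(id) + 1L]] <<- i
    sire[[length(sire) + 1L]] <<- s
    dam[[length(dam) + 1L]] <<- d
    sex[[length(sex) + 1L]] <<- sx
    gen[[length(gen) + 1L]] <<- g
    gam[length(gam) + 1L] <<- list(gm)   # list(...) so NULL is kept
    hapc[[length(hapc) + 1L]] <<- hc
  }

  for (k in seq_len(config@n_founder_males))
    addInd(sprintf("G0M%03d", k), NA_character_, NA_character_, "M", 0L,
           NULL, c(k == 1L, FALSE))  # male 1 is the carrier founder
  for (k in seq_len(config@n_founder_females))
    addInd(sprintf("G0F%03d", k), NA_character_, NA_character_, "F", 0L,
           NULL, c(FALSE, FALSE))
  founder_id <- id[[1]]

  for (g in seq_len(config@n_generations)) {
    gv <- unlist(gen); sv <- unlist(sex)
    cg <- vapply(hapc, sum, numeric(1))
    dams <- which(gv == g - 1L & sv == "F" & cg < 2)
    ## the carrier founder mates only through the usage fraction, so his
    ## share of matings equals founder_sire_usage_fraction exactly
    sires <- setdiff(which(gv == g - 1L & sv == "M" & cg < 2), 1L)
    if (length(dams) == 0 || (length(sires) == 0 && u == 0))
      stop("simulation error: breeding pool died out at generation ", g,
           "; increase litter_mean or founder sizes")
    n_off <- rpois(length(dams), config@litter_mean)
    born <- 0L
    for (di in seq_along(dams)) {
      if (n_off[di] == 0) next
      for (o in seq_len(n_off[di])) {
        use_founder <- runif(1) < u
        si <- if (use_founder || length(sires) == 0) 1L else
          sires[sample.int(length(sires), 1L)]
        born <- born + 1L
        pat <- .sampleGamete(morgans, L)
        mat <- .sampleGamete(morgans, L)
        pc <- hapc[[si]][.gameteHapAt(pat, config@causal_pos)]
        mc <- hapc[[dams[di]]][.gameteHapAt(mat, config@causal_pos)]
        addInd(sprintf("G%d_%04d", g, born), id[[si]], id[[dams[di]]],
               if (runif(1) < 0.5) "M" else "F", g,
               list(pat = pat, mat = mat), c(pc, mc))
      }
    }
    if (born == 0L)
      stop("simulation error: no offspring at generation ", g,
           "; increase litter_mean")
    if (g < config@n_generations && config@founders_per_generation > 0) {
      for (k in seq_len(config@founders_per_generation))
        addInd(sprintf("G%dI%03d", g, k), NA_character_, NA_character_,
               if (k %% 2 == 0) "M" else "F", g, NULL, c(FALSE, FALSE))
    }
  }

  ind <- data.frame(id = unlist(id), sire = unlist(sire),
                    dam = unlist(dam), sex = unlist(sex),
                    generation = unlist(gen),
                    causal_genotype = vapply(hapc, sum, numeric(1)),
                    stringsAsFactors = FALSE)
  ped <- new("Pedigree", individuals = ind, gametes = gam,
             hap_causal = do.call(rbind, hapc), chrom_length = L)
  attr(ped, "founder_id") <- founder_id
  ped
}

#' Find the common strict ancestors of a set of individuals
#'
#' Returns every individual that is a strict ancestor of each queried id; a
#' query member is returned only if it is also an ancestor of all the
#' others.
#'
#' @param pedigree a [Pedigree-class].
#' @param ids character vector of individual ids.
#' @return character vector of common-ancestor ids (possibly empty).
#' @export
findCommonAncestors <- function(pedigree, ids) {
  ind <- pedigree@individuals
  unknown <- setdiff(ids, ind$id)
  if (length(unknown))
    stop("lookup error: unknown id(s): ", paste(unknown, collapse = ", "))
  anc <- function(i) {
    out <- character(0)
    frontier <- i
    while (length(frontier)) {
      k <- match(frontier, ind$id)
      parents <- unique(stats::na.omit(c(ind$sire[k], ind$dam[k])))
      parents <- setdiff(parents, out)
      out <- c(out, parents)
      frontier <- parents
    }
    out
  }
  sets <- lapply(ids, anc)
  names(sets) <- ids
  common <- Reduce(intersect, sets)
  ## re-admit query members ancestral to all *other* queried ids
  for (m in ids) {
    others <- setdiff(ids, m)
    if (length(others) && all(vapply(others, function(o)
      m %in% sets[[o]], logical(1))))
      common <- union(common, m)
  }
  common
}

## Founder chip haplotypes: allele1 (code 1) drawn per marker from the map
## frequencies, with first-order Markov adjacency copying for background LD.
.sampleFounderChipHaps <- function(n_haps, freq, ld_copy_prob) {
  L <- length(freq)
  H <- matrix(2L, n_haps, L)
  for (h in seq_len(n_haps)) {
    base <- as.integer(runif(L) >= freq) + 1L  # 1 = allele1
    keep <- runif(L) >= ld_copy_prob
    keep[1] <- TRUE
    src <- cummax(seq_len(L) * keep)
    H[h, ] <- base[src]
  }
  H
}

## Ancestor closure (row indices) of a set of individual indices.
.ancestorClosure <- function(pedigree, idx) {
  ind <- pedigree@individuals
  sire_i <- match(ind$sire, ind$id)
  dam_i <- match(ind$dam, ind$id)
  need <- rep(FALSE, nrow(ind))
  need[idx] <- TRUE
  frontier <- idx
  while (length(frontier)) {
    parents <- unique(stats::na.omit(c(sire_i[frontier], dam_i[frontier])))
    parents <- parents[!need[parents]]
    need[parents] <- TRUE
    frontier <- parents
  }
  which(need)
}

## Drop founder alleles through the recorded mosaics at the given positions.
## founder_haps has two rows per founder, in pedigree order. Only rows for
## `need` individuals (plus their ancestors) are filled when given.
.projectLoci <- function(pedigree, founder_haps, positions, need = NULL) {
  ind <- pedigree@individuals
  N <- nrow(ind)
  sire_i <- match(ind$sire, ind$id)
  dam_i <- match(ind$dam, ind$id)
  is_founder <- is.na(sire_i)
  ford <- cumsum(is_founder)
  active <- if (is.null(need)) seq_len(N) else
    .ancestorClosure(pedigree, need)
  H <- matrix(NA_integer_, 2L * N, length(positions))
  for (i in active) {
    if (is_founder[i]) {
      H[2L * i - 1L, ] <- founder_haps[2L * ford[i] - 1L, ]
      H[2L * i, ] <- founder_haps[2L * ford[i], ]
    } else {
      g <- pedigree@gametes[[i]]
      p <- sire_i[i]
      sel <- .gameteHapAt(g$pat, positions)
      r <- H[2L * p - 1L, ]
      sw <- sel == 2L
      r[sw] <- H[2L * p, sw]
      H[2L * i - 1L, ] <- r
      p <- dam_i[i]
      sel <- .gameteHapAt(g$mat, positions)
      r <- H[2L * p - 1L, ]
      sw <- sel == 2L
      r[sw] <- H[2L * p, sw]
      H[2L * i, ] <- r
    }
  }
  H
}

#' Drop founder chip haplotypes through the pedigree
#'
#' Samples founder haplotypes from the marker frequency model (with
#' background LD) and propagates them through the pedigree's recorded
#' transmission mosaics. With `recomb_rate = 0` every transmitted haplotype
#' is an exact copy of one parental haplotype; the causal allele always
#' travels with the carrier founder's surrounding marker haplotype except
#' where crossovers occurred.
#'
#' @param pedigree a [Pedigree-class] from [buildPedigree()].
#' @param marker_map the chip [MarkerMap-class] (single chromosome).
#' @param config the [SimulationConfig-class].
#' @param freq optional allele-1 founder frequencies (from
#'   [simMarkerMap()]); drawn from the configured Beta distribution when
#'   missing.
#' @return A [PhasedGenotypes-class] over the chip markers.
#' @export
geneDrop <- function(pedigree, marker_map, config, freq = NULL) {
  m <- marker_map@markers
  if (length(unique(m$chrom)) > 1)
    stop("marker map must be on a single chromosome")
  if (any(m$pos > config@chrom_length))
    stop("marker positions exceed chrom_length")
  set.seed(.substream(config@seed, "founder"))
  if (is.null(freq))
    freq <- rbeta(nrow(m), config@allele_freq_beta[1],
                  config@allele_freq_beta[2])
  n_founders <- sum(is.na(pedigree@individuals$sire))
  FH <- .sampleFounderChipHaps(2L * n_founders, freq, config@ld_copy_prob)
  H <- .projectLoci(pedigree, FH, m$pos)
  new("PhasedGenotypes", pedigree = pedigree,
      loci = data.frame(id = m$marker_id, chrom = m$chrom, pos = m$pos,
                        stringsAsFactors = FALSE),
      haplotypes = H)
}

#' Count Mendelian-consistency violations in a gene drop
#'
#' For every non-founder haplotype and locus, checks that the transmitted
#' allele occurs in the corresponding parent. Returns the number of
#' violating (haplotype, locus) cells — zero for any correctly propagated
#' drop.
#'
#' @param phased a [PhasedGenotypes-class].
#' @return integer violation count.
#' @export
mendelianViolations <- function(phased) {
  ind <- phased@pedigree@individuals
  sire_i <- match(ind$sire, ind$id)
  dam_i <- match(ind$dam, ind$id)
  H <- phased@haplotypes
  bad <- 0L
  for (i in which(!is.na(sire_i))) {
    h <- H[2L * i - 1L, ]
    if (anyNA(h)) next
    p <- sire_i[i]
    bad <- bad + sum(h != H[2L * p - 1L, ] & h != H[2L * p, ])
    h <- H[2L * i, ]
    p <- dam_i[i]
    bad <- bad + sum(h != H[2L * p - 1L, ] & h != H[2L * p, ])
  }
  bad
}

#' Extract unphased chip genotypes for a set of individuals
#'
#' Collapses the two projected haplotypes of each individual to allele-1
#' dosage codes and optionally applies a per-call genotyping error.
#'
#' @param phased a [PhasedGenotypes-class] from [geneDrop()].
#' @param map the chip [MarkerMap-class].
#' @param ids individuals to extract (default: whole pedigree).
#' @param error per-call error probability; see [applyGenotypingError()].
#' @param seed seed for the error process.
#' @return A [GenotypeMatrix-class].
#' @export
chipGenotypes <- function(phased, map, ids = NULL, error = 0, seed = 1) {
  ped_ids <- phased@pedigree@individuals$id
  if (is.null(ids)) ids <- ped_ids
  idx <- match(ids, ped_ids)
  if (anyNA(idx))
    stop("lookup error: unknown id(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  H <- phased@haplotypes
  calls <- (H[2L * idx - 1L, , drop = FALSE] == 1L) +
    (H[2L * idx, , drop = FALSE] == 1L)
  dimnames(calls) <- list(ids, map@markers$marker_id)
  gm <- GenotypeMatrix(calls, map)
  if (error > 0) gm <- applyGenotypingError(gm, error, seed)
  gm
}

#' Apply a per-call genotyping error
#'
#' Each call is independently replaced, with probability `epsilon`, by a
#' uniformly random genotype code. The error process is coupled across
#' `epsilon` values at a fixed seed: the calls perturbed at a smaller
#' `epsilon` are a subset of those perturbed at a larger one, so error
#' effects grow monotonically in `epsilon`.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param epsilon per-call error probability in `[0, 1]`.
#' @param seed seed of the error substream.
#' @return A perturbed [GenotypeMatrix-class].
#' @export
applyGenotypingError <- function(genotypes, epsilon, seed = 1) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon == 0) return(genotypes)
  calls <- genotypes@calls
  set.seed(.substream(seed, "error"))
  u <- matrix(runif(length(calls)), nrow(calls))
  repl <- matrix(sample(0:2, length(calls), replace = TRUE), nrow(calls))
  flip <- u < epsilon & !is.na(calls)
  calls[flip] <- repl[flip]
  GenotypeMatrix(calls, genotypes@map)
}

#' Select the genotyped cohort and the sequencing quartet
#'
#' Draws the affected cohort at random from all affected individuals, the
#' control cohort from unaffected animals of the last three generations
#' (mirroring adult animals known to be unaffected; carriers are permitted
#' among controls), and nominates the whole-genome-sequencing quartet: two
#' affected cohort members, one obligate carrier (a parent of a selected
#' affected) and one wild-type non-carrier.
#'
#' @param pedigree a [Pedigree-class].
#' @param n_affected,n_controls cohort sizes.
#' @param seed sampling seed.
#' @return list with `cohort` (a [PhenotypeTable-class] of affected +
#'   control ids) and `quartet` (a [PhenotypeTable-class] with statuses
#'   affected, affected, carrier, wild_type, in that order).
#' @export
selectCohort <- function(pedigree, n_affected = 12, n_controls = 123,
                         seed = 1) {
  set.seed(seed)
  ind <- pedigree@individuals
  late <- ind$generation >= max(ind$generation) - 2L
  aff_pool <- ind$id[ind$causal_genotype == 2]
  ctl_pool <- ind$id[ind$causal_genotype < 2 & late]
  if (length(aff_pool) < n_affected)
    stop("simulation error: only ", length(aff_pool), " affected ",
         "individuals available (need ", n_affected, "); increase ",
         "n_generations or founder_sire_usage_fraction")
  if (length(ctl_pool) < n_controls)
    stop("simulation error: only ", length(ctl_pool), " control ",
         "candidates available (need ", n_controls, ")")
  aff <- sample(aff_pool, n_affected)
  ctl <- sample(setdiff(ctl_pool, aff), n_controls)
  cohort <- PhenotypeTable(c(aff, ctl),
                           c(rep("affected", n_affected),
                             rep("control", n_controls)))
  ## obligate carrier: the sire of the first selected affected (affected do
  ## not reproduce, so each parent carries exactly one causal copy)
  carrier <- ind$sire[match(aff[1], ind$id)]
  wt_pool <- setdiff(ind$id[ind$causal_genotype == 0 & late],
                     c(aff, ctl, carrier))
  if (length(wt_pool) == 0)
    wt_pool <- setdiff(ind$id[ind$causal_genotype == 0], c(aff, carrier))
  wt <- sample(wt_pool, 1)
  quartet <- PhenotypeTable(c(aff[1], aff[2], carrier, wt),
                            c("affected", "affected", "carrier",
                              "wild_type"))
  list(cohort = cohort, quartet = quartet)
}
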