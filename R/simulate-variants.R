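## Synthetic gene models and the quartet variant table.

#' Simulate gene models on the study chromosome
#'
#' Places `n_genes` non-overlapping coding gene models (1-4 CDS exons,
#' random strand, random coding sequence) uniformly on the chromosome. The
#' first model is the causal gene: a single-exon plus-strand CDS of 1,260 bp
#' positioned so that the configured `causal_pos` falls on coding position
#' 376, the first base of an arginine codon (CGC) at codon 126 — a C>T
#' change there is the implanted missense (R>C) causal variant.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `models` (list of [GeneModel-class], causal gene
#'   first) and `causal` (list: gene_id, pos, ref, alt, cds_pos).
#' @export
simGeneModels <- function(config) {
  set.seed(.substream(config@seed, "genes"))
  L <- config@chrom_length
  bases <- c("A", "C", "G", "T")

  c_len <- 1260L
  c_start <- config@causal_pos - 375
  if (c_start < 1 || c_start + c_len - 1 > L)
    stop("causal_pos too close to a chromosome end for the causal gene")
  cds <- sample(bases, c_len, replace = TRUE)
  cds[1:3] <- c("A", "T", "G")
  cds[376:378] <- c("C", "G", "C")           # codon 126 = CGC (Arg)
  cds[(c_len - 2):c_len] <- c("T", "A", "A")
  models <- list(GeneModel("GENE000", "GENE000.t1", config@chrom_name, "+",
                           c_start, c_start + c_len - 1,
                           paste(cds, collapse = "")))
  spans <- matrix(c(c_start - 1000, c_start + c_len - 1 + 1000), 1)

  k <- 1L
  while (k < config@n_genes) {
    n_ex <- sample.int(4L, 1L)
    len <- 3L * sample(150:450, 1L)
    w <- rep(len %/% n_ex, n_ex)
    w[n_ex] <- w[n_ex] + len - sum(w)
    introns <- if (n_ex > 1) sample(200:2000, n_ex - 1, replace = TRUE)
               else integer(0)
    span <- sum(w) + sum(introns)
    placed <- FALSE
    for (try in 1:50) {
      start <- sample.int(L - span, 1L)
      lo <- start - 1000; hi <- start + span + 1000
      if (all(hi < spans[, 1] | lo > spans[, 2])) { placed <- TRUE; break }
    }
    if (!placed) next
    ex_start <- start + cumsum(c(0, w[-n_ex] + introns))
    ex_end <- ex_start + w - 1
    strand <- sample(c("+", "-"), 1)
    seq <- paste(sample(bases, len, replace = TRUE), collapse = "")
    k <- k + 1L
    models[[k]] <- GeneModel(sprintf("GENE%03d", k - 1L),
                             sprintf("GENE%03d.t1", k - 1L),
                             config@chrom_name, strand, ex_start, ex_end,
                             seq)
    spans <- rbind(spans, c(lo, hi))
  }
  list(models = models,
       causal = list(gene_id = "GENE000", pos = config@causal_pos,
                     ref = "C", alt = "T", cds_pos = 376L))
}

#' Emit the sequenced-quartet variant table
#'
#' Places background variants on the chromosome (a configured fraction
#' inside CDS, with alternate alleles engineered to hit the configured
#' nonsynonymous fraction), assigns their alleles to founder haplotypes from
#' the variant frequency model, drops them through the recorded pedigree
#' mosaics, and reads off the genotypes of the sequencing quartet. Each
#' background variant is independently tagged with a dbSNP-like identifier
#' and as a chip site with the configured probabilities. The causal variant
#' is implanted at `causal_pos` as unknown-ID, non-chip and missense; its
#' quartet genotypes (hom-alt, hom-alt, het, hom-ref) follow from the drop
#' by construction. Only sites with at least one alternate call in the
#' quartet are emitted (like a joint call set); the causal site is always
#' kept.
#'
#' @param phased the chip [PhasedGenotypes-class] (supplies the marker
#'   positions to avoid and the pedigree).
#' @param quartet [PhenotypeTable-class] from [selectCohort()] (order:
#'   affected, affected, carrier, wild_type).
#' @param config the [SimulationConfig-class].
#' @param genes result of [simGeneModels()].
#' @param seed variant substream seed (default: the config master seed).
#' @return A [VariantTable-class] with the quartet as samples.
#' @export
emitVariants <- function(phased, quartet, config, genes,
                         seed = config@seed) {
  set.seed(.substream(seed, "variants"))
  models <- genes$models
  causal <- genes$causal
  L <- config@chrom_length
  n_bg <- config@n_background_variants
  bases <- c("A", "C", "G", "T")
  marker_pos <- phased@loci$pos

  cds_pool <- unlist(lapply(models, function(m)
    unlist(mapply(seq, m@exon_starts, m@exon_ends, SIMPLIFY = FALSE))))
  exclude <- c(marker_pos, causal$pos)

  n_cod <- round(n_bg * config@fraction_coding)
  n_non <- n_bg - n_cod
  cod_sites <- if (n_cod > 0)
    sample(setdiff(cds_pool, exclude), n_cod) else integer(0)

  non_sites <- integer(0)
  forbidden <- c(exclude, cds_pool, cod_sites)
  while (length(non_sites) < n_non) {
    cand <- sample.int(L, ceiling((n_non - length(non_sites)) * 1.3))
    if (causal$pos %in% cand)
      warning("background variant collided with causal_pos; repositioned")
    cand <- setdiff(cand, c(forbidden, non_sites))
    non_sites <- c(non_sites, cand)
  }
  non_sites <- non_sites[seq_len(n_non)]

  ## coding sites: choose alternate alleles to fill the nonsynonymous quota
  want_nonsyn <- round(config@fraction_nonsynonymous * n_cod)
  cod_ref <- cod_alt <- character(n_cod)
  for (j in seq_along(cod_sites)) {
    hit <- .modelAtPosition(models, config@chrom_name, cod_sites[j])
    proj <- .cdsProject(hit$model, cod_sites[j])
    m <- hit$model
    cds_chr <- as.character(m@cds)
    ref_cds <- substr(cds_chr, proj$cds_pos, proj$cds_pos)
    ci <- ceiling(proj$cds_pos / 3)
    codon <- substr(cds_chr, 3 * ci - 2, 3 * ci)
    off <- (proj$cds_pos - 1) %% 3
    ref_aa <- .translateCodon(codon)
    alts <- setdiff(bases, ref_cds)
    aa <- vapply(alts, function(a) {
      cc <- codon; substr(cc, off + 1, off + 1) <- a; .translateCodon(cc)
    }, character(1))
    nonsyn <- alts[aa != ref_aa]
    syn <- alts[aa == ref_aa]
    if (want_nonsyn > 0 && length(nonsyn)) {
      pick <- nonsyn[sample.int(length(nonsyn), 1)]
      want_nonsyn <- want_nonsyn - 1L
    } else if (length(syn)) {
      pick <- syn[sample.int(length(syn), 1)]
    } else {
      pick <- nonsyn[sample.int(length(nonsyn), 1)]
      want_nonsyn <- want_nonsyn - 1L
    }
    if (m@strand == "+") {
      cod_ref[j] <- ref_cds; cod_alt[j] <- pick
    } else {
      cod_ref[j] <- .complementBase(ref_cds)
      cod_alt[j] <- .complementBase(pick)
    }
  }

  non_ref <- sample(bases, n_non, replace = TRUE)
  non_alt <- vapply(non_ref, function(b)
    sample(setdiff(bases, b), 1), character(1))

  pos <- c(cod_sites, non_sites)
  ref <- c(cod_ref, non_ref)
  alt <- c(cod_alt, unname(non_alt))
  freq <- rbeta(n_bg, config@variant_freq_beta[1],
                config@variant_freq_beta[2])
  known <- runif(n_bg) < config@known_id_probability
  ids <- rep(NA_character_, n_bg)
  ids[known] <- sprintf("rs%08d", sample.int(99999999L, sum(known)))
  chip <- runif(n_bg) < config@chip_overlap_probability

  ## append the causal record
  pos <- c(pos, causal$pos)
  ref <- c(ref, causal$ref)
  alt <- c(alt, causal$alt)
  ids <- c(ids, NA_character_)
  chip <- c(chip, FALSE)
  o <- order(pos)
  pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
  ids <- ids[o]; chip <- chip[o]
  causal_col <- which(pos == causal$pos)
  freq_sorted <- c(freq, 0)[o]   # causal has no background frequency

  ped <- phased@pedigree
  n_founders <- sum(is.na(ped@individuals$sire))
  nh <- 2L * n_founders
  FH <- matrix(as.integer(matrix(runif(nh * length(pos)), nh) <
                            rep(freq_sorted, each = nh)), nh)
  FH[, causal_col] <- 0L
  FH[1L, causal_col] <- 1L   # carrier founder's first haplotype

  q_ids <- quartet@status$id
  q_idx <- match(q_ids, ped@individuals$id)
  if (anyNA(q_idx)) stop("quartet ids not found in pedigree")
  H <- .projectLoci(ped, FH, pos, need = q_idx)
  geno <- (H[2L * q_idx - 1L, , drop = FALSE] == 1L) +
    (H[2L * q_idx, , drop = FALSE] == 1L)
  geno <- t(geno)
  colnames(geno) <- q_ids

  if (!all(geno[causal_col, ] ==
             ped@individuals$causal_genotype[q_idx]))
    stop("internal inconsistency: causal projection disagrees with ",
         "pedigree causal genotypes")

  keep <- rowSums(geno, na.rm = TRUE) > 0
  keep[causal_col] <- TRUE
  VariantTable(data.frame(chrom = config@chrom_name, pos = pos[keep],
                          ref = ref[keep], alt = alt[keep],
                          id = ids[keep], chip = chip[keep],
                          stringsAsFactors = FALSE),
               geno[keep, , drop = FALSE])
}

#' Run a complete simulated mapping study
#'
#' Drives the whole generator: marker map, pedigree, chip gene drop, cohort
#' and quartet selection, synthetic gene models and (optionally) the quartet
#' variant table, and bundles everything with its ground truth.
#'
#' @param config a [SimulationConfig-class] (see [simConfig()]).
#' @param include_variants emit the quartet variant table (set `FALSE` when
#'   only the chip-mapping stage is needed).
#' @return A [SimulatedStudy-class].
#' @examples
#' sim <- simulateStudy(simConfig(seed = 1, n_generations = 5L,
#'                                n_chip_markers = 200L,
#'                                n_background_variants = 100L,
#'                                n_genes = 10L, n_affected = 4L,
#'                                n_controls = 20L),
#'                      include_variants = FALSE)
#' sim
#' @export
simulateStudy <- function(config, include_variants = TRUE) {
  mf <- simMarkerMap(config)
  ped <- buildPedigree(config)
  phased <- geneDrop(ped, mf$map, config, freq = mf$freq)
  sel <- selectCohort(ped, config@n_affected, config@n_controls,
                      seed = .substream(config@seed, "cohort"))
  genes <- simGeneModels(config)
  q_ids <- sel$quartet@status$id
  variants <- if (include_variants) {
    emitVariants(phased, sel$quartet, config, genes)
  } else {
    VariantTable(data.frame(chrom = character(0), pos = numeric(0),
                            ref = character(0), alt = character(0),
                            id = character(0), chip = logical(0),
                            stringsAsFactors = FALSE),
                 matrix(integer(0), 0, length(q_ids),
                        dimnames = list(NULL, q_ids)))
  }
  ind <- ped@individuals
  truth <- list(causal_pos = genes$causal$pos,
                causal_gene = genes$causal$gene_id,
                causal_cds_pos = genes$causal$cds_pos,
                causal_ref = genes$causal$ref,
                causal_alt = genes$causal$alt,
                founder_id = attr(ped, "founder_id"),
                carriers = ind$id[ind$causal_genotype == 1],
                affected = ind$id[ind$causal_genotype == 2])
  new("SimulatedStudy", config = config, pedigree = ped, map = mf$map,
      phased = phased, cohort = sel$cohort, quartet = sel$quartet,
      variants = variants, models = genes$models, truth = truth)
}

#' Accessors for SimulatedStudy
#'
#' @param sim a [SimulatedStudy-class].
#' @return `simTruth`: the ground-truth list; `quartetVariants`: the
#'   [VariantTable-class]; `geneModels`: list of [GeneModel-class];
#'   `cohortPhenotypes`/`quartetPhenotypes`: [PhenotypeTable-class]s;
#'   `simPedigree`, `simMap`, `simPhased`: the respective components;
#'   `chipSites`: data.frame of (chrom, pos) of every array site (map
#'   markers plus chip-tagged variants).
#' @export
simTruth <- function(sim) sim@truth

#' @rdname simTruth
#' @export
quartetVariants <- function(sim) sim@variants

#' @rdname simTruth
#' @export
geneModels <- function(sim) sim@models

#' @rdname simTruth
#' @export
cohortPhenotypes <- function(sim) sim@cohort

#' @rdname simTruth
#' @export
quartetPhenotypes <- function(sim) sim@quartet

#' @rdname simTruth
#' @export
simPedigree <- function(sim) sim@pedigree

#' @rdname simTruth
#' @export
simMap <- function(sim) sim@map

#' @rdname simTruth
#' @export
simPhased <- function(sim) sim@phased

#' @rdname simTruth
#' @export
chipSites <- function(sim) {
  v <- sim@variants@variants
  out <- rbind(
    data.frame(chrom = sim@map@markers$chrom, pos = sim@map@markers$pos,
               stringsAsFactors = FALSE),
    data.frame(chrom = v$chrom[v$chip], pos = v$pos[v$chip],
               stringsAsFactors = FALSE))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write a simulated study to disk
#'
#' Serialises the requested components: `"ped"` — cohort chip genotypes as
#' PED/MAP (with pedigree parentage and the configured genotyping error);
#' `"vcf"` — the quartet variant table; `"truth"` — per-individual causal
#' genotypes plus a key/value metadata table; `"genes"` — gene models as
#' GFF3 + genome FASTA (CDS bases embedded in N background); `"chip"` —
#' the array site list.
#'
#' @param sim a [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @param what subset of c("ped", "vcf", "truth", "genes", "chip").
#' @return Invisibly, a named character vector of the files written.
#' @export
writeSimulation <- function(sim, dir,
                            what = c("ped", "vcf", "truth", "genes",
                                     "chip")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- sim@config
  out <- character(0)
  if ("ped" %in% what) {
    gm <- chipGenotypes(sim@phased, sim@map, idsWithStatus(
      sim@cohort, c("affected", "control")),
      error = cfg@genotyping_error, seed = cfg@seed)
    writePedMap(gm, sim@cohort, file.path(dir, "cohort.ped"),
                file.path(dir, "cohort.map"), family = "SIM",
                parents = sim@pedigree@individuals)
    out <- c(out, ped = file.path(dir, "cohort.ped"),
             map = file.path(dir, "cohort.map"))
  }
  if ("vcf" %in% what) {
    writeVcfVariants(sim@variants, file.path(dir, "quartet.vcf"))
    out <- c(out, vcf = file.path(dir, "quartet.vcf"))
  }
  if ("truth" %in% what) {
    ind <- sim@pedigree@individuals
    write.table(ind[, c("id", "sire", "dam", "generation",
                        "causal_genotype")],
                file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    meta <- data.frame(
      key = c("causal_pos", "causal_gene", "causal_cds_pos", "causal_ref",
              "causal_alt", "founder_id"),
      value = c(sim@truth$causal_pos, sim@truth$causal_gene,
                sim@truth$causal_cds_pos, sim@truth$causal_ref,
                sim@truth$causal_alt, sim@truth$founder_id))
    write.table(meta, file.path(dir, "truth_meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out <- c(out, truth = file.path(dir, "truth.tsv"),
             truth_meta = file.path(dir, "truth_meta.tsv"))
  }
  if ("genes" %in% what) {
    writeGeneModels(sim@models, file.path(dir, "genes.gff3"),
                    file.path(dir, "genome.fa"), cfg@chrom_length)
    out <- c(out, gff = file.path(dir, "genes.gff3"),
             fasta = file.path(dir, "genome.fa"))
  }
  if ("chip" %in% what) {
    write.table(chipSites(sim), file.path(dir, "chip_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, chip = file.path(dir, "chip_sites.tsv"))
  }
  invisible(out)
}
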