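#' @import methods
#' @importFrom stats rbeta rbinom rpois runif setNames
#' @importFrom utils read.table write.table
NULL

.GENO_STATUSES <- c("affected", "control", "carrier", "wild_type", "unknown")
.CONSEQ_CLASSES <- c("intergenic", "intronic", "synonymous", "missense",
                     "nonsense", "stop_lost", "non_coding")
.CASCADE_STEPS <- c("interval", "genotype_pattern", "not_in_known_ids",
                    "not_on_chip", "nonsynonymous")

## ---------------------------------------------------------------------------
## MarkerMap
## ---------------------------------------------------------------------------

#' MarkerMap: ordered SNP-chip marker positions and alleles
#'
#' Container for the marker scaffold of a genotyping array: one row per
#' marker with identifier, chromosome, 1-based physical position and the two
#' possible alleles. Rows are kept sorted by (chrom, pos) and genotype codes
#' everywhere in the package are anchored to `allele1`/`allele2` of this map,
#' so "allele 1" means the same physical allele across all animals.
#'
#' @slot markers data.frame with columns `marker_id`, `chrom`, `pos`,
#'   `allele1`, `allele2`.
#' @export
setClass("MarkerMap", representation(markers = "data.frame"))

setValidity("MarkerMap", function(object) {
  m <- object@markers
  req <- c("marker_id", "chrom", "pos", "allele1", "allele2")
  if (!all(req %in% names(m)))
    return(paste("markers must have columns:", paste(req, collapse = ", ")))
  if (anyDuplicated(m$marker_id))
    return("duplicated marker_id")
  if (anyDuplicated(m[, c("chrom", "pos")]))
    return("duplicated (chrom, pos)")
  o <- order(m$chrom, m$pos)
  if (!identical(o, seq_len(nrow(m))))
    return("markers must be sorted by (chrom, pos)")
  if (nrow(m) > 0) {
    if (any(m$allele1 == m$allele2))
      return("allele1 must differ from allele2")
    if (!all(c(m$allele1, m$allele2) %in% c("A", "C", "G", "T")))
      return("alleles must be A/C/G/T")
    if (any(m$pos < 1))
      return("positions are 1-based and must be >= 1")
  }
  TRUE
})

#' Construct a MarkerMap
#'
#' @param markers data.frame with columns `marker_id`, `chrom`, `pos`,
#'   `allele1`, `allele2`; rows are sorted by (chrom, pos).
#' @return A [MarkerMap-class] object.
#' @export
MarkerMap <- function(markers) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  markers <- markers[order(markers$chrom, markers$pos), , drop = FALSE]
  rownames(markers) <- NULL
  new("MarkerMap", markers = markers)
}

setMethod("show", "MarkerMap", function(object) {
  m <- object@markers
  cat("MarkerMap with", nrow(m), "markers on",
      length(unique(m$chrom)), "chromosome(s)\n")
  if (nrow(m) > 0)
    cat("  span:", m$chrom[1], format(m$pos[1], big.mark = ","), "-",
        format(m$pos[nrow(m)], big.mark = ","), "\n")
})

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' GenotypeMatrix: chip genotype calls anchored to a MarkerMap
#'
#' Individuals x markers matrix of genotype codes counting copies of the
#' map's `allele1`: 2 = homozygous allele1, 1 = heterozygous, 0 = homozygous
#' allele2, `NA` = missing call.
#'
#' @slot calls integer matrix, rownames = individual ids, colnames =
#'   marker ids in map order.
#' @slot map the [MarkerMap-class] the columns refer to.
#' @export
setClass("GenotypeMatrix",
         representation(calls = "matrix", map = "MarkerMap"))

setValidity("GenotypeMatrix", function(object) {
  cl <- object@calls
  if (!is.integer(cl) && !all(is.na(cl)))
    return("calls must be an integer matrix")
  if (is.null(rownames(cl)) || is.null(colnames(cl)))
    return("calls must carry individual and marker dimnames")
  if (!identical(colnames(cl), object@map@markers$marker_id))
    return("column set/order must equal the MarkerMap")
  v <- cl[!is.na(cl)]
  if (length(v) && !all(v %in% 0:2))
    return("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(cl)))
    return("duplicated individual ids")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of allele1 dosages (0/1/2/NA) with individual
#'   rownames and marker colnames.
#' @param map the [MarkerMap-class] describing the columns.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(calls, map) {
  storage.mode(calls) <- "integer"
  new("GenotypeMatrix", calls = calls, map = map)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "individuals x",
      ncol(object@calls), "markers;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(object@calls))))
})

## ---------------------------------------------------------------------------
## PhenotypeTable
## ---------------------------------------------------------------------------

#' PhenotypeTable: disease status assignments
#'
#' Maps individual ids to a status from the closed set
#' affected / control / carrier / wild_type / unknown.
#'
#' @slot status data.frame with columns `id`, `status`.
#' @export
setClass("PhenotypeTable", representation(status = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  s <- object@status
  if (!all(c("id", "status") %in% names(s)))
    return("status must have columns id, status")
  if (anyDuplicated(s$id))
    return("each individual may appear only once")
  if (!all(s$status %in% .GENO_STATUSES))
    return(paste("status must be one of:",
                 paste(.GENO_STATUSES, collapse = ", ")))
  TRUE
})

#' Construct a PhenotypeTable
#'
#' @param ids character vector of individual ids.
#' @param statuses character vector (recycled if length 1) of statuses from
#'   affected/control/carrier/wild_type/unknown.
#' @return A [PhenotypeTable-class] object.
#' @export
PhenotypeTable <- function(ids, statuses) {
  if (length(statuses) == 1L) statuses <- rep(statuses, length(ids))
  new("PhenotypeTable",
      status = data.frame(id = as.character(ids),
                          status = as.character(statuses),
                          stringsAsFactors = FALSE))
}

setMethod("show", "PhenotypeTable", function(object) {
  tab <- table(factor(object@status$status, levels = .GENO_STATUSES))
  cat("PhenotypeTable:", nrow(object@status), "individuals (",
      paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
            collapse = ", "), ")\n")
})

## ---------------------------------------------------------------------------
## VariantTable
## ---------------------------------------------------------------------------

#' VariantTable: biallelic variant records with per-animal genotypes
#'
#' One row per (site, ALT allele) pair; multi-allelic VCF sites are split on
#' input. Genotypes are ALT-allele dosages (0 = hom ref, 1 = het, 2 = hom
#' alt, NA = missing). `id` is the known-variant identifier (`NA` when the
#' site is unknown to the reference database) and `chip` flags sites that
#' coincide with a genotyping-array marker.
#'
#' @slot variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `id`, `chip`.
#' @slot geno integer matrix, rows parallel to `variants`, columns = sample
#'   ids.
#' @export
setClass("VariantTable",
         representation(variants = "data.frame", geno = "matrix"))

setValidity("VariantTable", function(object) {
  v <- object@variants
  req <- c("chrom", "pos", "ref", "alt", "id", "chip")
  if (!all(req %in% names(v)))
    return(paste("variants must have columns:", paste(req, collapse = ", ")))
  if (nrow(v) != nrow(object@geno))
    return("geno must have one row per variant")
  if (nrow(v) > 0) {
    if (any(v$ref == v$alt))
      return("ref must differ from alt")
    if (!all(grepl("^[ACGT]+$", c(v$ref, v$alt))))
      return("alleles must be nonempty strings over A/C/G/T")
    o <- order(v$chrom, v$pos)
    if (!identical(o, seq_len(nrow(v))))
      return("variants must be sorted by (chrom, pos)")
  }
  if (is.null(colnames(object@geno)))
    return("geno must carry sample ids as colnames")
  g <- object@geno[!is.na(object@geno)]
  if (length(g) && !all(g %in% 0:2))
    return("genotypes must be 0, 1, 2 or NA")
  TRUE
})

#' Construct a VariantTable
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `id` (NA for unknown), `chip` (logical).
#' @param geno integer matrix of ALT dosages, one row per variant, columns
#'   named by sample.
#' @return A [VariantTable-class] object.
#' @export
VariantTable <- function(variants, geno) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  geno <- geno[o, , drop = FALSE]
  storage.mode(geno) <- "integer"
  rownames(variants) <- NULL
  rownames(geno) <- NULL
  new("VariantTable", variants = variants, geno = geno)
}

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable:", nrow(object@variants), "biallelic records,",
      ncol(object@geno), "samples;",
      sum(is.na(object@variants$id)), "unknown-ID,",
      sum(object@variants$chip), "chip-site\n")
})

## ---------------------------------------------------------------------------
## GeneModel
## ---------------------------------------------------------------------------

#' GeneModel: a coding transcript model with its CDS sequence
#'
#' CDS exons in ascending genomic order plus the spliced coding sequence in
#' transcript (5'->3') orientation; minus-strand models store the
#' reverse-complemented sequence so codon arithmetic is strand-free.
#'
#' @slot gene_id,tx_id character identifiers.
#' @slot chrom character contig name.
#' @slot strand "+" or "-".
#' @slot exon_starts,exon_ends numeric, 1-based inclusive, ascending.
#' @slot cds a [Biostrings::DNAString] of the spliced CDS (length divisible
#'   by 3).
#' @export
setClass("GeneModel",
         representation(gene_id = "character", tx_id = "character",
                        chrom = "character", strand = "character",
                        exon_starts = "numeric", exon_ends = "numeric",
                        cds = "ANY"))

setValidity("GeneModel", function(object) {
  s <- object@exon_starts; e <- object@exon_ends
  if (length(s) != length(e) || length(s) == 0)
    return("exon_starts/exon_ends must be nonempty and parallel")
  if (any(e < s)) return("exon end < start")
  if (is.unsorted(s, strictly = TRUE) && length(s) > 1)
    return("exons must be in ascending genomic order")
  if (length(s) > 1 && any(s[-1] <= e[-length(e)]))
    return("exons must not overlap")
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  len <- sum(e - s + 1)
  if (len != length(object@cds))
    return("CDS sequence length must equal summed exon widths")
  if (len %% 3 != 0) return("CDS length must be divisible by 3")
  TRUE
})

#' Construct a GeneModel
#'
#' @param gene_id,tx_id identifiers.
#' @param chrom contig name.
#' @param strand "+" or "-".
#' @param exon_starts,exon_ends CDS exon coordinates (1-based inclusive,
#'   ascending genomic order).
#' @param cds spliced coding sequence (character or DNAString), 5'->3' in
#'   transcript orientation.
#' @return A [GeneModel-class] object.
#' @export
GeneModel <- function(gene_id, tx_id, chrom, strand, exon_starts, exon_ends,
                      cds) {
  new("GeneModel", gene_id = gene_id, tx_id = tx_id, chrom = chrom,
      strand = strand, exon_starts = as.numeric(exon_starts),
      exon_ends = as.numeric(exon_ends),
      cds = Biostrings::DNAString(as.character(cds)))
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s) %s:%s-%s (%s), %d CDS exon(s), %d bp CDS\n",
              object@gene_id, object@tx_id, object@chrom,
              format(min(object@exon_starts), big.mark = ","),
              format(max(object@exon_ends), big.mark = ","),
              object@strand, length(object@exon_starts),
              length(object@cds)))
})

## ---------------------------------------------------------------------------
## HomozygosityInterval
## ---------------------------------------------------------------------------

#' HomozygosityInterval: a shared homozygous marker run
#'
#' A maximal run of consecutive markers at which every typed affected animal
#' is homozygous and all affected share the same allele — the footprint of an
#' identical-by-descent founder haplotype. `start_bp`/`end_bp` are the
#' positions of the first and last qualifying markers (1-based inclusive);
#' because the true segment breakpoints lie somewhere between the outermost
#' concordant marker and the first discordant one, the interval also carries
#' a search envelope (`flank_start_bp`/`flank_end_bp`, see
#' [searchRegion()]) delimited by the flanking discordant markers — the
#' region a variant search must cover.
#'
#' @slot chrom chromosome.
#' @slot start_bp,end_bp positions of the outermost member markers.
#' @slot flank_start_bp,flank_end_bp bounds of the search envelope (NA
#'   falls back to the marker span).
#' @slot marker_ids member markers, in map order.
#' @slot shared_allele integer 1/2 per member marker: which map allele all
#'   affected are homozygous for.
#' @slot score sum of the member markers' likelihood-ratio statistics.
#' @export
setClass("HomozygosityInterval",
         representation(chrom = "character", start_bp = "numeric",
                        end_bp = "numeric", flank_start_bp = "numeric",
                        flank_end_bp = "numeric", marker_ids = "character",
                        shared_allele = "integer", score = "numeric"),
         prototype(flank_start_bp = NA_real_, flank_end_bp = NA_real_))

setValidity("HomozygosityInterval", function(object) {
  if (length(object@marker_ids) != length(object@shared_allele))
    return("shared_allele must parallel marker_ids")
  if (length(object@marker_ids) == 0) return("interval must be nonempty")
  if (!all(object@shared_allele %in% 1:2))
    return("shared_allele must be 1 or 2")
  if (object@end_bp < object@start_bp) return("end_bp < start_bp")
  if (!is.na(object@flank_start_bp) &&
      object@flank_start_bp > object@start_bp)
    return("flank_start_bp must not exceed start_bp")
  if (!is.na(object@flank_end_bp) && object@flank_end_bp < object@end_bp)
    return("flank_end_bp must not precede end_bp")
  TRUE
})

#' Search envelope of a homozygosity interval
#'
#' The maximal region compatible with the shared segment: from just after
#' the nearest discordant marker on the left to just before the nearest
#' discordant marker on the right (falling back to the outermost member
#' markers when no flanking marker was scanned). Variant searches over a
#' mapped interval should use this envelope, since the true breakpoints lie
#' beyond the outermost concordant markers.
#'
#' @param interval a [HomozygosityInterval-class].
#' @return numeric of length 2: start and end (1-based inclusive).
#' @export
searchRegion <- function(interval) {
  c(if (is.na(interval@flank_start_bp)) interval@start_bp
    else interval@flank_start_bp,
    if (is.na(interval@flank_end_bp)) interval@end_bp
    else interval@flank_end_bp)
}

setMethod("show", "HomozygosityInterval", function(object) {
  cat(sprintf(
    "HomozygosityInterval %s:%s-%s (%.2f Mb), %d markers, score %.1f\n",
    object@chrom, format(object@start_bp, big.mark = ","),
    format(object@end_bp, big.mark = ","),
    (object@end_bp - object@start_bp) / 1e6,
    length(object@marker_ids), object@score))
  region <- searchRegion(object)
  if (region[1] != object@start_bp || region[2] != object@end_bp)
    cat(sprintf("  search envelope: %s-%s\n",
                format(region[1], big.mark = ","),
                format(region[2], big.mark = ",")))
})

#' Number of markers in a homozygosity interval
#' @param interval a [HomozygosityInterval-class].
#' @return integer count of member markers.
#' @export
nMarkers <- function(interval) length(interval@marker_ids)

## ---------------------------------------------------------------------------
## CascadeReport
## ---------------------------------------------------------------------------

#' CascadeReport: step counts and final candidates of the filter cascade
#'
#' Records, in order, the number of variants remaining after each
#' prioritisation step (interval, genotype_pattern, not_in_known_ids,
#' not_on_chip, nonsynonymous) together with the annotated, ranked final
#' candidate list.
#'
#' @slot steps data.frame with columns `step`, `n_remaining`.
#' @slot candidates data.frame of surviving variants with consequence
#'   columns.
#' @export
setClass("CascadeReport",
         representation(steps = "data.frame", candidates = "data.frame"))

setValidity("CascadeReport", function(object) {
  s <- object@steps
  if (!all(c("step", "n_remaining") %in% names(s)))
    return("steps must have columns step, n_remaining")
  if (!identical(s$step, .CASCADE_STEPS))
    return(paste("steps must be exactly:",
                 paste(.CASCADE_STEPS, collapse = ", ")))
  if (any(diff(s$n_remaining) > 0))
    return("n_remaining must be nonincreasing")
  TRUE
})

setMethod("show", "CascadeReport", function(object) {
  cat(formatCascadeReport(object), sep = "\n")
})

## ---------------------------------------------------------------------------
## HaplotypeSignature
## ---------------------------------------------------------------------------

#' HaplotypeSignature: the disease-associated marker haplotype
#'
#' The marker panel of an indirect carrier test: for each marker of the
#' mapped interval, the allele riding on the disease haplotype. An animal is
#' called from its unphased chip genotypes against this signature.
#'
#' @slot chrom chromosome.
#' @slot marker_ids signature markers in map order.
#' @slot pos their positions.
#' @slot risk_allele integer 1/2 per marker.
#' @slot min_informative minimum number of non-missing signature markers
#'   required to emit a call.
#' @export
setClass("HaplotypeSignature",
         representation(chrom = "character", marker_ids = "character",
                        pos = "numeric", risk_allele = "integer",
                        min_informative = "integer"))

setValidity("HaplotypeSignature", function(object) {
  n <- length(object@marker_ids)
  if (n == 0) return("signature must contain at least one marker")
  if (length(object@risk_allele) != n || length(object@pos) != n)
    return("risk_allele and pos must parallel marker_ids")
  if (!all(object@risk_allele %in% 1:2))
    return("risk_allele must be 1 or 2")
  if (object@min_informative < 1 || object@min_informative > n)
    return("min_informative must be in [1, number of markers]")
  TRUE
})

setMethod("show", "HaplotypeSignature", function(object) {
  cat(sprintf(
    "HaplotypeSignature: %d markers on %s (%s-%s), min_informative = %d\n",
    length(object@marker_ids), object@chrom,
    format(min(object@pos), big.mark = ","),
    format(max(object@pos), big.mark = ","), object@min_informative))
})

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Pedigree: individuals of a gene-drop simulation
#'
#' One row per individual with parentage, sex, discrete generation and the
#' number of causal-allele copies carried (0/1/2; 2 implies affected under
#' full penetrance). Transmission mosaics (crossover breakpoints and the
#' starting parental haplotype of each gamete, sampled under a Haldane map)
#' are stored alongside so any set of loci can later be dropped through the
#' same inheritance history.
#'
#' @slot individuals data.frame with columns `id`, `sire`, `dam`, `sex`,
#'   `generation`, `causal_genotype` (parents NA for founders).
#' @slot gametes list parallel to individuals: NULL for founders, else
#'   `list(pat = list(breaks, start), mat = list(breaks, start))`.
#' @slot hap_causal logical matrix (individuals x 2): whether each haplotype
#'   carries the causal allele.
#' @slot chrom_length simulated chromosome length in bp.
#' @export
setClass("Pedigree",
         representation(individuals = "data.frame", gametes = "list",
                        hap_causal = "matrix", chrom_length = "numeric"))

setValidity("Pedigree", function(object) {
  ind <- object@individuals
  req <- c("id", "sire", "dam", "sex", "generation", "causal_genotype")
  if (!all(req %in% names(ind)))
    return(paste("individuals must have columns:",
                 paste(req, collapse = ", ")))
  if (anyDuplicated(ind$id)) return("duplicated individual ids")
  if (length(object@gametes) != nrow(ind))
    return("gametes must parallel individuals")
  idx <- match(ind$sire, ind$id)
  idx2 <- match(ind$dam, ind$id)
  ok <- is.na(ind$sire) |
    (!is.na(idx) & ind$generation[idx] < ind$generation)
  ok2 <- is.na(ind$dam) |
    (!is.na(idx2) & ind$generation[idx2] < ind$generation)
  if (!all(ok & ok2))
    return("parents must exist and belong to earlier generations")
  if (!all(ind$causal_genotype %in% 0:2))
    return("causal_genotype must be 0, 1 or 2")
  TRUE
})

setMethod("show", "Pedigree", function(object) {
  ind <- object@individuals
  cat(sprintf(
    "Pedigree: %d individuals, generations 0-%d; carriers: %d, affected: %d\n",
    nrow(ind), max(ind$generation), sum(ind$causal_genotype == 1),
    sum(ind$causal_genotype == 2)))
})

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' SimulationConfig: parameters of the gene-drop study simulator
#'
#' Defaults emulate the mapped study design at desk scale: a cohort of 12
#' affected calves and 123 unaffected controls genotyped on a chip scaled
#' down to 3,000 markers over a single 100 Mb chromosome, a heavily used
#' carrier founder sire ~8 generations back, and a sequenced quartet (two
#' affected, one obligate carrier, one wild type) whose variant table
#' carries an implanted causal missense variant.
#'
#' @slot seed master seed; split internally into named substreams.
#' @slot n_generations generations dropped below the founders.
#' @slot n_founder_males,n_founder_females generation-0 founders.
#' @slot founders_per_generation unrelated immigrants entering each later
#'   generation (half of each sex).
#' @slot litter_mean mean offspring per dam per generation (Poisson).
#' @slot founder_sire_usage_fraction probability a mating is sired by the
#'   carrier founder.
#' @slot chrom_name,chrom_length simulated chromosome.
#' @slot n_chip_markers chip markers placed uniformly on the chromosome.
#' @slot recomb_rate cM per Mb (Haldane, no interference).
#' @slot allele_freq_beta shape parameters of the Beta distribution of
#'   chip-marker allele-1 frequencies.
#' @slot ld_copy_prob first-order Markov adjacency-copy probability used
#'   when sampling founder haplotypes (background LD).
#' @slot causal_pos position of the implanted causal variant.
#' @slot n_background_variants background variants in the quartet table.
#' @slot known_id_probability probability a background variant carries a
#'   dbSNP-like identifier.
#' @slot chip_overlap_probability probability a background variant is also
#'   a chip site.
#' @slot fraction_coding fraction of background variants placed in CDS.
#' @slot fraction_nonsynonymous fraction of coding background variants
#'   engineered to be nonsynonymous.
#' @slot variant_freq_beta shape parameters of the Beta distribution of
#'   background-variant founder allele frequencies.
#' @slot n_genes synthetic gene models placed on the chromosome.
#' @slot genotyping_error per-call error probability for chip extraction.
#' @slot n_affected,n_controls default cohort sizes.
#' @export
setClass("SimulationConfig",
         representation(seed = "integer", n_generations = "integer",
                        n_founder_males = "integer",
                        n_founder_females = "integer",
                        founders_per_generation = "integer",
                        litter_mean = "numeric",
                        founder_sire_usage_fraction = "numeric",
                        chrom_name = "character", chrom_length = "numeric",
                        n_chip_markers = "integer", recomb_rate = "numeric",
                        allele_freq_beta = "numeric",
                        ld_copy_prob = "numeric", causal_pos = "numeric",
                        n_background_variants = "integer",
                        known_id_probability = "numeric",
                        chip_overlap_probability = "numeric",
                        fraction_coding = "numeric",
                        fraction_nonsynonymous = "numeric",
                        variant_freq_beta = "numeric",
                        n_genes = "integer", genotyping_error = "numeric",
                        n_affected = "integer", n_controls = "integer"))

setValidity("SimulationConfig", function(object) {
  pr <- c(object@founder_sire_usage_fraction, object@known_id_probability,
          object@chip_overlap_probability, object@fraction_coding,
          object@fraction_nonsynonymous, object@ld_copy_prob,
          object@genotyping_error)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
  if (object@n_generations < 2) return("n_generations must be >= 2")
  if (object@causal_pos < 1 || object@causal_pos > object@chrom_length)
    return("causal_pos must lie within the chromosome")
  if (object@recomb_rate < 0) return("recomb_rate must be >= 0")
  if (object@litter_mean <= 0) return("litter_mean must be > 0")
  if (length(object@allele_freq_beta) != 2 ||
      length(object@variant_freq_beta) != 2)
    return("Beta parameter vectors must have length 2")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig (seed %d): %d generations, founder sire usage %.2f\n",
    "  chromosome %s: %s bp, %d chip markers, %.2g cM/Mb, causal @ %s\n",
    "  cohort %d affected + %d controls; %d background variants\n"),
    object@seed, object@n_generations, object@founder_sire_usage_fraction,
    object@chrom_name, format(object@chrom_length, big.mark = ","),
    object@n_chip_markers, object@recomb_rate,
    format(object@causal_pos, big.mark = ","),
    object@n_affected, object@n_controls, object@n_background_variants))
})

## ---------------------------------------------------------------------------
## PhasedGenotypes
## ---------------------------------------------------------------------------

#' PhasedGenotypes: projected haplotype alleles over a locus set
#'
#' The result of dropping founder haplotypes through the pedigree's recorded
#' transmission mosaics at a given set of loci. Haplotype rows 2i-1 and 2i
#' hold the paternal and maternal haplotypes of pedigree individual i.
#' Allele coding at chip markers is 1/2 (map allele1/allele2); at variant
#' loci it is 0/1 (ref/alt).
#'
#' @slot pedigree the [Pedigree-class] the drop ran on.
#' @slot loci data.frame with columns `id`, `chrom`, `pos`.
#' @slot haplotypes integer matrix (2 x individuals) x loci.
#' @export
setClass("PhasedGenotypes",
         representation(pedigree = "Pedigree", loci = "data.frame",
                        haplotypes = "matrix"))

setValidity("PhasedGenotypes", function(object) {
  if (nrow(object@haplotypes) !=
      2 * nrow(object@pedigree@individuals))
    return("haplotypes must have two rows per pedigree individual")
  if (ncol(object@haplotypes) != nrow(object@loci))
    return("haplotype columns must parallel loci")
  TRUE
})

setMethod("show", "PhasedGenotypes", function(object) {
  cat("PhasedGenotypes:", nrow(object@haplotypes), "haplotypes x",
      nrow(object@loci), "loci\n")
})

## ---------------------------------------------------------------------------
## SimulatedStudy
## ---------------------------------------------------------------------------

#' SimulatedStudy: all artefacts of one simulated mapping study
#'
#' Bundles the pedigree, marker map, phased chip haplotypes, cohort and
#' sequencing-quartet phenotype tables, quartet variant table, synthetic
#' gene models and the ground truth needed to validate downstream analyses.
#'
#' @slot config the [SimulationConfig-class] used.
#' @slot pedigree the [Pedigree-class].
#' @slot map the chip [MarkerMap-class].
#' @slot phased [PhasedGenotypes-class] at the chip markers.
#' @slot cohort [PhenotypeTable-class]: affected + control animals.
#' @slot quartet [PhenotypeTable-class]: the sequenced four animals.
#' @slot variants [VariantTable-class] for the quartet (may be empty).
#' @slot models list of [GeneModel-class].
#' @slot truth list: causal_pos, causal_gene, causal_cds_pos, founder_id,
#'   carrier ids, chip-site positions.
#' @export
setClass("SimulatedStudy",
         representation(config = "SimulationConfig", pedigree = "Pedigree",
                        map = "MarkerMap", phased = "PhasedGenotypes",
                        cohort = "PhenotypeTable",
                        quartet = "PhenotypeTable",
                        variants = "VariantTable", models = "list",
                        truth = "list"))

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy (seed", object@config@seed, ")\n")
  show(object@pedigree)
  show(object@map)
  show(object@cohort)
  if (nrow(object@variants@variants) > 0) show(object@variants)
})
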