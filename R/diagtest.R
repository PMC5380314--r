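## Haplotype-based indirect carrier test: derive the disease-associated
## marker haplotype from the mapped interval, then classify animals from
## unphased chip genotypes. Affected animals are homozygous for the risk
## haplotype by construction, so the signature is read directly off any
## affected cohort member; carrier calls rest on compatibility logic
## (het-or-hom-risk everywhere, het somewhere) rather than phasing. Being
## indirect, the test misclassifies recombinant haplotypes that carry the
## marker signature without the causal allele — the reason such tests are
## eventually replaced by a direct mutation assay.

#' Derive the disease-haplotype signature from a mapped interval
#'
#' The risk allele at each signature marker is the interval's shared
#' homozygous allele. As a guard, markers at which any affected animal is
#' typed and not homozygous for that allele are excluded with a warning
#' (none exist for an interval produced by [detectIntervals()]).
#'
#' @param genotypes the training [GenotypeMatrix-class].
#' @param interval a [HomozygosityInterval-class] from the same cohort.
#' @param affected_ids the training affected animals.
#' @param min_informative minimum number of non-missing signature markers
#'   required for a call; default 80% of the signature markers.
#' @return A [HaplotypeSignature-class].
#' @export
deriveSignature <- function(genotypes, interval, affected_ids,
                            min_informative = NULL) {
  if (length(interval@marker_ids) == 0)
    stop("configuration error: empty interval")
  g <- genotypes@calls[affected_ids, interval@marker_ids, drop = FALSE]
  expect <- ifelse(interval@shared_allele == 1L, 2L, 0L)
  ok <- colSums(!sweep(g, 2, expect, `==`), na.rm = TRUE) == 0
  if (!all(ok)) {
    warning(sum(!ok), " interval marker(s) excluded from the signature: ",
            "a typed affected animal is not homozygous for the shared ",
            "allele")
  }
  ids <- interval@marker_ids[ok]
  risk <- interval@shared_allele[ok]
  m <- genotypes@map@markers
  pos <- m$pos[match(ids, m$marker_id)]
  n <- length(ids)
  if (n == 0)
    stop("configuration error: no usable signature marker")
  if (is.null(min_informative))
    min_informative <- as.integer(ceiling(0.8 * n))
  if (min_informative > n)
    stop("configuration error: min_informative (", min_informative,
         ") exceeds the number of signature markers (", n, ")")
  new("HaplotypeSignature", chrom = interval@chrom, marker_ids = ids,
      pos = pos, risk_allele = as.integer(risk),
      min_informative = as.integer(min_informative))
}

#' Classify animals against a haplotype signature
#'
#' For each animal, over its non-missing signature markers: homozygous for
#' the risk allele at all markers gives `affected_genotype`; heterozygous
#' or homozygous-risk at all markers with at least one heterozygote gives
#' `carrier`; homozygous for the non-risk allele at any marker gives
#' `non_carrier` (one non-risk homozygote excludes an intact risk
#' haplotype); fewer than `min_informative` non-missing markers gives
#' `ambiguous`.
#'
#' @param genotypes a [GenotypeMatrix-class] covering the signature
#'   markers (missing calls allowed).
#' @param signature a [HaplotypeSignature-class].
#' @return named character vector of calls, one per matrix row, with
#'   values in affected_genotype / carrier / non_carrier / ambiguous.
#' @export
classifyAnimals <- function(genotypes, signature) {
  missing_m <- setdiff(signature@marker_ids,
                       colnames(genotypes@calls))
  if (length(missing_m))
    stop("genotype matrix does not cover signature marker(s): ",
         paste(missing_m, collapse = ", "))
  g <- genotypes@calls[, signature@marker_ids, drop = FALSE]
  ## risk-allele dosage: flip coding where the risk allele is allele 2
  flip <- signature@risk_allele == 2L
  rd <- g
  rd[, flip] <- 2L - g[, flip, drop = FALSE]
  n_inf <- rowSums(!is.na(rd))
  n_hom_risk <- rowSums(rd == 2L, na.rm = TRUE)
  n_het <- rowSums(rd == 1L, na.rm = TRUE)
  n_hom_non <- rowSums(rd == 0L, na.rm = TRUE)
  call <- rep("ambiguous", nrow(rd))
  informative <- n_inf >= signature@min_informative
  call[informative & n_hom_risk == n_inf & n_inf > 0] <- "affected_genotype"
  call[informative & n_hom_non == 0 & n_het >= 1] <- "carrier"
  call[informative & n_hom_non >= 1] <- "non_carrier"
  setNames(call, rownames(rd))
}

#' Map true causal genotypes to expected carrier-test calls
#'
#' Convenience for validation against simulator truth: 2 ->
#' affected_genotype, 1 -> carrier, 0 -> non_carrier.
#'
#' @param causal_genotype integer vector of causal-allele copy numbers.
#' @return character vector of expected calls.
#' @export
expectedCallFromTruth <- function(causal_genotype) {
  c("non_carrier", "carrier", "affected_genotype")[causal_genotype + 1L]
}

#' Write and read a haplotype signature as TSV
#'
#' @param signature a [HaplotypeSignature-class].
#' @param path file path.
#' @return `writeSignature`: invisibly, `path`; `readSignature`: the
#'   [HaplotypeSignature-class].
#' @export
writeSignature <- function(signature, path) {
  df <- data.frame(chrom = signature@chrom,
                   marker_id = signature@marker_ids, pos = signature@pos,
                   risk_allele = signature@risk_allele,
                   min_informative = signature@min_informative,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric",
                                  "integer", "integer"))
  new("HaplotypeSignature", chrom = df$chrom[1],
      marker_ids = df$marker_id, pos = df$pos,
      risk_allele = df$risk_allele,
      min_informative = df$min_informative[1])
}
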