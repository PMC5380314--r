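## VCF 4.2 reading (via vcfR) and plain-text writing for quartet variant
## tables. Multi-allelic sites are split into one biallelic record per ALT
## allele; in a split record, copies of any other ALT allele count as
## reference. A CHIP flag in INFO round-trips the chip-site annotation.

#' Read a VCF into a VariantTable
#'
#' Parses a VCF 4.2 file (GT required in FORMAT), splits multi-allelic
#' sites into biallelic records and codes genotypes as ALT-allele dosage
#' (0/1/2, `NA` for missing). Phase separators are treated as unphased.
#' The ID field "." becomes `NA` (unknown to the reference database) and a
#' `CHIP` INFO flag sets the chip-site column.
#'
#' @param vcf_path path to a plain-text VCF.
#' @param sample_roles optional [PhenotypeTable-class]; every id named in it
#'   must be a sample of the VCF, otherwise a configuration error is raised.
#' @return A [VariantTable-class], sorted by (chrom, pos).
#' @export
readVcfVariants <- function(vcf_path, sample_roles = NULL) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_roles)) {
    missing <- setdiff(sample_roles@status$id, samples)
    if (length(missing))
      stop("configuration error: sample(s) named in roles absent from ",
           "VCF header: ", paste(missing, collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("format error: GT not present in FORMAT")

  n <- nrow(fix)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    calls <- strsplit(gsub("|", "/", gt[i, ], fixed = TRUE), "/",
                      fixed = TRUE)
    info <- fix[i, "INFO"]
    chip <- !is.na(info) && grepl("(^|;)CHIP(;|$|=)", info)
    id <- fix[i, "ID"]
    if (is.na(id) || id == ".") id <- NA_character_
    out <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      dos <- vapply(calls, function(a) {
        if (length(a) == 0 || any(is.na(a)) || any(a == "."))
          return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      out[[k]] <- list(
        row = data.frame(chrom = fix[i, "CHROM"],
                         pos = as.numeric(fix[i, "POS"]),
                         ref = fix[i, "REF"], alt = alts[k], id = id,
                         chip = chip, stringsAsFactors = FALSE),
        dos = dos)
    }
    recs[[i]] <- out
  }
  recs <- unlist(recs, recursive = FALSE)
  variants <- do.call(rbind, lapply(recs, `[[`, "row"))
  geno <- do.call(rbind, lapply(recs, `[[`, "dos"))
  colnames(geno) <- samples
  VariantTable(variants, geno)
}

#' Write a VariantTable as a plain-text VCF 4.2
#'
#' Deterministic text serialisation (byte-identical for identical input):
#' unknown IDs are written as ".", chip sites carry a `CHIP` INFO flag and
#' genotypes are unphased GT strings.
#'
#' @param x a [VariantTable-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeVcfVariants <- function(x, path) {
  v <- x@variants
  g <- x@geno
  gt_str <- matrix("./.", nrow(g), ncol(g))
  gt_str[!is.na(g) & g == 0] <- "0/0"
  gt_str[!is.na(g) & g == 1] <- "0/1"
  gt_str[!is.na(g) & g == 2] <- "1/1"
  gt_str[is.na(g)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CHIP,Number=0,Type=Flag,Description=\"Site present on the genotyping array\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(g)), collapse = "\t"))
  body <- if (nrow(v) == 0) character(0) else {
    info <- ifelse(v$chip, "CHIP", ".")
    id <- ifelse(is.na(v$id), ".", v$id)
    paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE), id,
          v$ref, v$alt, ".", ".", info, "GT",
          apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Accessors for VariantTable
#'
#' @param x a [VariantTable-class].
#' @return `variantInfo`: the data.frame of variant fields; `variantGeno`:
#'   the ALT-dosage matrix; `nVariants`: the record count.
#' @export
variantInfo <- function(x) x@variants

#' @rdname variantInfo
#' @export
variantGeno <- function(x) x@geno

#' @rdname variantInfo
#' @export
nVariants <- function(x) nrow(x@variants)
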