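## Coding-consequence annotation of single-nucleotide variants against
## GeneModel transcripts, using the standard genetic code.

#' Consequence: predicted coding effect of a variant
#'
#' @slot consequence_class one of intergenic, intronic, synonymous,
#'   missense, nonsense, stop_lost, non_coding.
#' @slot gene gene id (NA outside genes).
#' @slot cds_pos 1-based coding-nucleotide index (NA outside CDS).
#' @slot codon_index 1-based codon number, `ceiling(cds_pos / 3)`.
#' @slot codon_offset 0-based position within the codon,
#'   `(cds_pos - 1) %% 3`.
#' @slot ref_aa,alt_aa one-letter amino acids ("*" = stop).
#' @slot hgvs_c,hgvs_p compact HGVS-style labels (e.g. c.376C>T, p.R126C).
#' @export
setClass("Consequence",
         representation(consequence_class = "character", gene = "character",
                        cds_pos = "integer", codon_index = "integer",
                        codon_offset = "integer", ref_aa = "character",
                        alt_aa = "character", hgvs_c = "character",
                        hgvs_p = "character"))

setValidity("Consequence", function(object) {
  if (!object@consequence_class %in% .CONSEQ_CLASSES)
    return("unknown consequence class")
  if (!is.na(object@cds_pos)) {
    if (object@codon_index != ceiling(object@cds_pos / 3))
      return("codon_index must equal ceiling(cds_pos / 3)")
    if (object@codon_offset != (object@cds_pos - 1) %% 3)
      return("codon_offset must equal (cds_pos - 1) mod 3")
  }
  TRUE
})

setMethod("show", "Consequence", function(object) {
  if (is.na(object@cds_pos)) {
    cat("Consequence:", object@consequence_class,
        if (!is.na(object@gene)) paste0("(", object@gene, ")") else "",
        "\n")
  } else {
    cat(sprintf("Consequence: %s in %s — %s / %s (codon %d)\n",
                object@consequence_class, object@gene, object@hgvs_c,
                object@hgvs_p, object@codon_index))
  }
})

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("invalid codon: ", codon)
  aa
}

## First gene model whose span contains the position; NULL when intergenic.
.modelAtPosition <- function(models, chrom, pos) {
  for (m in models) {
    if (m@chrom != chrom) next
    if (pos >= min(m@exon_starts) && pos <= max(m@exon_ends))
      return(list(model = m,
                  in_exon = any(pos >= m@exon_starts & pos <= m@exon_ends)))
  }
  NULL
}

## Genomic position -> 1-based coding-nucleotide index (strand-aware).
.cdsProject <- function(model, pos) {
  widths <- model@exon_ends - model@exon_starts + 1
  j <- which(pos >= model@exon_starts & pos <= model@exon_ends)
  if (length(j) == 0) return(NULL)
  if (model@strand == "+") {
    cds_pos <- sum(widths[seq_len(j - 1)]) + (pos - model@exon_starts[j]) + 1
  } else {
    after <- if (j < length(widths)) sum(widths[(j + 1):length(widths)])
             else 0
    cds_pos <- after + (model@exon_ends[j] - pos) + 1
  }
  list(cds_pos = as.integer(cds_pos))
}

#' Annotate the coding consequence of a single-nucleotide variant
#'
#' Projects a genomic SNV into transcript coordinates (strand-aware: on the
#' minus strand the coding base is the complement and coding positions
#' count from the transcript 5' end), retrieves the affected codon from the
#' model's CDS, applies the standard genetic code and classifies the change
#' as synonymous, missense, nonsense or stop_lost. Positions inside a gene
#' span but outside its CDS exons are intronic; positions in no model are
#' intergenic. When several models contain the position the first one wins.
#'
#' @param variant list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` (single nucleotides; indels raise an unsupported-variant error).
#' @param models list of [GeneModel-class].
#' @return A [Consequence-class] object.
#' @examples
#' m <- GeneModel("G1", "G1.t1", "7", "+", 101, 109, "ATGCGCTAA")
#' annotateConsequence(list(chrom = "7", pos = 104, ref = "C", alt = "T"),
#'                     list(m))
#' @export
annotateConsequence <- function(variant, models) {
  v <- as.list(variant)
  if (nchar(v$ref) != 1 || nchar(v$alt) != 1)
    stop("unsupported-variant error: only single-nucleotide variants can ",
         "be classified; got ", v$ref, ">", v$alt)
  blank <- function(class, gene = NA_character_) {
    new("Consequence", consequence_class = class, gene = gene,
        cds_pos = NA_integer_, codon_index = NA_integer_,
        codon_offset = NA_integer_, ref_aa = NA_character_,
        alt_aa = NA_character_, hgvs_c = NA_character_,
        hgvs_p = NA_character_)
  }
  hit <- .modelAtPosition(models, v$chrom, v$pos)
  if (is.null(hit)) return(blank("intergenic"))
  m <- hit$model
  if (!hit$in_exon) return(blank("intronic", m@gene_id))

  proj <- .cdsProject(m, v$pos)
  cds_pos <- proj$cds_pos
  cds_chr <- as.character(m@cds)
  cds_ref <- substr(cds_chr, cds_pos, cds_pos)
  exp_ref <- if (m@strand == "+") v$ref else .complementBase(v$ref)
  if (cds_ref != exp_ref)
    warning("reference allele ", v$ref, " at ", v$chrom, ":", v$pos,
            " disagrees with model CDS base ", cds_ref,
            "; using the model sequence")
  cds_alt <- if (m@strand == "+") v$alt else .complementBase(v$alt)

  ci <- as.integer(ceiling(cds_pos / 3))
  off <- as.integer((cds_pos - 1) %% 3)
  codon <- substr(cds_chr, 3 * ci - 2, 3 * ci)
  alt_codon <- codon
  substr(alt_codon, off + 1, off + 1) <- cds_alt
  ref_aa <- .translateCodon(codon)
  alt_aa <- .translateCodon(alt_codon)
  class <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "nonsense"
  else if (ref_aa == "*") "stop_lost"
  else "missense"
  new("Consequence", consequence_class = class, gene = m@gene_id,
      cds_pos = cds_pos, codon_index = ci, codon_offset = off,
      ref_aa = ref_aa, alt_aa = alt_aa,
      hgvs_c = sprintf("c.%d%s>%s", cds_pos, cds_ref, cds_alt),
      hgvs_p = sprintf("p.%s%d%s", ref_aa, ci, alt_aa))
}

#' Amino acids replaced by an in-frame complex indel
#'
#' Length arithmetic for a coding replacement event: a reference segment of
#' whole codons is replaced by the segment obtained after deleting
#' `del_bp` and inserting `ins_bp` bases. The net length change must
#' preserve the reading frame. For example, a 15 bp insertion combined
#' with a 3 bp deletion inside a two-codon (6 bp) reference segment yields
#' a (6 - 3 + 15) / 3 = 6 amino-acid replacement segment.
#'
#' @param ref_bp length of the replaced reference segment in bp (a
#'   multiple of 3).
#' @param ins_bp inserted bases.
#' @param del_bp deleted bases.
#' @return integer: number of amino acids in the replacement segment.
#' @export
inFrameIndelAa <- function(ref_bp, ins_bp, del_bp) {
  if (ref_bp %% 3 != 0)
    stop("reference segment must be codon-aligned (multiple of 3 bp)")
  if ((ins_bp - del_bp) %% 3 != 0)
    stop("indel is frameshifting: net length change not a multiple of 3")
  new_bp <- ref_bp - del_bp + ins_bp
  if (new_bp < 0) stop("deletion longer than the reference segment")
  as.integer(new_bp / 3)
}

#' Column conservation score from a protein multiple alignment
#'
#' Fraction of non-gap sequences whose residue at the column equals the
#' majority residue; ties are broken toward the reference (first)
#' sequence's residue when it is among the tied residues, otherwise toward
#' the first tied residue in row order.
#'
#' @param alignment character vector of aligned, equal-length protein
#'   sequences (or an `AAStringSet`); "-" marks gaps.
#' @param column_index 1-based alignment column.
#' @return fraction in `[0, 1]`.
#' @export
conservationScore <- function(alignment, column_index) {
  seqs <- as.character(alignment)
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("aligned sequences must have equal length")
  if (column_index < 1 || column_index > w)
    stop("column_index out of range")
  res <- substr(seqs, column_index, column_index)
  nongap <- res[res != "-"]
  if (length(nongap) == 0)
    stop("undefined-score error: all-gap column")
  counts <- table(nongap)
  top <- names(counts)[counts == max(counts)]
  maj <- if (res[1] %in% top) res[1] else {
    first <- nongap[nongap %in% top][1]
    first
  }
  sum(nongap == maj) / length(nongap)
}
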