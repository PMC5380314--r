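## Gene-model I/O: GFF3 (rtracklayer) + genome FASTA (Biostrings).
## Only CDS features with a transcript Parent are used; the spliced CDS is
## stored 5'->3' in transcript orientation so downstream codon arithmetic
## is strand-free. Contig names must match exactly between GFF3 and FASTA;
## there is no alias table.

#' Read coding gene models from GFF3 + FASTA
#'
#' Groups CDS features by their transcript Parent, orders exons 5'->3',
#' extracts and splices the coding sequence from the genome (minus-strand
#' models are reverse-complemented), and drops models whose CDS length is
#' not divisible by 3 with a warning.
#'
#' @param gff_path GFF3 file with CDS features carrying a `Parent`
#'   attribute.
#' @param fasta_path genome FASTA covering all CDS coordinates.
#' @return A list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(gff_path, fasta_path) {
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  cds <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(cds) == 0) return(list())
  parent <- vapply(as.list(cds$Parent), function(p)
    if (length(p)) p[1] else NA_character_, character(1))
  if (anyNA(parent))
    stop("format error: CDS feature without a transcript Parent")

  ## transcript -> gene mapping from mRNA features when present
  tx <- gr[!is.na(gr$type) & gr$type %in% c("mRNA", "transcript")]
  tx_gene <- setNames(
    vapply(as.list(tx$Parent), function(p)
      if (length(p)) p[1] else NA_character_, character(1)),
    tx$ID)

  models <- list()
  for (t in unique(parent)) {
    ex <- cds[parent == t]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    strand <- as.character(GenomicRanges::strand(ex))[1]
    if (!strand %in% c("+", "-"))
      stop("format error: CDS for ", t, " lacks a strand")
    o <- order(GenomicRanges::start(ex))
    starts <- GenomicRanges::start(ex)[o]
    ends <- GenomicRanges::end(ex)[o]
    if (!chrom %in% names(genome))
      stop("format error: CDS of ", t, " references contig '", chrom,
           "' absent from FASTA")
    len <- sum(ends - starts + 1)
    if (len %% 3 != 0) {
      warning("gene model ", t, " excluded: CDS length ", len,
              " not divisible by 3")
      next
    }
    pieces <- lapply(seq_along(starts), function(j)
      Biostrings::subseq(genome[[chrom]], starts[j], ends[j]))
    seq <- do.call(Biostrings::xscat, pieces)
    if (strand == "-")
      seq <- Biostrings::reverseComplement(seq)
    gid <- tx_gene[t]
    if (is.na(gid)) gid <- t
    models[[length(models) + 1L]] <-
      GeneModel(gene_id = unname(gid), tx_id = t, chrom = chrom,
                strand = strand, exon_starts = starts, exon_ends = ends,
                cds = seq)
  }
  models
}

#' Write gene models as GFF3 and a genome FASTA
#'
#' Serialises gene/mRNA/CDS features via rtracklayer and reconstructs a
#' genome FASTA for the contig: CDS exon bases come from the models'
#' sequences (reverse-complemented back onto the plus strand for
#' minus-strand models); all other positions are written as `N`, which is
#' sufficient for coding-consequence annotation.
#'
#' @param models list of [GeneModel-class] on a single contig.
#' @param gff_path,fasta_path output paths.
#' @param chrom_length contig length for the FASTA.
#' @return Invisibly, the two paths.
#' @export
writeGeneModels <- function(models, gff_path, fasta_path, chrom_length) {
  stopifnot(length(models) > 0)
  chrom <- models[[1]]@chrom
  rows <- list()
  for (m in models) {
    g_start <- min(m@exon_starts); g_end <- max(m@exon_ends)
    w <- m@exon_ends - m@exon_starts + 1
    ## GFF3 phase: bases to trim from the exon start (in transcript
    ## orientation) to reach a codon boundary
    tx_order <- if (m@strand == "+") seq_along(w) else rev(seq_along(w))
    before <- cumsum(c(0, w[tx_order]))[seq_along(w)]
    phase <- integer(length(w))
    phase[tx_order] <- (3 - before %% 3) %% 3
    rows[[length(rows) + 1L]] <- data.frame(
      start = c(g_start, g_start, m@exon_starts),
      end = c(g_end, g_end, m@exon_ends),
      type = c("gene", "mRNA", rep("CDS", length(m@exon_starts))),
      ID = c(m@gene_id, m@tx_id,
             paste0(m@tx_id, ".cds", seq_along(m@exon_starts))),
      Parent = c(NA, m@gene_id, rep(m@tx_id, length(m@exon_starts))),
      phase = c(NA, NA, phase),
      strand = m@strand, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Parent <- tab$Parent
  gr$phase <- as.integer(tab$phase)
  rtracklayer::export(gr, gff_path, format = "gff3")

  at <- list(); pieces <- character(0)
  for (m in models) {
    cds_plus <- if (m@strand == "+") m@cds else
      Biostrings::reverseComplement(m@cds)
    off <- 0
    for (j in seq_along(m@exon_starts)) {
      w <- m@exon_ends[j] - m@exon_starts[j] + 1
      at[[length(at) + 1L]] <- c(m@exon_starts[j], m@exon_ends[j])
      pieces <- c(pieces,
                  as.character(Biostrings::subseq(cds_plus, off + 1,
                                                  off + w)))
      off <- off + w
    }
  }
  ranges <- IRanges::IRanges(vapply(at, `[`, numeric(1), 1),
                             vapply(at, `[`, numeric(1), 2))
  base <- Biostrings::DNAString(strrep("N", chrom_length))
  dna <- Biostrings::DNAStringSet(
    Biostrings::replaceAt(base, ranges, pieces))
  names(dna) <- chrom
  Biostrings::writeXStringSet(dna, fasta_path)
  invisible(c(gff = gff_path, fasta = fasta_path))
}
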