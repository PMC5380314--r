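## The candidate-variant prioritisation cascade: five ordered filters over
## the sequenced-quartet variant table — mapped interval, perfect
## genotype/phenotype pattern, absence from the known-variant database,
## absence from the genotyping chip, and nonsynonymous coding consequence.

#' Keep variants inside a homozygosity interval
#'
#' Retains records on the interval's chromosome whose position lies inside
#' its search envelope ([searchRegion()]; boundaries inclusive). The
#' envelope extends to the flanking discordant markers because the shared
#' segment's true breakpoints lie beyond the outermost concordant marker;
#' for intervals without flank information it equals the marker span
#' `start_bp..end_bp`.
#'
#' @param variants a [VariantTable-class].
#' @param interval a [HomozygosityInterval-class].
#' @return the filtered [VariantTable-class].
#' @export
filterRegion <- function(variants, interval) {
  v <- variants@variants
  region <- searchRegion(interval)
  keep <- v$chrom == interval@chrom & v$pos >= region[1] &
    v$pos <= region[2]
  VariantTable(v[keep, , drop = FALSE],
               variants@geno[keep, , drop = FALSE])
}

#' Keep variants with the recessive genotype/phenotype pattern
#'
#' Retains records at which every affected animal is homozygous for the
#' alternate allele, every wild-type animal homozygous for the reference
#' and every carrier heterozygous. With `allow_missing = FALSE` (default) a
#' missing genotype in any required animal removes the record; with `TRUE`
#' that animal is simply ignored for the record.
#'
#' @param variants a [VariantTable-class].
#' @param roles a [PhenotypeTable-class] over the variant table's samples;
#'   must contain at least one affected; carrier and wild_type are
#'   optional.
#' @param allow_missing missing-genotype policy.
#' @return the filtered [VariantTable-class].
#' @export
filterGenotypePattern <- function(variants, roles, allow_missing = FALSE) {
  g <- variants@geno
  aff <- intersect(affectedIds(roles), colnames(g))
  wt <- intersect(idsWithStatus(roles, "wild_type"), colnames(g))
  car <- intersect(idsWithStatus(roles, "carrier"), colnames(g))
  if (length(aff) == 0)
    stop("configuration error: no affected among the sequenced samples")
  checkGroup <- function(ids, expected) {
    if (length(ids) == 0)
      return(rep(TRUE, nrow(variants@variants)))
    sub <- g[, ids, drop = FALSE]
    hit <- sub == expected
    if (allow_missing) {
      hit[is.na(sub)] <- TRUE
    } else {
      hit[is.na(sub)] <- FALSE
    }
    rowSums(hit) == length(ids)
  }
  keep <- checkGroup(aff, 2L) & checkGroup(wt, 0L) & checkGroup(car, 1L)
  VariantTable(variants@variants[keep, , drop = FALSE],
               g[keep, , drop = FALSE])
}

#' Remove known-database and chip-site variants
#'
#' Two recorded sub-steps: first removes records whose identifier is in
#' `known_ids` (or any record with an assigned identifier when
#' `known_ids = NULL`), then removes records whose (chrom, pos) is in
#' `chip_positions`. Chip matching is positional only — alleles are not
#' compared.
#'
#' @param variants a [VariantTable-class].
#' @param known_ids character vector of known identifiers, or `NULL` to
#'   treat any assigned ID as known.
#' @param chip_positions data.frame with columns `chrom`, `pos` (may be
#'   empty or NULL).
#' @return list with `variants` (the filtered [VariantTable-class]),
#'   `n_after_known` and `n_after_chip`.
#' @export
filterKnown <- function(variants, known_ids = NULL, chip_positions = NULL) {
  v <- variants@variants
  known <- if (is.null(known_ids)) !is.na(v$id)
           else !is.na(v$id) & v$id %in% known_ids
  v1 <- v[!known, , drop = FALSE]
  g1 <- variants@geno[!known, , drop = FALSE]
  n_after_known <- nrow(v1)
  if (!is.null(chip_positions) && nrow(chip_positions) > 0) {
    key <- paste(v1$chrom, v1$pos)
    on_chip <- key %in% paste(chip_positions$chrom, chip_positions$pos)
  } else {
    on_chip <- rep(FALSE, nrow(v1))
  }
  out <- VariantTable(v1[!on_chip, , drop = FALSE],
                      g1[!on_chip, , drop = FALSE])
  list(variants = out, n_after_known = n_after_known,
       n_after_chip = nrow(out@variants))
}

#' Run the full prioritisation cascade
#'
#' Applies the five filters in order — mapped interval, genotype pattern,
#' not in the known-variant database, not on the genotyping chip,
#' nonsynonymous coding (missense, nonsense or stop_lost) — recording the
#' count after each step, and returns the surviving candidates annotated
#' and ranked: unknown-ID records first, then by descending cross-species
#' conservation score (when provided), then by position.
#'
#' @param variants a [VariantTable-class].
#' @param interval a [HomozygosityInterval-class].
#' @param roles a [PhenotypeTable-class] over the sequenced samples.
#' @param known_ids see [filterKnown()].
#' @param chip_positions see [filterKnown()].
#' @param models list of [GeneModel-class] for consequence annotation.
#' @param conservation optional named numeric vector of conservation
#'   scores keyed by "chrom:pos:ref:alt".
#' @param allow_missing missing-genotype policy of
#'   [filterGenotypePattern()].
#' @return A [CascadeReport-class].
#' @export
runCascade <- function(variants, interval, roles, known_ids = NULL,
                       chip_positions = NULL, models = list(),
                       conservation = NULL, allow_missing = FALSE) {
  s1 <- filterRegion(variants, interval)
  s2 <- filterGenotypePattern(s1, roles, allow_missing = allow_missing)
  s34 <- filterKnown(s2, known_ids, chip_positions)
  s4 <- s34$variants

  v <- s4@variants
  cons_class <- character(nrow(v))
  ann <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    ann[[i]] <- tryCatch(
      annotateConsequence(v[i, c("chrom", "pos", "ref", "alt")], models),
      error = function(e) NULL)   # indels etc. -> "other", never coding
    cons_class[i] <- if (is.null(ann[[i]])) "other"
                     else ann[[i]]@consequence_class
  }
  keep <- cons_class %in% c("missense", "nonsense", "stop_lost")
  v5 <- v[keep, , drop = FALSE]
  ann5 <- ann[keep]

  cand <- if (nrow(v5) == 0) {
    data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
               alt = character(0), id = character(0), gene = character(0),
               consequence = character(0), aa_substitution = character(0),
               hgvs_c = character(0), hgvs_p = character(0),
               conservation = numeric(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(v5$chrom, v5$pos, v5$ref, v5$alt, sep = ":")
    cs <- if (is.null(conservation)) rep(NA_real_, nrow(v5))
          else unname(conservation[key])
    data.frame(
      chrom = v5$chrom, pos = v5$pos, ref = v5$ref, alt = v5$alt,
      id = v5$id,
      gene = vapply(ann5, function(a) a@gene, character(1)),
      consequence = vapply(ann5, function(a) a@consequence_class,
                           character(1)),
      aa_substitution = vapply(ann5, function(a)
        paste0(a@ref_aa, "/", a@alt_aa), character(1)),
      hgvs_c = vapply(ann5, function(a) a@hgvs_c, character(1)),
      hgvs_p = vapply(ann5, function(a) a@hgvs_p, character(1)),
      conservation = cs, stringsAsFactors = FALSE)
  }
  if (nrow(cand) > 0) {
    o <- order(!is.na(cand$id),               # unknown-ID first
               -ifelse(is.na(cand$conservation), -Inf, cand$conservation),
               cand$chrom, cand$pos)
    cand <- cand[o, , drop = FALSE]
    rownames(cand) <- NULL
  }
  new("CascadeReport",
      steps = data.frame(
        step = .CASCADE_STEPS,
        n_remaining = c(nVariants(s1), nVariants(s2), s34$n_after_known,
                        s34$n_after_chip, nrow(cand)),
        stringsAsFactors = FALSE),
      candidates = cand)
}

#' Render a cascade report in the classic two-column layout
#'
#' @param report a [CascadeReport-class].
#' @return character vector of lines: a header and one
#'   "step description<TAB>count" line per filtering step.
#' @export
formatCascadeReport <- function(report) {
  labels <- c(
    interval = "Polymorphisms in the homozygous interval",
    genotype_pattern =
      "Polymorphisms homozygous in affected cattle, but absent in WT",
    not_in_known_ids = "Polymorphisms absent from known-variant database",
    not_on_chip = "Polymorphisms absent from SNP chip",
    nonsynonymous = "Non-synonymous coding polymorphisms")
  c("Filtering steps\tNo. polymorphisms",
    paste0(labels[report@steps$step], "\t", report@steps$n_remaining))
}

#' Accessors for CascadeReport
#'
#' @param report a [CascadeReport-class].
#' @return `cascadeSteps`: data.frame of (step, n_remaining);
#'   `cascadeCandidates`: the ranked candidate data.frame.
#' @export
cascadeSteps <- function(report) report@steps

#' @rdname cascadeSteps
#' @export
cascadeCandidates <- function(report) report@candidates
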