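## Homozygosity mapping: per-marker affected genotype counts, control
## allele frequency with extreme-value reporting, a Hardy-Weinberg
## likelihood-ratio statistic, and detection of shared homozygous intervals.
##
## The statistic is a trinomial genotype likelihood ratio computed from the
## affected counts (n1, n2, n3) and the clamped control allele-1 frequency
## f1 alone: the null fixes Hardy-Weinberg genotype probabilities at f1, the
## alternative maximises the same likelihood over the allele frequency. The
## clamping of exact 0 and 1 to 0.1 and 0.9 is what keeps the null
## log-likelihood finite at fixed or absent alleles.

#' Affected genotype counts at a marker
#'
#' Counts affected animals homozygous for map allele 1 (`n1`),
#' heterozygous (`n2`) and homozygous for allele 2 (`n3`); missing
#' genotypes are excluded from all three counts.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param affected_ids character vector of affected individuals (must be
#'   rows of the matrix).
#' @param marker_id marker to count at.
#' @return named integer vector `c(n1, n2, n3)`.
#' @export
markerCounts <- function(genotypes, affected_ids, marker_id) {
  if (!marker_id %in% colnames(genotypes@calls))
    stop("lookup error: unknown marker ", marker_id)
  bad <- setdiff(affected_ids, rownames(genotypes@calls))
  if (length(bad))
    stop("lookup error: unknown individual(s): ",
         paste(bad, collapse = ", "))
  g <- genotypes@calls[affected_ids, marker_id]
  c(n1 = sum(g == 2L, na.rm = TRUE), n2 = sum(g == 1L, na.rm = TRUE),
    n3 = sum(g == 0L, na.rm = TRUE))
}

#' Control allele-1 frequency with extreme-value reporting
#'
#' Computes the allele-1 frequency among typed controls,
#' `(2 hom1 + het) / (2 typed)`, then applies the reporting rule for exact
#' extremes: a raw frequency of 0 is reported as 0.1 and a raw frequency of
#' 1 as 0.9; all intermediate values are returned unchanged.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param control_ids character vector of control individuals.
#' @param marker_id marker of interest.
#' @return the (possibly clamped) allele-1 frequency.
#' @export
controlFreq <- function(genotypes, control_ids, marker_id) {
  if (!marker_id %in% colnames(genotypes@calls))
    stop("lookup error: unknown marker ", marker_id)
  g <- genotypes@calls[control_ids, marker_id]
  g <- g[!is.na(g)]
  if (length(g) == 0)
    stop("undefined-frequency error: no typed control at ", marker_id)
  f1 <- sum(g) / (2 * length(g))
  if (f1 == 0) 0.1 else if (f1 == 1) 0.9 else f1
}

## Trinomial genotype log-likelihood under Hardy-Weinberg at allele-1
## frequency p; zero-count terms contribute 0 regardless of p.
.trinomLogLik <- function(n1, n2, n3, p) {
  ll <- 0
  if (n1 > 0) ll <- ll + n1 * log(p^2)
  if (n2 > 0) ll <- ll + n2 * log(2 * p * (1 - p))
  if (n3 > 0) ll <- ll + n3 * log((1 - p)^2)
  ll
}

#' Likelihood-ratio statistic for affected genotype counts
#'
#' `lrt = 2 [sup_p l(p) - l(f1)]` where
#' `l(p) = n1 log p^2 + n2 log 2p(1-p) + n3 log (1-p)^2` is the trinomial
#' genotype log-likelihood under Hardy-Weinberg. The supremum is attained
#' at the affected-sample allele frequency `(2 n1 + n2) / 2(n1+n2+n3)`;
#' zero-count terms contribute 0, so the statistic is finite even at
#' boundary estimates. `f1` must already be clamped away from 0 and 1.
#'
#' @param counts numeric vector `(n1, n2, n3)` with sum >= 1.
#' @param f1 control allele-1 frequency in the open interval (0, 1).
#' @return the nonnegative statistic.
#' @export
markerLrt <- function(counts, f1) {
  n1 <- counts[[1]]; n2 <- counts[[2]]; n3 <- counts[[3]]
  n <- n1 + n2 + n3
  if (n < 1) stop("counts must sum to at least 1")
  if (!is.finite(f1) || f1 <= 0 || f1 >= 1)
    stop("domain error: f1 must lie strictly inside (0, 1); ",
         "clamp extreme frequencies upstream")
  p_hat <- (2 * n1 + n2) / (2 * n)
  lrt <- 2 * (.trinomLogLik(n1, n2, n3, p_hat) -
                .trinomLogLik(n1, n2, n3, f1))
  max(lrt, 0)
}

#' Scan all markers: counts, control frequency and LRT
#'
#' Produces one row per marker at which at least 90% of affected animals
#' are typed, ordered by (chrom, pos), with the marker-statistics schema:
#' marker_id, chrom, pos, n1, n2, n3, lrt, f1. Markers below the typing
#' threshold, or with no typed control, are dropped with a warning.
#'
#' @param genotypes a [GenotypeMatrix-class] covering affected and
#'   controls.
#' @param phenotypes a [PhenotypeTable-class]; rows with status "affected"
#'   form the case set and rows with status "control" the frequency
#'   reference.
#' @return data.frame of per-marker statistics.
#' @export
scanMarkers <- function(genotypes, phenotypes) {
  aff <- intersect(affectedIds(phenotypes), rownames(genotypes@calls))
  ctl <- intersect(controlIds(phenotypes), rownames(genotypes@calls))
  if (length(aff) == 0)
    stop("configuration error: no affected individuals in phenotype table")
  if (length(ctl) == 0)
    stop("configuration error: no control individuals in phenotype table")
  A <- genotypes@calls[aff, , drop = FALSE]
  C <- genotypes@calls[ctl, , drop = FALSE]
  n1 <- colSums(A == 2L, na.rm = TRUE)
  n2 <- colSums(A == 1L, na.rm = TRUE)
  n3 <- colSums(A == 0L, na.rm = TRUE)
  typed <- n1 + n2 + n3
  ok_typed <- typed >= 0.9 * length(aff)
  ctl_typed <- colSums(!is.na(C))
  ok_ctl <- ctl_typed > 0
  drop_n <- sum(!ok_typed | !ok_ctl)
  if (drop_n > 0)
    warning(drop_n, " marker(s) dropped: <90% of affected typed or no ",
            "typed control")
  keep <- ok_typed & ok_ctl

  f1_raw <- colSums(C, na.rm = TRUE) / (2 * pmax(ctl_typed, 1L))
  f1 <- ifelse(f1_raw == 0, 0.1, ifelse(f1_raw == 1, 0.9, f1_raw))
  p_hat <- (2 * n1 + n2) / (2 * pmax(typed, 1L))
  llAt <- function(p) {
    ifelse(n1 > 0, n1 * log(p^2), 0) +
      ifelse(n2 > 0, n2 * log(2 * p * (1 - p)), 0) +
      ifelse(n3 > 0, n3 * log((1 - p)^2), 0)
  }
  lrt <- pmax(2 * (llAt(p_hat) - llAt(f1)), 0)

  m <- genotypes@map@markers
  out <- data.frame(marker_id = m$marker_id, chrom = m$chrom, pos = m$pos,
                    n1 = n1, n2 = n2, n3 = n3, lrt = lrt, f1 = f1,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write a marker-statistics table as TSV
#'
#' @param stats data.frame from [scanMarkers()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMarkerStats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect shared homozygous intervals
#'
#' Finds all maximal runs of at least `min_markers` consecutive scanned
#' markers at which every typed affected animal is homozygous and all
#' affected share the same allele (n2 = 0 and one of n1/n3 = 0, with at
#' least one typed). Runs are ranked by score (sum of member LRT values),
#' ties broken by marker count and then by leftmost position; interval
#' boundaries are the first and last qualifying marker positions, and each
#' interval additionally records its search envelope up to the flanking
#' discordant markers (see [searchRegion()]). Consecutiveness is taken
#' over the scanned markers (markers dropped by the scan's typing
#' threshold do not interrupt a run).
#'
#' @param stats data.frame from [scanMarkers()].
#' @param genotypes,phenotypes optional; when both are given, the interval
#'   membership is re-verified against the raw genotypes as a guard.
#' @param min_markers minimum run length (default 5, guarding against
#'   single-marker genotyping artifacts).
#' @return list of [HomozygosityInterval-class], best first (possibly
#'   empty).
#' @export
detectIntervals <- function(stats, genotypes = NULL, phenotypes = NULL,
                            min_markers = 5) {
  if (nrow(stats) == 0) stop("stats must be nonempty")
  qual <- stats$n2 == 0 & (stats$n1 == 0 | stats$n3 == 0) &
    (stats$n1 + stats$n3) >= 1
  intervals <- list()
  for (ch in unique(stats$chrom)) {
    s <- stats[stats$chrom == ch, , drop = FALSE]
    q <- qual[stats$chrom == ch]
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_markers)) {
      i0 <- starts[k]; i1 <- ends[k]
      run <- s[i0:i1, , drop = FALSE]
      intervals[[length(intervals) + 1L]] <- new(
        "HomozygosityInterval", chrom = ch, start_bp = run$pos[1],
        end_bp = run$pos[nrow(run)],
        flank_start_bp = if (i0 > 1) s$pos[i0 - 1] + 1 else run$pos[1],
        flank_end_bp = if (i1 < nrow(s)) s$pos[i1 + 1] - 1
                       else run$pos[nrow(run)],
        marker_ids = run$marker_id,
        shared_allele = ifelse(run$n1 > 0, 1L, 2L),
        score = sum(run$lrt))
    }
  }
  if (length(intervals) == 0) return(list())
  if (!is.null(genotypes) && !is.null(phenotypes)) {
    aff <- affectedIds(phenotypes)
    for (iv in intervals) {
      g <- genotypes@calls[aff, iv@marker_ids, drop = FALSE]
      expect <- ifelse(iv@shared_allele == 1L, 2L, 0L)
      ok <- sweep(g, 2, expect, `==`) | is.na(g)
      if (!all(ok))
        stop("internal inconsistency: interval member marker with a ",
             "non-homozygous affected genotype")
    }
  }
  score <- vapply(intervals, function(x) x@score, numeric(1))
  nm <- vapply(intervals, function(x) length(x@marker_ids), numeric(1))
  lp <- vapply(intervals, function(x) x@start_bp, numeric(1))
  intervals[order(-score, -nm, lp)]
}
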