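## PED/MAP chip-genotype interchange.
##
## Dialect: whitespace-delimited PED with 6 leading columns (family, id,
## sire, dam, sex, phenotype) followed by two ACGT allele characters per
## marker ("0 0" = missing); the MAP file is a 6-column extension of the
## PLINK map (chrom, marker_id, cM, pos, allele1, allele2) so that genotype
## coding can be anchored to the map alleles.

#' Read chip genotypes from PED/MAP files
#'
#' Parses a whitespace-delimited PED file against its marker map and returns
#' map-anchored genotype codes: 2 = homozygous for the map's `allele1`,
#' 1 = heterozygous, 0 = homozygous `allele2`, `NA` = missing ("0 0").
#' The PED phenotype column is decoded as 2 = affected, 1 = control, and
#' 0 or -9 = unknown.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the 6-column map file (chrom, marker_id, cM, pos,
#'   allele1, allele2).
#' @return A list with elements `map` ([MarkerMap-class]), `genotypes`
#'   ([GenotypeMatrix-class]) and `phenotypes` ([PhenotypeTable-class]).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines("1 M1 0 100 A G\n1 M2 0 200 C T", file.path(dir, "toy.map"))
#' writeLines("FAM A1 0 0 1 2 A A C T", file.path(dir, "toy.ped"))
#' x <- readPedMap(file.path(dir, "toy.ped"), file.path(dir, "toy.map"))
#' genotypeCalls(x$genotypes)
#' @export
readPedMap <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  mp <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric",
                                  "numeric", "character", "character"))
  if (ncol(mp) != 6)
    stop("format error: MAP file must have 6 columns ",
         "(chrom, marker_id, cM, pos, allele1, allele2)")
  names(mp) <- c("chrom", "marker_id", "cM", "pos", "allele1", "allele2")
  map <- MarkerMap(mp[, c("marker_id", "chrom", "pos", "allele1",
                          "allele2")])
  ## re-read order must follow the map's sorted order
  ord <- match(map@markers$marker_id, mp$marker_id)
  nm <- nrow(map@markers)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  expected <- 6 + 2 * nm
  if (any(nf != expected))
    stop("format error: PED line(s) ",
         paste(which(nf != expected), collapse = ", "),
         " have ", paste(unique(nf[nf != expected]), collapse = "/"),
         " fields; expected ", expected)

  n <- length(fields)
  ids <- vapply(fields, `[`, character(1), 2L)
  if (anyDuplicated(ids))
    stop("format error: duplicated individual id in PED")
  pheno_code <- vapply(fields, `[`, character(1), 6L)
  status <- ifelse(pheno_code == "2", "affected",
                   ifelse(pheno_code == "1", "control", "unknown"))

  a1 <- map@markers$allele1
  a2 <- map@markers$allele2
  calls <- matrix(NA_integer_, n, nm,
                  dimnames = list(ids, map@markers$marker_id))
  for (i in seq_len(n)) {
    g <- fields[[i]][-(1:6)]
    x1 <- g[2 * ord - 1]
    x2 <- g[2 * ord]
    miss <- x1 == "0" | x2 == "0"
    bad <- !miss & !((x1 == a1 | x1 == a2) & (x2 == a1 | x2 == a2))
    if (any(bad)) {
      j <- which(bad)[1]
      stop("format error: allele '", x1[j], "/", x2[j], "' at marker ",
           map@markers$marker_id[j], " (PED line ", i,
           ") matches neither map allele ", a1[j], "/", a2[j])
    }
    cc <- (x1 == a1) + (x2 == a1)
    cc[miss] <- NA_integer_
    calls[i, ] <- cc
  }
  list(map = map,
       genotypes = GenotypeMatrix(calls, map),
       phenotypes = PhenotypeTable(ids, status))
}

#' Write chip genotypes to PED/MAP files
#'
#' Inverse of [readPedMap()]: serialises a [GenotypeMatrix-class] with its
#' phenotype assignments to the whitespace-delimited PED dialect and its
#' [MarkerMap-class] to the 6-column map format. Heterozygotes are written
#' allele1-first, so write-then-read round-trips the genotype codes exactly.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param phenotypes a [PhenotypeTable-class] covering the matrix rows
#'   (affected -> 2, control -> 1, anything else -> 0).
#' @param ped_path,map_path output paths.
#' @param family family id written in PED column 1.
#' @param parents optional data.frame (`id`, `sire`, `dam`, `sex`) used to
#'   fill PED columns 3-5; unknown parents are written as "0".
#' @return Invisibly, the two paths.
#' @export
writePedMap <- function(genotypes, phenotypes, ped_path, map_path,
                        family = "FAM", parents = NULL) {
  m <- genotypes@map@markers
  map_df <- data.frame(m$chrom, m$marker_id, 0, m$pos, m$allele1, m$allele2)
  write.table(map_df, map_path, quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)

  calls <- genotypes@calls
  ids <- rownames(calls)
  st <- phenotypes@status$status[match(ids, phenotypes@status$id)]
  pheno <- ifelse(is.na(st), "0",
                  ifelse(st == "affected", "2",
                         ifelse(st == "control", "1", "0")))
  sire <- dam <- rep("0", length(ids))
  sex <- rep("0", length(ids))
  if (!is.null(parents)) {
    k <- match(ids, parents$id)
    sire <- ifelse(is.na(k) | is.na(parents$sire[k]), "0", parents$sire[k])
    dam <- ifelse(is.na(k) | is.na(parents$dam[k]), "0", parents$dam[k])
    sex <- ifelse(is.na(k), "0",
                  ifelse(parents$sex[k] == "M", "1",
                         ifelse(parents$sex[k] == "F", "2", "0")))
  }

  a1 <- m$allele1
  a2 <- m$allele2
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    cc <- calls[i, ]
    x1 <- ifelse(is.na(cc), "0", ifelse(cc >= 1, a1, a2))
    x2 <- ifelse(is.na(cc), "0", ifelse(cc == 2, a1, a2))
    writeLines(paste(c(family, ids[i], sire[i], dam[i], sex[i], pheno[i],
                       as.vector(rbind(x1, x2))), collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Extract genotype calls, marker map or sample ids
#'
#' Accessors for [GenotypeMatrix-class].
#'
#' @param x a [GenotypeMatrix-class].
#' @return `genotypeCalls`: the integer call matrix; `markerMap`: the
#'   [MarkerMap-class]; `sampleIds`: character vector of individual ids.
#' @export
genotypeCalls <- function(x) x@calls

#' @rdname genotypeCalls
#' @export
markerMap <- function(x) x@map

#' @rdname genotypeCalls
#' @export
sampleIds <- function(x) rownames(x@calls)

#' Extract ids by phenotype status
#'
#' @param x a [PhenotypeTable-class].
#' @param status one or more statuses from
#'   affected/control/carrier/wild_type/unknown.
#' @return character vector of ids with the requested status(es).
#' @export
idsWithStatus <- function(x, status) {
  x@status$id[x@status$status %in% status]
}

#' @rdname idsWithStatus
#' @export
affectedIds <- function(x) idsWithStatus(x, "affected")

#' @rdname idsWithStatus
#' @export
controlIds <- function(x) idsWithStatus(x, "control")

#' Read a simulation configuration from a YAML file
#'
#' Reads scalar fields named after [SimulationConfig-class] slots and
#' merges them over the defaults of [simConfig()].
#'
#' @param path YAML file path.
#' @return A [SimulationConfig-class].
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simConfig, vals)
}
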