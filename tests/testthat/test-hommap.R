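# Marker statistics, likelihood-ratio statistic and interval detection.

test_that("affected genotype counts exclude missing calls", {
  map <- toyMap(2)
  calls <- matrix(c(2L, 1L,
                    1L, 1L,
                    0L, 1L,
                    NA, 1L), 4, 2, byrow = TRUE)
  gm <- toyGenotypes(calls, map)
  expect_equal(markerCounts(gm, sprintf("I%02d", 1:4), "M01"),
               c(n1 = 1, n2 = 1, n3 = 1))
  expect_equal(markerCounts(gm, character(0), "M01"),
               c(n1 = 0, n2 = 0, n3 = 0))
  # the mapped-interval signature: all twelve affected homozygous
  gm12 <- toyGenotypes(matrix(2L, 12, 2), map)
  expect_equal(markerCounts(gm12, sampleIds(gm12), "M01"),
               c(n1 = 12, n2 = 0, n3 = 0))
  expect_error(markerCounts(gm, "I01", "NOPE"), "lookup error")
})

test_that("control frequency applies the extreme-value reporting rule", {
  map <- toyMap(1)
  hom2 <- toyGenotypes(matrix(0L, 5, 1), map)
  expect_equal(controlFreq(hom2, sampleIds(hom2), "M01"), 0.1)
  hom1 <- toyGenotypes(matrix(2L, 5, 1), map)
  expect_equal(controlFreq(hom1, sampleIds(hom1), "M01"), 0.9)
  mix <- toyGenotypes(matrix(c(2L, 1L), 2, 1), map)
  expect_equal(controlFreq(mix, sampleIds(mix), "M01"), 0.75)
  miss <- toyGenotypes(matrix(NA_integer_, 2, 1), map)
  expect_error(controlFreq(miss, sampleIds(miss), "M01"),
               "undefined-frequency")
})

test_that("the LRT matches the grid-search oracle on worked cases", {
  # all-homozygous signature against a balanced control frequency
  expect_equal(markerLrt(c(12, 0, 0), 0.5), 2 * 12 * log(4),
               tolerance = 1e-12)
  expect_equal(markerLrt(c(12, 0, 0), 0.5), gridLrt(12, 0, 0, 0.5),
               tolerance = 1e-6)
  # counts that sit exactly on the null
  expect_equal(markerLrt(c(3, 6, 3), 0.5), 0, tolerance = 1e-12)
  # fixation of allele 2 in affected against a high allele-1 frequency;
  # the grid oracle gives 2 * (0 - 10 * log((1 - 0.9)^2)) = 92.103...
  expect_equal(markerLrt(c(0, 0, 10), 0.9), gridLrt(0, 0, 10, 0.9),
               tolerance = 1e-6)
  expect_equal(markerLrt(c(0, 0, 10), 0.9), -20 * log(0.01),
               tolerance = 1e-9)
  expect_error(markerLrt(c(1, 0, 0), 1), "domain error")
  expect_error(markerLrt(c(0, 0, 0), 0.5), "at least 1")
})

test_that("the LRT is nonnegative, zero at the null and monotone in f1
           for all-homozygous counts", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(1:50, 1)
    n1 <- sample(0:n, 1); n2 <- sample(0:(n - n1), 1)
    n3 <- n - n1 - n2
    f1 <- runif(1, 0.01, 0.99)
    lrt <- markerLrt(c(n1, n2, n3), f1)
    expect_gte(lrt, 0)
    # zero exactly when the affected allele frequency equals f1
    p_hat <- (2 * n1 + n2) / (2 * n)
    if (abs(p_hat - f1) < 1e-12) expect_equal(lrt, 0)
  }
  expect_equal(markerLrt(c(5, 3, 2), 0.65), 0, tolerance = 1e-12)
  f <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(f, function(x) markerLrt(c(8, 0, 0), x), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("scan returns the marker-statistics schema and is null on
           matched cohorts", {
  map <- toyMap(6)
  # per-marker genotypes drawn so that affected counts (1,2,1) sit exactly
  # on the control frequency 0.5
  aff <- matrix(rep(c(2L, 1L, 1L, 0L), 6), 4, 6)
  ctl <- matrix(rep(c(2L, 1L, 1L, 0L), 6), 4, 6)
  gm <- toyGenotypes(rbind(aff, ctl), map)
  ph <- PhenotypeTable(sampleIds(gm), rep(c("affected", "control"),
                                          each = 4))
  st <- scanMarkers(gm, ph)
  expect_identical(names(st), c("marker_id", "chrom", "pos", "n1", "n2",
                                "n3", "lrt", "f1"))
  expect_equal(nrow(st), 6L)
  expect_true(all(st$lrt == 0))
  expect_true(all(st$f1 == 0.5))
  expect_false(is.unsorted(st$pos))
})

test_that("markers below the 90% affected-typing threshold are dropped", {
  map <- toyMap(2)
  calls <- matrix(2L, 12, 2)
  calls[1, 1] <- NA          # 11/12 typed: kept
  calls[1:2, 2] <- NA        # 10/12 typed: dropped
  gm <- toyGenotypes(rbind(calls, matrix(1L, 3, 2)), map,
                     ids = c(sprintf("A%02d", 1:12), "C1", "C2", "C3"))
  ph <- PhenotypeTable(sampleIds(gm),
                       c(rep("affected", 12), rep("control", 3)))
  expect_warning(st <- scanMarkers(gm, ph), "dropped")
  expect_identical(st$marker_id, "M01")
  expect_equal(st$n1, 11)
})

test_that("interval detection equals brute-force window enumeration", {
  # ten-marker toy chromosome: markers 4-8 all-affected-homozygous
  map <- toyMap(10)
  aff <- matrix(1L, 4, 10)
  aff[, 4:8] <- 2L
  aff[, 6] <- 0L             # run may switch the shared allele
  ctl <- matrix(1L, 4, 10)
  gm <- toyGenotypes(rbind(aff, ctl), map)
  ph <- PhenotypeTable(sampleIds(gm), rep(c("affected", "control"),
                                          each = 4))
  st <- scanMarkers(gm, ph)
  ivs <- detectIntervals(st, gm, ph, min_markers = 3)
  expect_length(ivs, 1L)
  expect_equal(ivs[[1]]@start_bp, 4000)
  expect_equal(ivs[[1]]@end_bp, 8000)
  expect_identical(ivs[[1]]@shared_allele, c(1L, 1L, 2L, 1L, 1L))
  # search envelope extends to the flanking discordant markers
  expect_equal(searchRegion(ivs[[1]]), c(3001, 8999))

  # all-heterozygous affected yield no interval
  gm2 <- toyGenotypes(rbind(matrix(1L, 4, 10), ctl), map)
  st2 <- scanMarkers(gm2, ph)
  expect_length(detectIntervals(st2, min_markers = 3), 0L)

  # randomized fixtures against exhaustive enumeration
  set.seed(17)
  for (rep in 1:25) {
    nm <- sample(20:200, 1)
    mp <- toyMap(nm)
    a <- matrix(sample(0:2, 6 * nm, replace = TRUE,
                       prob = c(0.2, 0.3, 0.5)), 6, nm)
    cl <- matrix(sample(0:2, 6 * nm, replace = TRUE), 6, nm)
    g <- toyGenotypes(rbind(a, cl), mp)
    p <- PhenotypeTable(sampleIds(g), rep(c("affected", "control"),
                                          each = 6))
    s <- scanMarkers(g, p)
    got <- detectIntervals(s, g, p, min_markers = 2)
    want <- bruteIntervals(s, 2)
    expect_equal(length(got), length(want))
    if (length(got)) {
      key <- function(ch, st_, en) paste(ch, st_, en)
      expect_setequal(
        vapply(got, function(x) key(x@chrom, x@start_bp, x@end_bp),
               character(1)),
        vapply(want, function(x) key(x$chrom, x$start, x$end),
               character(1)))
      sc <- setNames(vapply(want, `[[`, numeric(1), "score"),
                     vapply(want, function(x)
                       key(x$chrom, x$start, x$end), character(1)))
      for (x in got)
        expect_equal(x@score, unname(sc[key(x@chrom, x@start_bp,
                                            x@end_bp)]),
                     tolerance = 1e-9)
    }
  }
})

test_that("intervals are ranked by score, then size, then position", {
  st <- data.frame(
    marker_id = sprintf("M%02d", 1:12), chrom = "1",
    pos = 1:12 * 1000,
    n1 = c(4, 4, 4, 0, 4, 4, 4, 0, 4, 4, 4, 4),
    n2 = c(0, 0, 0, 4, 0, 0, 0, 4, 0, 0, 0, 0),
    n3 = 0,
    lrt = c(5, 5, 5, 0, 1, 1, 1, 0, 1, 1, 1, 1),
    f1 = 0.5, stringsAsFactors = FALSE)
  ivs <- detectIntervals(st, min_markers = 3)
  expect_length(ivs, 3L)
  expect_equal(ivs[[1]]@score, 15)                      # highest score
  expect_equal(nMarkers(ivs[[2]]), 4L)                  # tie -> more markers
  expect_equal(ivs[[2]]@start_bp, 9000)
  expect_equal(ivs[[3]]@start_bp, 5000)
})
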