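makeTestPeaks <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

test_that("containment counting obeys the footprint rule", {
  seq <- "GGTCAAAATGACC"
  occ <- scanElements(seq, ERE13, 5)
  ## a peak exactly covering the element counts it once
  p1 <- makeTestPeaks("seq1", 1, 13)
  cnt <- countInPeaks(occ, p1, elementUniverse(ERE13, 1))
  expect_equal(cnt$count[cnt$element_id == "consensus"], 1L)
  expect_equal(sum(cnt$count), 1L)
  ## an occurrence straddling the peak edge is not contained
  p2 <- makeTestPeaks("seq1", 2, 13)
  expect_equal(sum(countInPeaks(occ, p2)$count), 0L)
  ## but still counts under the any-overlap alternative
  expect_equal(sum(countInPeaks(occ, p2, mode = "any")$count), 1L)
  ## overlapping peaks each count independently
  p3 <- makeTestPeaks("seq1", c(1, 1), c(13, 13))
  expect_equal(sum(countInPeaks(occ, p3)$count), 2L)
  ## mismatched sequence names warn and count zero
  p4 <- makeTestPeaks("chrX", 1, 13)
  expect_warning(cnt4 <- countInPeaks(occ, p4), "share no sequence names")
  expect_equal(sum(cnt4$count), 0L)
})

test_that("peak counting equals a brute-force per-peak window scan", {
  g <- makeGenome(50000, ERE13,
                  plantings = c(consensus = 15, "3A" = 15, "1T8C" = 10),
                  seed = 23)
  occ <- scanElements(g$genome, ERE13, 2)
  set.seed(31)
  starts <- sample(49800, 150)
  peaks <- makeTestPeaks("syn1", starts, starts + 199)
  cnt <- countInPeaks(occ, peaks, elementUniverse(ERE13, 2))
  oracle <- brutePeakCounts(unname(g$genome),
                            data.frame(start = starts, end = starts + 199),
                            ERE13, 2)
  got <- stats::setNames(cnt$count, cnt$element_id)
  expect_equal(got[names(oracle)], oracle[names(oracle)])
  expect_equal(sum(got), sum(oracle))
  ## duplicated elements inside one peak: every containment counts by
  ## default, once per peak under the presence flag
  dupSeq <- paste0("GGTCAAAATGACC", "TT", "GGTCAAAATGACC")
  dupOcc <- scanElements(dupSeq, ERE13, 0)
  wide <- makeTestPeaks("seq1", 1, nchar(dupSeq))
  expect_equal(sum(countInPeaks(dupOcc, wide)$count), 2L)
  expect_equal(sum(countInPeaks(dupOcc, wide, perPeak = TRUE)$count), 1L)
})

test_that("unique assignment picks the least-variant element deterministically", {
  seqs <- paste0("GGTCAAAATGACC",            # consensus   (k = 0)
                 "TT", "TGTCAAAATGACC",      # 1T          (k = 1)
                 strrep("T", 20))
  occ <- scanElements(seqs, ERE13, 4)
  peaks <- makeTestPeaks("seq1", c(1, 14, 30), c(28, 28, 48))
  res <- assignUnique(occ, peaks)
  expect_equal(res$assignment$element_id[1], "consensus")  # 0-nt beats 1-nt
  expect_equal(res$assignment$element_id[2], "1T")
  expect_true(is.na(res$assignment$element_id[3]))
  ## ties between distinct minimum-k elements: leftmost occurrence wins,
  ## audit counter reports the tie
  tieSeq <- paste0("TGTCAAAATGACC", "TT", "GGTCAAAATGACA")  # 1T then 10A
  tieOcc <- scanElements(tieSeq, ERE13, 1)
  tiePeak <- makeTestPeaks("seq1", 1, nchar(tieSeq))
  tieRes <- assignUnique(tieOcc, tiePeak)
  expect_equal(tieRes$assignment$element_id, "1T")
  expect_equal(tieRes$nTies, 1L)
  ## the level histogram of labels is invariant to peak order
  rev3 <- assignUnique(occ, rev(peaks))
  expect_equal(sort(table(res$assignment$k)), sort(table(rev3$assignment$k)))
})

test_that("degenerate consensus matching is monotone in pattern looseness", {
  g <- makeGenome(30000, HRE13,
                  plantings = c(consensus = 20, "2C" = 20, "1T5A" = 20),
                  seed = 37)
  starts <- pmax(g$truth$start - 20, 1)
  peaks <- makeTestPeaks("syn1", starts, starts + 60)
  ps <- peakSequences(g$genome, peaks)
  ## the concrete consensus matches peaks that contain it
  expect_gt(iupacMatch(ps, "GAACANNNTGTTC"), 0)
  ## an all-N pattern matches every peak
  expect_equal(iupacMatch(ps, strrep("N", 10)), 1)
  ## looser PRE-style pattern matches at least the stricter GRE-style one
  gre2 <- iupacMatch(ps, "VAGRACAKWCTGTYC")
  pre <- iupacMatch(ps, "VAGRACAKNCTGTBC")
  expect_gte(pre, gre2)
  expect_error(iupacMatch(ps, "AXG"), "invalid IUPAC")
})

test_that("uniform peak subsampling scales counts binomially", {
  g <- makeGenome(200000, ERE13, plantings = c(consensus = 80, "3A" = 80),
                  seed = 41)
  occ <- scanElements(g$genome, ERE13, 1)
  set.seed(43)
  starts <- sample(199800, 4000, replace = TRUE)
  peaks <- makeTestPeaks("syn1", starts, starts + 150)
  full <- countInPeaks(occ, peaks, elementUniverse(ERE13, 1))
  keep <- seq_along(peaks) %% 2L == 0L          # q = 0.5
  sub <- countInPeaks(occ, peaks[keep], elementUniverse(ERE13, 1))
  q <- 0.5
  tot <- full$count
  expect_true(all(abs(sub$count - q * tot) <=
                    3 * sqrt(pmax(tot, 1) * q * (1 - q)) + 1e-9))
})
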