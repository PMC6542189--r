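test_that("scanning finds the consensus and respects ambiguity rules", {
  occ <- scanElements("GGTCAAAATGACC", ERE13, 5)
  expect_equal(length(occ), 1L)
  expect_equal(occ$element_id, "consensus")
  expect_equal(occ$k, 0L)
  expect_equal(GenomicRanges::start(occ), 1L)
  expect_equal(GenomicRanges::width(occ), 13L)
  ## too short -> empty
  expect_equal(length(scanElements("GGTCA", ERE13, 5)), 0L)
  ## ambiguity at a primary or a spacer position skips the window
  expect_equal(length(scanElements("GNTCAAAATGACC", ERE13, 5)), 0L)
  expect_equal(length(scanElements("GGTCAANATGACC", ERE13, 5)), 0L)
})

test_that("scanning equals the brute-force per-window Hamming oracle", {
  g <- makeGenome(20000, ERE13,
                  plantings = c(consensus = 10, "1T" = 10, "3A8C" = 10,
                                "2C7A9T" = 5),
                  seed = 11)
  occ <- scanElements(g$genome, ERE13, 3)
  oracle <- bruteScan(unname(g$genome), ERE13, 3)
  got <- data.frame(start = GenomicRanges::start(occ),
                    element_id = occ$element_id, k = occ$k,
                    stringsAsFactors = FALSE)
  got <- got[order(got$start), ]
  oracle <- oracle[order(oracle$start), ]
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle)
  ## every planted position is recovered with its planted identity
  found <- stats::setNames(got$element_id, got$start)
  expect_true(all(found[as.character(g$truth$start)] == g$truth$element_id))
})

test_that("a sequence concatenated with its reverse complement balances every element", {
  s <- randomSeq(30000, seed = 5)
  mirrored <- paste0(s, "N", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))))
  occ <- scanElements(mirrored, ERE13, 1)
  tab <- table(occ$element_id)
  ids <- names(tab)
  rc <- rcElement(ERE13, ids)
  expect_equal(as.integer(tab[rc]), as.integer(tab))
})

test_that("k-mer counting covers exactly the valid forward-strand windows", {
  t1 <- countKmers("ACGT", 1)
  expect_equal(sort(t1@counts), c(A = 1L, C = 1L, G = 1L, T = 1L))
  tab4 <- countKmers("ACGT", 4)
  expect_equal(tab4@counts, c(ACGT = 1L))
  expect_equal(missingCount(tab4)[["n_missing"]], 256 - 1)
  ## window arithmetic on a longer random sequence
  s <- randomSeq(10000, seed = 7)
  expect_equal(countKmers(s, 3)@nWindows, 10000 - 2)
  ## records are scanned independently; sentinels break windows
  two <- c(a = "ACGT", b = "ACGT")
  expect_equal(countKmers(two, 4)@counts, c(ACGT = 2L))
  expect_equal(countKmers(paste0("ACGT", "N", "ACGT"), 4)@counts,
               c(ACGT = 2L))
  expect_error(countKmers("ACGT", 0), "between 1 and 32")
  expect_equal(missingCount(countKmers("AAAA", 2)),
               c(n_present = 1, n_missing = 15))
  m10 <- missingCount(countKmers(randomSeq(100000, seed = 8), 10))
  expect_lte(m10[["n_present"]], 100000 - 9)
  expect_lte(m10[["n_present"]], 4^10)
})

test_that("parity comparison matches a full-vector Biostrings cross-check", {
  s <- randomSeq(40000, seed = 21, prob = c(0.35, 0.15, 0.2, 0.3))
  tab <- countKmers(s, 4)
  full <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), 4)
  for (op in c("reverse_complement", "reverse", "complement")) {
    rep <- parityCompare(tab, op)
    perm <- switch(op,
      reverse_complement = as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(names(full)))),
      reverse = as.character(Biostrings::reverse(
        Biostrings::DNAStringSet(names(full)))),
      complement = as.character(Biostrings::complement(
        Biostrings::DNAStringSet(names(full)))))
    expect_equal(rep$correlation, cor(full, full[perm]), tolerance = 1e-12)
    ## correlation is symmetric in the two count vectors
    expect_equal(rep$correlation, cor(full[perm], full), tolerance = 1e-12)
  }
  expect_equal(parityCompare(tab, "reverse_complement")$n_missing,
               missingCount(tab)[["n_missing"]])
})

test_that("a mirrored genome has exact reverse-complement parity", {
  m <- makeMirroredGenome(60000, seed = 9)
  for (k in c(3, 7)) {
    tab <- countKmers(m, k)
    rc <- parityCompare(tab, "reverse_complement")
    expect_identical(rc$correlation, 1)
    expect_identical(rc$slope, 1)
    expect_identical(rc$intercept, 0)
    ## parity conservation: one-operation comparisons agree with each other
    expect_equal(parityCompare(tab, "reverse")$correlation,
                 parityCompare(tab, "complement")$correlation,
                 tolerance = 1e-12)
  }
})
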