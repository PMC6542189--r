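test_that("variant enumeration has the combinatorial sizes and a stable order", {
  for (k in 0:3) {
    v <- enumerateVariants(ERE13, k)
    expect_equal(nrow(v), choose(10, k) * 3^k)
    expect_equal(nrow(v), variantCount(ERE13, k))
    expect_false(anyDuplicated(v$id) > 0)
    expect_true(all(nchar(v$seq) == footprint(ERE13)))
  }
  v1 <- enumerateVariants(ERE13, 1)
  ## positions lexicographic, bases alphabetical (consensus G excluded at 1, 2)
  expect_equal(v1$id[1:6], c("1A", "1C", "1T", "2A", "2C", "2T"))
  expect_identical(v1, enumerateVariants(ERE13, 1))
  ## every substituted base differs from the consensus base
  cons <- primaryBases(ERE13)
  ok <- vapply(seq_len(nrow(v1)), function(i) {
    p <- as.integer(sub("[ACGT]$", "", v1$id[i]))
    b <- sub("^[0-9]+", "", v1$id[i])
    b != cons[p]
  }, logical(1))
  expect_true(all(ok))
  expect_error(enumerateVariants(ERE13, 11), "between 0 and")
  expect_error(enumerateVariants(ERE13, -1), "between 0 and")
})

test_that("reverse complement acts through the pair map and is an involution", {
  expect_equal(rcElement(ERE13, "consensus"), "consensus")
  expect_equal(rcElement(ERE13, "1T"), "10A")
  expect_equal(realizeElement(ERE13, "1T"), "TGTCANNNTGACC")
  expect_equal(realizeElement(ERE13, "10A"), "GGTCANNNTGACA")
  ## realized rc sequence is the biological reverse complement
  ids <- enumerateVariants(ERE13, 2)$id
  rc <- rcElement(ERE13, ids)
  seqFwd <- realizeElement(ERE13, ids[1:50])
  seqRc <- realizeElement(ERE13, rc[1:50])
  expect_equal(seqRc, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqFwd))))
  ## involution and bijection of each level onto itself
  for (k in 1:2) {
    lev <- enumerateVariants(ERE13, k)$id
    r <- rcElement(ERE13, lev)
    expect_equal(rcElement(ERE13, r), lev)
    expect_setequal(r, lev)
  }
})

test_that("half-site group taxonomy matches the published census", {
  g <- enumerateHalfSiteGroups(ERE13)
  expect_equal(nrow(g), 252)
  expect_true(all(g$nV == g$nD))
  expect_true(all(g$nV + g$nD + g$nS == 5))
  expect_equal(sum(g$representative), 126)
  expect_equal(as.integer(table(g$nV[g$representative])), c(16, 80, 30))
  expect_equal(as.integer(table(g$nV)), c(32, 160, 60))
  ## census identity: sum_v C(5,v) C(5-v,v) 2^(5-2v) = 252
  expect_equal(sum(sapply(0:2, function(v)
    choose(5, v) * choose(5 - v, v) * 2^(5 - 2 * v))), 252)
  ## rc is an involution with no fixed points for n = 10
  expect_equal(g$rcId[g$rcId], g$id)
  expect_false(any(g$innate))
  ## worked example from the taxonomy: group 2-4-5-7-9 has vacancies at
  ## pairs 1-10 and 3-8 and doubles at 2-9 and 4-7
  row <- g[g$fixed == "2-4-5-7-9", ]
  expect_equal(row$vacPairs, "1-10,3-8")
  expect_equal(row$dblPairs, "2-9,4-7")
})

test_that("15-nt taxonomy has 924 groups with 20 innate palindromes", {
  g15 <- enumerateHalfSiteGroups(builtinSchema("ERE15"))
  expect_equal(nrow(g15), 924)
  expect_equal(sum(g15$innate), 20)
  ## innate exactly when no pair is split across fixed/free
  expect_equal(g15$innate, g15$nS == 0)
  expect_true(all(g15$nV[g15$innate] == 3))
  expect_equal(as.integer(table(g15$nV)), c(64, 480, 360, 20))
})

test_that("group membership covers the published 1,024-element census", {
  g <- enumerateHalfSiteGroups(ERE13)
  grp1 <- g[g$fixed == "1-2-3-4-5", ]
  m1 <- groupMembers(ERE13, grp1, 1)
  expect_setequal(m1$id, c("6A", "6C", "6G", "7A", "7C", "7T", "8C", "8G",
                           "8T", "9A", "9G", "9T", "10A", "10G", "10T"))
  sizes <- sapply(0:5, function(k) nrow(groupMembers(ERE13, grp1, k)))
  expect_equal(sizes, choose(5, 0:5) * 3^(0:5))
  expect_equal(sum(sizes), 1024)
  expect_error(groupMembers(ERE13, grp1, 6), "between 0 and")
  ## a level-1 element belongs to choose(9, 5) = 126 groups, so the level-1
  ## membership total over all groups is 30 * 126 = 252 * 15
  v1 <- enumerateVariants(ERE13, 1)
  nGroups <- vapply(v1$posMask, function(m)
    sum(bitwAnd(m, g$fixedMask) == 0L), numeric(1))
  expect_true(all(nGroups == choose(9, 5)))
  expect_equal(sum(nGroups), 252 * 15)
})

test_that("axis order mirrors representatives onto their reverse complements", {
  g <- enumerateHalfSiteGroups(ERE13)
  ord <- axisOrder(g, vacancyHierarchy("ERE13"))
  expect_equal(g$fixed[ord[1]], "1-2-3-4-5")
  expect_equal(g$fixed[ord[252]], "6-7-8-9-10")
  expect_equal(g$rcId[ord], rev(ord))
  ## vacancy blocks run zero / one / two left of centre
  expect_equal(g$nV[ord[1:126]], rep(0:2, times = c(16, 80, 30)))
  expect_error(axisOrder(g, c("3-8", "1-10")), "permutation")
  expect_error(axisOrder(g, c("3-8", "1-10", "5-6", "4-7", "4-7")),
               "permutation")
  g15 <- enumerateHalfSiteGroups(builtinSchema("ERE15"))
  ord15 <- axisOrder(g15, vacancyHierarchy("ERE15"))
  expect_equal(length(ord15), 924)
  expect_true(all(g15$innate[ord15[453:472]]))
  expect_equal(g15$rcId[ord15[1:452]], rev(ord15[473:924]))
})

test_that("group states respect the two symmetries of the taxonomy", {
  g <- enumerateHalfSiteGroups(ERE13)
  ## complement partner: the group fixing exactly the free positions
  compId <- vapply(strsplit(g$fixed, "-"), function(f) {
    key <- paste(setdiff(1:10, as.integer(f)), collapse = "-")
    g$id[g$fixed == key]
  }, integer(1))
  for (grouping in list(ereStateGrouping(ERE13),
                        signatureGrouping(ERE13, c(2, 2, 1)))) {
    st <- stateOfGroup(g, grouping)
    ## mapping the fixed set through the pair map keeps every pair's
    ## occupancy class, so reverse-complement partners share their state —
    ## the structural reason the S/N display is mirror-symmetric
    expect_equal(st$state[g$rcId], st$state)
    ## complementing the fixed set swaps vacancies with double occupants
    ## and negates the state, making the census symmetric about zero
    expect_equal(st$state[compId], -st$state)
    expect_true(all(st$state[g$nV == 0] == 0))
  }
})

test_that("distinct state counts agree with the generic-weight brute force", {
  signatures <- list(c(4, 1), c(3, 2), c(3, 1, 1), c(2, 2, 1),
                     c(2, 1, 1, 1), c(1, 1, 1, 1, 1))
  for (sig in signatures) {
    res <- countDistinctStates(ERE13, signatureGrouping(ERE13, sig))
    expect_equal(res$nStates, bruteDistinctStates(ERE13, sig),
                 info = paste(sig, collapse = ","))
    expect_equal(sum(res$census$count), 252)
    ## group counts are symmetric about the zero state
    expect_equal(res$census$count, rev(res$census$count))
  }
  ## the named receptor groupings give the published plateau censuses
  ere <- countDistinctStates(ERE13, ereStateGrouping(ERE13))
  expect_equal(ere$nStates, 5)
  expect_equal(ere$census$count, c(6, 60, 120, 60, 6))
  hre <- countDistinctStates(HRE13, hreStateGrouping(HRE13))
  expect_equal(hre$census$count, c(56, 140, 56))
})
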