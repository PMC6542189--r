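## Independent oracles, deliberately naive: they never share code with the
## package paths they check.

## Per-window Hamming scan: loop over every window, compare primary
## characters one by one.
bruteScan <- function(seqStr, schema, kMax) {
  n <- nPrimary(schema)
  h <- n %/% 2L
  sp <- spacerLength(schema)
  f <- n + sp
  cons <- primaryBases(schema)
  chars <- strsplit(seqStr, "")[[1]]
  res <- list()
  if (length(chars) < f) {
    return(data.frame(start = integer(0), element_id = character(0),
                      k = integer(0), stringsAsFactors = FALSE))
  }
  primOff <- c(seq_len(h), (h + sp + 1L):f) - 1L
  for (s in seq_len(length(chars) - f + 1L)) {
    win <- chars[s:(s + f - 1L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    obs <- win[primOff + 1L]
    mism <- which(obs != cons)
    if (length(mism) > kMax) next
    id <- if (length(mism) == 0L) "consensus" else
      paste0(mism, obs[mism], collapse = "")
    res[[length(res) + 1L]] <- data.frame(
      start = s, element_id = id, k = length(mism),
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(0), element_id = character(0),
                      k = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

## Generic-weight brute force for distinct state counts: enumerate every
## choice of n/2 fixed positions directly from combn, score vacancies and
## double occupants with square roots of primes, count distinct sums.
bruteDistinctStates <- function(schema, classSizes) {
  n <- nPrimary(schema)
  h <- n %/% 2L
  classSizes <- classSizes[classSizes > 0]
  stopifnot(sum(classSizes) == h)
  cls <- rep(seq_along(classSizes), classSizes)  # pair p -> class
  w <- sqrt(c(2, 3, 5, 7, 11, 13))[seq_along(classSizes)]
  combs <- utils::combn(n, h)
  states <- apply(combs, 2, function(f) {
    inF <- rep(FALSE, n)
    inF[f] <- TRUE
    cnt <- inF[seq_len(h)] + inF[n:(h + 1L)]
    sum(w[cls[cnt == 0L]]) - sum(w[cls[cnt == 2L]])
  })
  length(unique(round(states, 9)))
}

## Per-peak brute-force containment count: substring each peak out of the
## genome and scan it naively.
brutePeakCounts <- function(genomeStr, peaksDf, schema, kMax) {
  counts <- list()
  for (i in seq_len(nrow(peaksDf))) {
    sub <- substr(genomeStr, peaksDf$start[i], peaksDf$end[i])
    hits <- bruteScan(sub, schema, kMax)
    for (id in hits$element_id)
      counts[[id]] <- (if (is.null(counts[[id]])) 0L else counts[[id]]) + 1L
  }
  unlist(counts)
}

randomSeq <- function(n, seed, prob = rep(0.25, 4)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

ERE13 <- builtinSchema("ERE13")
HRE13 <- builtinSchema("HRE13")
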