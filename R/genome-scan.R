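## Coerce sequence input (character / DNAString / DNAStringSet / list of
## either) to a named character vector, one element per record.
asSequenceSet <- function(x) {
  if (is(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  if (is(x, "DNAString")) x <- as.character(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(toupper(x))
  }
  stop("unsupported sequence input of class ", class(x)[1])
}

#' Scan sequences for variant-element occurrences
#'
#' Reports every forward-strand window whose primary positions are within
#' Hamming distance `kMax` of the schema consensus. Each record of a
#' multi-sequence input is scanned independently (windows never cross
#' record boundaries); windows containing a non-ACGT character at any
#' primary *or* spacer position are skipped, so every reported occurrence
#' has an unambiguous location and identity.
#'
#' @param seqs sequences: character vector, `DNAString`, or
#'   `DNAStringSet` (names become seqnames).
#' @param schema an [ElementSchema-class].
#' @param kMax maximum substitution count to report, `0 <= kMax <= n`.
#' @return A [GenomicRanges::GRanges] on strand `"+"` with metadata
#'   columns `element_id` and `k`; coordinates follow the usual 1-based
#'   closed GRanges convention (use [writeOccurrencesBed()] for 0-based
#'   half-open BED export).
#' @examples
#' occ <- scanElements("GGTCAAAATGACC", builtinSchema("ERE13"), 1)
#' occ$element_id  # "consensus"
#' @export
scanElements <- function(seqs, schema, kMax) {
  n <- nPrimary(schema)
  kMax <- as.integer(kMax)
  if (kMax < 0L || kMax > n) stop("kMax must be between 0 and ", n)
  seqs <- asSequenceSet(seqs)
  f <- footprint(schema)
  h <- n %/% 2L
  primOff <- c(seq_len(h), (h + spacerLength(schema) + 1L):f) - 1L
  cons <- primaryBases(schema)
  hits <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    len <- nchar(s)
    nw <- len - f + 1L
    if (nw < 1L) return(NULL)
    chars <- strsplit(s, "")[[1]]
    bad <- cumsum(!(chars %in% DNA_BASES))
    starts <- seq_len(nw)
    valid <- (bad[starts + f - 1L] -
                c(0L, bad)[starts]) == 0L
    dist <- integer(nw)
    obs <- matrix("", 0L, 0L)
    mism <- vector("list", n)
    for (j in seq_len(n)) {
      mism[[j]] <- chars[starts + primOff[j]] != cons[j]
      dist <- dist + mism[[j]]
    }
    keep <- which(valid & dist <= kMax)
    if (length(keep) == 0L) return(NULL)
    ids <- character(length(keep))
    idx <- which(dist[keep] == 0L)
    ids[idx] <- "consensus"
    nz <- which(dist[keep] > 0L)
    if (length(nz)) {
      mm <- vapply(mism, function(z) z[keep[nz]], logical(length(nz)))
      if (length(nz) == 1L) mm <- matrix(mm, nrow = 1L)
      ids[nz] <- vapply(seq_along(nz), function(r) {
        p <- which(mm[r, ])
        paste0(p, chars[keep[nz[r]] + primOff[p]], collapse = "")
      }, character(1))
    }
    GenomicRanges::GRanges(nm,
      IRanges::IRanges(start = keep, width = f), strand = "+",
      element_id = ids, k = dist[keep])
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L)
    return(GenomicRanges::GRanges(element_id = character(0), k = integer(0)))
  out <- do.call(c, hits)
  names(out) <- NULL
  out
}

#' Count forward-strand k-mers
#'
#' Counts every window of length `k` containing only A/C/G/T on the
#' forward strand. Windows spanning record boundaries or containing
#' ambiguity characters (including sentinel breaks) are not counted.
#' Storage is proportional to the number of distinct observed k-mers.
#'
#' @param seqs sequences as in [scanElements()].
#' @param k word length, `1 <= k <= 32`.
#' @return A [KmerCountTable-class].
#' @examples
#' countKmers("ACGT", 1)
#' @export
countKmers <- function(seqs, k) {
  k <- as.integer(k)
  if (k < 1L || k > 32L) stop("k must be between 1 and 32")
  seqs <- asSequenceSet(seqs)
  words <- lapply(seqs, function(s) {
    len <- nchar(s)
    nw <- len - k + 1L
    if (nw < 1L) return(character(0))
    chars <- strsplit(s, "")[[1]]
    bad <- cumsum(!(chars %in% DNA_BASES))
    starts <- seq_len(nw)
    valid <- (bad[starts + k - 1L] - c(0L, bad)[starts]) == 0L
    substring(s, starts[valid], starts[valid] + k - 1L)
  })
  words <- unlist(words, use.names = FALSE)
  if (length(words) == 0L)
    return(new("KmerCountTable", k = k, counts = integer(0), nWindows = 0))
  dt <- data.table::data.table(kmer = words)
  tab <- dt[, .N, by = "kmer"]
  data.table::setorder(tab, "kmer")
  new("KmerCountTable", k = k,
      counts = stats::setNames(tab$N, tab$kmer),
      nWindows = as.numeric(length(words)))
}

applyKmerOperation <- function(kmers, operation) {
  x <- Biostrings::DNAStringSet(kmers)
  as.character(switch(operation,
    reverse_complement = Biostrings::reverseComplement(x),
    reverse = Biostrings::reverse(x),
    complement = Biostrings::complement(x),
    stop("unknown operation: ", operation)))
}

#' Single-strand k-mer parity comparison
#'
#' Compares the population count of every k-mer with the count of its
#' image under a strand operation (reverse complement, reverse, or
#' complement): Chargaff's second parity rule predicts near-perfect
#' correlation for the reverse complement. With `zeroInclusive = TRUE`
#' (default) the Pearson correlation, least-squares slope and intercept
#' are taken over all `4^k` k-mers with absent k-mers counted as zero —
#' computed analytically from the observed table, so the full `4^k`
#' vector is never materialised. With `zeroInclusive = FALSE` only k-mer
#' pairs present on both sides enter.
#'
#' @param table a [KmerCountTable-class].
#' @param operation one of `"reverse_complement"`, `"reverse"`,
#'   `"complement"`.
#' @param zeroInclusive logical; include absent k-mers as zero counts.
#' @return one-row data.frame: `k`, `operation`, `correlation`, `slope`,
#'   `intercept`, `n_present`, `n_missing`, `zero_inclusive`.
#' @export
parityCompare <- function(table,
                          operation = c("reverse_complement", "reverse",
                                        "complement"),
                          zeroInclusive = TRUE) {
  operation <- match.arg(operation)
  k <- table@k
  if (k < 1L) stop("degenerate k-mer space")
  cnt <- as.numeric(table@counts)
  names(cnt) <- names(table@counts)
  M <- 4^k
  opNames <- applyKmerOperation(names(cnt), operation)
  y <- cnt[opNames]
  y[is.na(y)] <- 0
  present <- sum(cnt > 0)
  if (zeroInclusive) {
    ## x runs over all 4^k k-mers (absent = 0); y is a permutation of x,
    ## so Sx = Sy and Sxx = Syy.
    Sx <- sum(cnt)
    Sxx <- sum(cnt^2)
    Sxy <- sum(cnt * y)
    vx <- Sxx - Sx^2 / M
    cv <- Sxy - Sx^2 / M
    corr <- if (vx > 0) cv / vx else NA_real_
    slope <- if (vx > 0) cv / vx else NA_real_
    intercept <- (Sx / M) - slope * (Sx / M)
  } else {
    both <- cnt > 0 & y > 0
    if (sum(both) < 2L) {
      corr <- slope <- intercept <- NA_real_
    } else {
      fit <- stats::lm(y[both] ~ cnt[both])
      corr <- stats::cor(cnt[both], y[both])
      slope <- unname(stats::coef(fit)[2])
      intercept <- unname(stats::coef(fit)[1])
    }
  }
  data.frame(k = k, operation = operation, correlation = corr,
             slope = slope, intercept = intercept,
             n_present = as.numeric(present),
             n_missing = M - as.numeric(present),
             zero_inclusive = zeroInclusive, stringsAsFactors = FALSE)
}

#' Present and missing k-mers
#'
#' @param table a [KmerCountTable-class].
#' @return named numeric vector `c(n_present, n_missing)` with
#'   `n_present + n_missing = 4^k`.
#' @examples
#' missingCount(countKmers("AAAA", 2))  # 1 present, 15 missing
#' @export
missingCount <- function(table) {
  present <- sum(table@counts > 0)
  c(n_present = as.numeric(present),
    n_missing = 4^table@k - as.numeric(present))
}
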