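#' Read a peak set from a BED file
#'
#' Thin wrapper around [rtracklayer::import.bed()]; accepts 3+-column BED
#' (0-based half-open on disk, 1-based closed as a `GRanges` in memory).
#'
#' @param path BED file path.
#' @return A [GenomicRanges::GRanges] of peak intervals.
#' @export
readPeaksBed <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1L))
    stop("degenerate peak interval (end <= start) in ", path)
  gr
}

#' Nominal peak-set statistics
#'
#' @param peaks a `GRanges` of peaks.
#' @return list with `N` (number of peaks), `L` (nominal peak length:
#'   mean interval width, rounded) and `totalLength` (sum of widths).
#' @export
peakStats <- function(peaks) {
  list(N = length(peaks),
       L = as.integer(roundHalfUp(mean(GenomicRanges::width(peaks)))),
       totalLength = sum(as.numeric(GenomicRanges::width(peaks))))
}

#' Count element occurrences inside peaks
#'
#' An occurrence is counted once for every peak that fully contains its
#' footprint (default), so an element duplicated inside one peak counts
#' every time and overlapping peaks each count independently — no merging,
#' no per-peak hierarchy. Alternatives: `mode = "any"` counts occurrences
#' that overlap a peak by at least one base; `perPeak = TRUE` collapses to
#' presence/absence per (element, peak) pair.
#'
#' @param occurrences `GRanges` from [scanElements()] (metadata
#'   `element_id`, `k`).
#' @param peaks `GRanges` of peak intervals.
#' @param elements optional element table ([enumerateVariants()] /
#'   [elementUniverse()]); when supplied, elements never seen get explicit
#'   zero counts and the output is ordered like `elements`.
#' @param mode `"within"` (containment, default) or `"any"` (any overlap).
#' @param perPeak logical; count each element at most once per peak.
#' @return data.frame with columns `element_id`, `k`, `count`.
#' @export
countInPeaks <- function(occurrences, peaks, elements = NULL,
                         mode = c("within", "any"), perPeak = FALSE) {
  mode <- match.arg(mode)
  shared <- intersect(as.character(unique(GenomicRanges::seqnames(occurrences))),
                      as.character(unique(GenomicRanges::seqnames(peaks))))
  if (length(occurrences) && length(peaks) && length(shared) == 0L)
    warning("occurrences and peaks share no sequence names; all counts zero")
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    occurrences, peaks, type = mode, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits)
  if (perPeak) {
    keyed <- paste(occurrences$element_id[qh], S4Vectors::subjectHits(hits))
    keep <- !duplicated(keyed)
    qh <- qh[keep]
  }
  dt <- data.table::data.table(element_id = occurrences$element_id[qh],
                               k = occurrences$k[qh])
  agg <- dt[, .N, by = c("element_id", "k")]
  if (is.null(elements)) {
    out <- data.frame(element_id = agg$element_id, k = agg$k,
                      count = agg$N, stringsAsFactors = FALSE)
    return(out[order(out$k, out$element_id), , drop = FALSE])
  }
  cnt <- stats::setNames(agg$N, agg$element_id)
  count <- unname(cnt[elements$id])
  count[is.na(count)] <- 0L
  data.frame(element_id = elements$id, k = elements$k, count = count,
             pos = elements$pos, posMask = elements$posMask,
             stringsAsFactors = FALSE)
}

#' Aggregate counts by substitution level
#'
#' @param counts output of [countInPeaks()].
#' @param schema an [ElementSchema-class] (for the element multiplicity
#'   `m = choose(n, k) * 3^k` column).
#' @return data.frame `k`, `count`, `m`.
#' @export
aggregateByLevel <- function(counts, schema) {
  ks <- sort(unique(counts$k))
  data.frame(k = ks,
             count = vapply(ks, function(k) sum(counts$count[counts$k == k]),
                            numeric(1)),
             m = variantCount(schema, ks))
}

#' Aggregate counts by variant-position combination
#'
#' @param counts output of [countInPeaks()] run with an `elements` table
#'   (needs the `pos` column).
#' @return data.frame `k`, `pos`, `count`, `m` (3^k elements per
#'   combination).
#' @export
aggregateByPositions <- function(counts) {
  if (is.null(counts$pos))
    stop("counts must carry the 'pos' column (run countInPeaks with elements=)")
  dt <- data.table::data.table(k = counts$k, pos = counts$pos,
                               count = counts$count)
  agg <- dt[, list(count = sum(count)), by = c("k", "pos")]
  data.table::setorder(agg, "k", "pos")
  data.frame(k = agg$k, pos = agg$pos, count = agg$count, m = 3^agg$k,
             stringsAsFactors = FALSE)
}

#' Aggregate counts by half-site group and level
#'
#' A level-k element belongs to every group whose fixed positions avoid
#' all its substituted positions, so each count contributes to
#' `choose(n - k, n/2)` groups.
#'
#' @param counts output of [countInPeaks()] run with an `elements` table
#'   (needs `posMask`).
#' @param groups output of [enumerateHalfSiteGroups()].
#' @return numeric matrix, groups x levels (`dimnames` = group id,
#'   level).
#' @export
aggregateByGroup <- function(counts, groups) {
  if (is.null(counts$posMask))
    stop("counts must carry 'posMask' (run countInPeaks with elements=)")
  dt <- data.table::data.table(k = counts$k, posMask = counts$posMask,
                               count = counts$count)
  agg <- dt[, list(count = sum(count)), by = c("k", "posMask")]
  ks <- sort(unique(agg$k))
  out <- matrix(0, nrow(groups), length(ks),
                dimnames = list(groups$id, ks))
  for (i in seq_len(nrow(groups))) {
    ok <- bitwAnd(agg$posMask, groups$fixedMask[i]) == 0L
    if (!any(ok)) next
    sub <- agg[ok]
    for (k in unique(sub$k))
      out[i, as.character(k)] <- sum(sub$count[sub$k == k])
  }
  out
}

#' Assign each peak its least-variant element
#'
#' Labels every peak by the contained element with the fewest
#' substitutions (the consensus wins over a 1-nt variant, and so on);
#' peaks containing no occurrence get `NA`. Ties between distinct
#' minimum-k elements are broken deterministically: leftmost occurrence
#' first, then lexicographically smallest element id; the number of peaks
#' whose label was decided by the tiebreak is reported for audit.
#'
#' @param occurrences `GRanges` from [scanElements()].
#' @param peaks `GRanges` of peaks.
#' @param mode containment rule as in [countInPeaks()].
#' @return list with `assignment` (data.frame `peak`, `element_id`, `k`)
#'   and `nTies`.
#' @export
assignUnique <- function(occurrences, peaks, mode = c("within", "any")) {
  mode <- match.arg(mode)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    occurrences, peaks, type = mode, ignore.strand = TRUE))
  dt <- data.table::data.table(
    peak = S4Vectors::subjectHits(hits),
    element_id = occurrences$element_id[S4Vectors::queryHits(hits)],
    k = occurrences$k[S4Vectors::queryHits(hits)],
    start = GenomicRanges::start(occurrences)[S4Vectors::queryHits(hits)])
  assignment <- data.frame(peak = seq_along(peaks),
                           element_id = NA_character_, k = NA_integer_,
                           stringsAsFactors = FALSE)
  nTies <- 0L
  if (nrow(dt)) {
    data.table::setorder(dt, "peak", "k", "start", "element_id")
    minK <- dt[, list(nMin = length(unique(element_id[k == k[1]]))),
               by = "peak"]
    nTies <- sum(minK$nMin > 1L)
    first <- dt[!duplicated(dt$peak)]
    assignment$element_id[first$peak] <- first$element_id
    assignment$k[first$peak] <- first$k
  }
  list(assignment = assignment, nTies = nTies)
}

#' Extract peak sequences from a genome
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param peaks `GRanges` of peaks (must lie within the genome records).
#' @return A [Biostrings::DNAStringSet], one sequence per peak.
#' @export
peakSequences <- function(genome, peaks) {
  genome <- asSequenceSet(genome)
  chr <- as.character(GenomicRanges::seqnames(peaks))
  if (!all(chr %in% names(genome)))
    stop("peaks reference sequences absent from the genome")
  Biostrings::DNAStringSet(substring(
    genome[chr], GenomicRanges::start(peaks), GenomicRanges::end(peaks)))
}

#' Fraction of peaks matching a degenerate consensus
#'
#' Scans each peak sequence (and its reverse complement) for a window
#' matching an IUPAC degenerate pattern and returns the fraction of peaks
#' with at least one match. A proxy for the resolution of fixed-consensus
#' motif calling; looser (more degenerate) patterns match a superset of
#' the peaks matched by stricter ones.
#'
#' @param peakSeqs `DNAStringSet` of peak sequences (see
#'   [peakSequences()]).
#' @param pattern IUPAC pattern string (e.g. `"RGRACASNSTGTYCYB"`).
#' @return fraction of peaks matched, in `[0, 1]`.
#' @export
iupacMatch <- function(peakSeqs, pattern) {
  pattern <- toupper(pattern)
  codes <- strsplit(pattern, "")[[1]]
  if (!all(codes %in% names(Biostrings::IUPAC_CODE_MAP)))
    stop("invalid IUPAC code in pattern: ",
         paste(setdiff(codes, names(Biostrings::IUPAC_CODE_MAP)),
               collapse = ", "))
  if (!is(peakSeqs, "DNAStringSet"))
    peakSeqs <- Biostrings::DNAStringSet(peakSeqs)
  fwd <- Biostrings::vcountPattern(pattern, peakSeqs, fixed = FALSE)
  rev <- Biostrings::vcountPattern(
    pattern, Biostrings::reverseComplement(peakSeqs), fixed = FALSE)
  mean(fwd + rev > 0)
}
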