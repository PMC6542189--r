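#' Occupancy probability of element variants
#'
#' Evaluates the logistic occupancy link of an [OccupancyModel-class] for
#' a set of variant elements:
#' `P = plogis(alpha - beta * k + sum_w - gamma * crossover)`, where
#' `sum_w` adds the model's pair weight once for every palindromic pair
#' carrying at least one substitution, and `crossover` is 1 when
#' substitutions occur on both sides of the spacer. The link depends only
#' on pair identities and the crossover flag, so
#' `occupancyProb(model, schema, id) == occupancyProb(model, schema,
#' rcElement(schema, id))` for every element.
#'
#' @param model an [OccupancyModel-class].
#' @param schema an [ElementSchema-class].
#' @param ids character vector of element ids.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
occupancyProb <- function(model, schema, ids) {
  pl <- pairLabels(schema)
  w <- rep(0, length(pl))
  names(w) <- pl
  if (length(model@pairWeights)) {
    if (!all(names(model@pairWeights) %in% pl))
      stop("pairWeights names must be pair labels of the schema")
    w[names(model@pairWeights)] <- model@pairWeights
  }
  h <- nPrimary(schema) %/% 2L
  parsed <- parseElementId(ids)
  vapply(parsed, function(pb) {
    k <- length(pb$pos)
    pairs <- unique(pairOfPosition(schema, pb$pos))
    cross <- as.numeric(any(pb$pos <= h) && any(pb$pos > h))
    stats::plogis(model@alpha - model@beta * k + sum(w[pairs]) -
                    model@gamma * cross)
  }, numeric(1))
}

#' Simulate a genome with planted element variants
#'
#' Draws an i.i.d. background sequence from the given base composition and
#' inserts the requested element variants at non-overlapping recorded
#' positions (spacer bases drawn at random, so planted elements carry
#' arbitrary spacers like genomic ones). Fully reproducible from the seed.
#'
#' @param length genome length in nt.
#' @param schema an [ElementSchema-class] (needed when planting).
#' @param plantings named integer vector: element id -> number of copies.
#' @param composition base probabilities, named `A`, `C`, `G`, `T`.
#' @param seed integer seed.
#' @param seqname name of the emitted record.
#' @return list with `genome` (named character vector, length 1),
#'   `truth` (data.frame `seqnames`, `start` (1-based), `end`,
#'   `element_id`, `k`).
#' @export
makeGenome <- function(length, schema = NULL, plantings = NULL,
                       composition = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25),
                       seed = 1L, seqname = "syn1") {
  length <- as.integer(length)
  if (length < 1L) stop("genome length must be positive")
  composition <- composition[DNA_BASES]
  if (anyNA(composition) || any(composition < 0) || sum(composition) <= 0)
    stop("composition must give non-negative weights for A, C, G, T")
  set.seed(as.integer(seed))
  chars <- sample(DNA_BASES, length, replace = TRUE,
                  prob = composition / sum(composition))
  truth <- data.frame(seqnames = character(0), start = integer(0),
                      end = integer(0), element_id = character(0),
                      k = integer(0), stringsAsFactors = FALSE)
  if (!is.null(plantings) && sum(plantings) > 0) {
    if (is.null(schema)) stop("schema is required to plant elements")
    f <- footprint(schema)
    ids <- rep(names(plantings), plantings)
    nPlant <- length(ids)
    if (nPlant * f >= length / 2)
      stop("infeasible planting density: planted footprint exceeds half the genome")
    ## non-overlap by construction: sample disjoint blocks of width f
    blockStarts <- seq(1L, length - f + 1L, by = f)
    if (nPlant > length(blockStarts))
      stop("not enough room to plant ", nPlant, " elements")
    starts <- sort(sample(blockStarts, nPlant))
    ids <- sample(ids)                      # shuffle ids over positions
    seqsPlanted <- realizeElement(schema, ids)
    k <- lengths(lapply(parseElementId(ids), `[[`, "pos"))
    for (i in seq_len(nPlant)) {
      el <- strsplit(seqsPlanted[i], "")[[1]]
      sp <- el == "N"
      if (any(sp)) el[sp] <- sample(DNA_BASES, sum(sp), replace = TRUE)
      chars[starts[i]:(starts[i] + f - 1L)] <- el
    }
    truth <- data.frame(seqnames = seqname, start = starts,
                        end = starts + f - 1L, element_id = ids, k = k,
                        stringsAsFactors = FALSE)
  }
  genome <- stats::setNames(paste(chars, collapse = ""), seqname)
  list(genome = genome, truth = truth)
}

#' Simulate an exactly inversion-symmetric genome
#'
#' Emits `S + sentinel + reverseComplement(S)` for a random half-sequence
#' `S`. The sentinel (`N`) prevents windows from spanning the junction, so
#' the forward-strand count of every k-mer equals the count of its
#' reverse complement *exactly*, for every k — the construction used to
#' validate the parity engine.
#'
#' @param length total number of ACGT bases (even); the emitted record has
#'   `length + 1` characters including the sentinel.
#' @param seed integer seed.
#' @param composition base probabilities for the half-sequence.
#' @param seqname record name.
#' @return named character vector of length 1.
#' @export
makeMirroredGenome <- function(length, seed = 1L,
                               composition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                               seqname = "mirror1") {
  length <- as.integer(length)
  if (length < 2L || length %% 2L != 0L)
    stop("length must be a positive even number of bases")
  set.seed(as.integer(seed))
  composition <- composition[DNA_BASES]
  half <- paste(sample(DNA_BASES, length %/% 2L, replace = TRUE,
                       prob = composition / sum(composition)),
                collapse = "")
  stats::setNames(paste0(half, "N", revcompChar(half)), seqname)
}

#' Simulate a ChIP peak set over a genome
#'
#' Scans the genome for all element occurrences up to `kMax`, emits a peak
#' of length `L` centred on each occurrence with the probability given by
#' the occupancy model, and adds `NBackground` peaks at uniform positions.
#' Alongside the peaks, the generator returns its own expected per-element
#' count table (occurrences times occupancy probability, plus the chance
#' of a background peak containing the occurrence), the ground truth for
#' recovery tests.
#'
#' @param genome named character vector (e.g. from [makeGenome()]).
#' @param schema an [ElementSchema-class].
#' @param model an [OccupancyModel-class].
#' @param kMax maximum substitution level considered bindable.
#' @param NBackground number of uniformly placed background peaks.
#' @param L peak length (must be at least the element footprint).
#' @param seed integer seed.
#' @return list with `peaks` (`GRanges`), `expected` (data.frame
#'   `element_id`, `k`, `nOccurrences`, `pOccupancy`, `expectedCount`),
#'   and `occurrences` (the scan result).
#' @export
makePeaks <- function(genome, schema, model, kMax, NBackground, L,
                      seed = 1L) {
  f <- footprint(schema)
  L <- as.integer(L)
  if (L < f) stop("peak length L must be at least the element footprint (",
                  f, ")")
  genome <- asSequenceSet(genome)
  glen <- nchar(genome)
  if (any(glen < L)) stop("genome records must be at least one peak long")
  occ <- scanElements(genome, schema, kMax)
  set.seed(as.integer(seed))
  peaks <- GenomicRanges::GRanges()
  pOcc <- numeric(0)
  if (length(occ)) {
    uid <- unique(occ$element_id)
    pMap <- stats::setNames(occupancyProb(model, schema, uid), uid)
    pOcc <- unname(pMap[occ$element_id])
    emit <- stats::runif(length(occ)) < pOcc
    if (any(emit)) {
      centre <- GenomicRanges::start(occ)[emit] + (f - 1L) %/% 2L
      st <- centre - (L - 1L) %/% 2L
      chrLen <- glen[as.character(GenomicRanges::seqnames(occ))[emit]]
      st <- pmin(pmax(st, 1L), chrLen - L + 1L)
      peaks <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(occ))[emit],
        IRanges::IRanges(start = st, width = L))
    }
  }
  if (NBackground > 0) {
    chr <- sample(names(genome), NBackground, replace = TRUE,
                  prob = glen / sum(glen))
    st <- vapply(glen[chr] - L + 1L, function(m) sample.int(m, 1L),
                 integer(1))
    bg <- GenomicRanges::GRanges(chr, IRanges::IRanges(start = st,
                                                       width = L))
    peaks <- if (length(peaks)) c(peaks, bg) else bg
  }
  expected <- NULL
  if (length(occ)) {
    dt <- data.table::data.table(element_id = occ$element_id, k = occ$k,
                                 p = pOcc)
    agg <- dt[, list(nOccurrences = .N, pOccupancy = p[1]),
              by = c("element_id", "k")]
    ## chance that one uniform background peak fully contains an occurrence
    pBg <- NBackground * (L - f + 1) / (sum(glen) - L + 1)
    expected <- data.frame(
      element_id = agg$element_id, k = agg$k,
      nOccurrences = agg$nOccurrences, pOccupancy = agg$pOccupancy,
      expectedCount = agg$nOccurrences * (agg$pOccupancy + pBg),
      stringsAsFactors = FALSE)
    expected <- expected[order(expected$k, expected$element_id), ]
    rownames(expected) <- NULL
  }
  list(peaks = peaks, expected = expected, occurrences = occ)
}
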