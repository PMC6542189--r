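#' @rdname ElementSchema-class
#' @param x an `ElementSchema`.
#' @export
setGeneric("schemaName", function(x) standardGeneric("schemaName"))
#' @rdname ElementSchema-class
#' @export
setMethod("schemaName", "ElementSchema", function(x) x@name)

#' @rdname ElementSchema-class
#' @export
setGeneric("halfSite", function(x) standardGeneric("halfSite"))
#' @rdname ElementSchema-class
#' @export
setMethod("halfSite", "ElementSchema", function(x) x@halfSite)

#' @rdname ElementSchema-class
#' @export
setGeneric("spacerLength", function(x) standardGeneric("spacerLength"))
#' @rdname ElementSchema-class
#' @export
setMethod("spacerLength", "ElementSchema", function(x) x@spacerLen)

#' @rdname ElementSchema-class
#' @export
setGeneric("nPrimary", function(x) standardGeneric("nPrimary"))
#' @rdname ElementSchema-class
#' @export
setMethod("nPrimary", "ElementSchema", function(x) 2L * nchar(x@halfSite))

#' @rdname ElementSchema-class
#' @export
setGeneric("footprint", function(x) standardGeneric("footprint"))

#' @describeIn ElementSchema-class total element length on the genome,
#'   primary positions plus spacer.
#' @export
setMethod("footprint", "ElementSchema", function(x) nPrimary(x) + x@spacerLen)

#' @rdname ElementSchema-class
#' @param spacer character used to render the unconstrained spacer
#'   positions (`"N"` by default).
#' @export
setGeneric("consensusSequence",
           function(x, spacer = "N") standardGeneric("consensusSequence"))

#' @describeIn ElementSchema-class the full consensus,
#'   `half_site + spacer + reverseComplement(half_site)`.
#' @export
setMethod("consensusSequence", "ElementSchema", function(x, spacer = "N") {
  paste0(x@halfSite, strrep(spacer, x@spacerLen), revcompChar(x@halfSite))
})

#' Primary-position consensus bases
#'
#' The consensus base at each of the `n` primary positions, spacer excluded.
#' Positions `1..n/2` are the half-site; positions `n/2+1..n` are its
#' reverse complement.
#'
#' @param schema an [ElementSchema-class].
#' @return character vector of length `n`.
#' @export
primaryBases <- function(schema) {
  left <- strsplit(schema@halfSite, "")[[1]]
  c(left, rev(complementBase(left)))
}

#' Palindromic pair map
#'
#' @param schema an [ElementSchema-class].
#' @return integer matrix with columns `p` and `partner` (`n + 1 - p`),
#'   one row per palindromic position pair `p = 1..n/2`.
#' @export
pairMap <- function(schema) {
  n <- nPrimary(schema)
  h <- n %/% 2L
  cbind(p = seq_len(h), partner = n + 1L - seq_len(h))
}

#' Palindromic pair labels
#'
#' @param schema an [ElementSchema-class].
#' @return character vector like `c("1-10", "2-9", ...)`, indexed by the
#'   lower member of each pair.
#' @export
pairLabels <- function(schema) {
  pm <- pairMap(schema)
  paste0(pm[, "p"], "-", pm[, "partner"])
}

## Pair index (1..n/2) of each primary position.
pairOfPosition <- function(schema, pos) {
  n <- nPrimary(schema)
  ifelse(pos <= n %/% 2L, pos, n + 1L - pos)
}

#' Built-in response-element schemas
#'
#' Stock schemas for the nuclear-receptor and p53 response elements:
#' \describe{
#'   \item{ERE13}{estrogen response element, `GGTCAnnnTGACC` (n = 10).}
#'   \item{HRE13}{ketosteroid hormone response element, `GAACAnnnTGTTC`.}
#'   \item{ERE15}{flank-extended ERE, `AGGTCAnnnTGACCT` (n = 12).}
#'   \item{HRE15}{flank-extended HRE, `AGAACAnnnTGTTCT`.}
#'   \item{p53RE}{p53 response element, `TGCCCGGGCA` (no spacer).}
#' }
#'
#' @param name one of `"ERE13"`, `"HRE13"`, `"ERE15"`, `"HRE15"`, `"p53RE"`.
#' @return An [ElementSchema-class].
#' @examples
#' consensusSequence(builtinSchema("HRE13"))
#' @export
builtinSchema <- function(name = c("ERE13", "HRE13", "ERE15", "HRE15",
                                   "p53RE")) {
  name <- match.arg(name)
  switch(name,
    ERE13 = ElementSchema("ERE13", "GGTCA", 3),
    HRE13 = ElementSchema("HRE13", "GAACA", 3),
    ERE15 = ElementSchema("ERE15", "AGGTCA", 3),
    HRE15 = ElementSchema("HRE15", "AGAACA", 3),
    p53RE = ElementSchema("p53RE", "TGCCC", 0))
}

#' Empirical vacancy hierarchies
#'
#' The preference order of the palindromic position pairs (most preferred
#' vacancy first) observed for each receptor class, used to order the
#' half-site-group display axis.
#'
#' @param name schema name as in [builtinSchema()].
#' @return character vector of pair labels, a permutation of
#'   `pairLabels(builtinSchema(name))`.
#' @export
vacancyHierarchy <- function(name = c("ERE13", "HRE13", "ERE15", "HRE15",
                                      "p53RE")) {
  name <- match.arg(name)
  switch(name,
    ERE13 = c("3-8", "1-10", "5-6", "4-7", "2-9"),
    HRE13 = c("2-9", "5-6", "1-10", "4-7", "3-8"),
    ERE15 = c("4-9", "1-12", "2-11", "6-7", "5-8", "3-10"),
    HRE15 = c("3-10", "1-12", "6-7", "2-11", "5-8", "4-9"),
    p53RE = c("5-6", "1-10", "3-8", "4-7", "2-9"))
}
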