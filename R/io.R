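## TSV conventions: tab-separated, header row, "." for missing values,
## fixed column orders. All genomic coordinates written to BED are 0-based
## half-open; 1-based numbering exists only for primary positions inside
## an element.

writeTsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.numeric(v)) v <- as.character(v)
    v[is.na(v)] <- "."
    df[[j]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an element enumeration as TSV
#'
#' Columns: `element_id`, `k`, `substitutions` (comma-separated
#' `pos:base` terms), `sequence` (spacer as N) and `rc_element_id`.
#'
#' @param elements [enumerateVariants()] / [elementUniverse()] output.
#' @param schema the [ElementSchema-class] used.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeElementsTsv <- function(elements, schema, path) {
  subs <- vapply(parseElementId(elements$id), function(pb) {
    if (length(pb$pos) == 0L) return(".")
    paste(paste0(pb$pos, ":", pb$base), collapse = ",")
  }, character(1))
  writeTsv(data.frame(
    element_id = elements$id, k = elements$k, substitutions = subs,
    sequence = elements$seq,
    rc_element_id = rcElement(schema, elements$id),
    stringsAsFactors = FALSE), path)
}

#' Write the half-site-group taxonomy as TSV
#'
#' @param groups [enumerateHalfSiteGroups()] output.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGroupsTsv <- function(groups, path) {
  writeTsv(groups[, c("id", "fixed", "nV", "nD", "nS", "vacPairs",
                      "dblPairs", "vacLabel", "dblLabel", "rcId",
                      "innate", "representative")], path)
}

#' Write element occurrences as 6-column BED
#'
#' Emits `chrom, start (0-based), end (half-open), element_id, k,
#' strand`; all occurrences are forward-strand by construction.
#'
#' @param occurrences `GRanges` from [scanElements()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeOccurrencesBed <- function(occurrences, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(occurrences)),
    start = GenomicRanges::start(occurrences) - 1L,
    end = GenomicRanges::end(occurrences),
    name = occurrences$element_id,
    score = occurrences$k,
    strand = "+", stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read element occurrences from 6-column BED
#'
#' Inverse of [writeOccurrencesBed()].
#'
#' @param path BED file.
#' @return `GRanges` with `element_id` and `k` metadata.
#' @export
readOccurrencesBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand, element_id = df$name, k = as.integer(df$score))
}

#' Write a genome as FASTA
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFastaFile <- function(genome, path) {
  if (!is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(asSequenceSet(genome))
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaFile <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  asSequenceSet(Biostrings::readDNAStringSet(path))
}

#' Write a peak set as 3-column BED
#'
#' @param peaks `GRanges`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePeaksBed <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' YAML configuration naming the schema, analysis parameters and file
#' paths for a pipeline run. Recognised fields: `schema` (built-in name),
#' `k_max`, `hierarchy` (pair labels, optional — defaults to the
#' schema's), `grouping` (class-size signature or named pair lists),
#' `peaks` (BED path), `genome` (FASTA path), `p` (significance level),
#' `out_dir`, `seed`.
#'
#' @param path YAML file.
#' @return validated named list with an `ElementSchema` in `$schema` and
#'   defaults filled in.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema)) stop("config must name a schema")
  schema <- builtinSchema(cfg$schema)
  hierarchy <- if (is.null(cfg$hierarchy)) vacancyHierarchy(cfg$schema)
    else as.character(cfg$hierarchy)
  if (!setequal(hierarchy, pairLabels(schema)))
    stop("config hierarchy is not a permutation of the schema's pairs")
  kMax <- if (is.null(cfg$k_max)) nPrimary(schema) %/% 2L else
    as.integer(cfg$k_max)
  if (kMax < 0L || kMax > nPrimary(schema))
    stop("config k_max out of range")
  p <- if (is.null(cfg$p)) 0.001 else as.numeric(cfg$p)
  if (p <= 0 || p >= 0.5) stop("config p must be in (0, 0.5)")
  list(schemaName = cfg$schema, schema = schema, kMax = kMax,
       hierarchy = hierarchy, grouping = cfg$grouping,
       peaks = cfg$peaks, genome = cfg$genome, p = p,
       outDir = if (is.null(cfg$out_dir)) "." else cfg$out_dir,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}
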