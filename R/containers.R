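#' Genome annotation container
#'
#' Typed genomic features of a single-replicon genome, 1-based inclusive
#' coordinates. Recognized feature kinds are CDS, tRNA, rRNA and sRNA.
#'
#' @param features data.frame with columns `id`, `kind`, `start`, `end`,
#'   `strand` ("+"/"-"). May have zero rows.
#' @param genome_id Reference sequence name.
#' @param genome_length Genome size in bp (positive integer).
#'
#' @return An object of class `genome_annotation`: a list with elements
#'   `genome_id`, `genome_length` and `features`.
#' @export
#' @examples
#' genome_annotation(
#'   data.frame(id = "cdsA", kind = "CDS", start = 100, end = 399, strand = "+"),
#'   genome_id = "toy", genome_length = 1000
#' )
genome_annotation <- function(features, genome_id, genome_length) {
  genome_length <- as.integer(genome_length)
  if (is.null(features) || nrow(features) == 0) {
    features <- data.frame(
      id = character(0), kind = character(0),
      start = integer(0), end = integer(0), strand = character(0)
    )
  }
  required <- c("id", "kind", "start", "end", "strand")
  if (!all(required %in% names(features))) {
    stop("features must have columns: ", paste(required, collapse = ", "))
  }
  features <- features[, required]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (genome_length < 1) stop("genome_length must be positive")
  if (nrow(features) > 0) {
    bad <- which(features$start < 1 | features$start > features$end |
                   features$end > genome_length)
    if (length(bad) > 0) {
      stop("feature '", features$id[bad[1]],
           "' violates 1 <= start <= end <= genome_length")
    }
    if (!all(features$kind %in% FEATURE_KINDS)) {
      stop("feature kind must be one of: ", paste(FEATURE_KINDS, collapse = ", "))
    }
    if (anyDuplicated(features$id)) stop("feature identifiers must be unique")
    if (!all(features$strand %in% c("+", "-"))) {
      stop("feature strand must be '+' or '-'")
    }
  }
  rownames(features) <- NULL
  structure(
    list(genome_id = as.character(genome_id), genome_length = genome_length,
         features = features),
    class = "genome_annotation"
  )
}

FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "sRNA")

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", x$genome_id, "(", x$genome_length, "bp )\n")
  print(table(factor(x$features$kind, levels = FEATURE_KINDS)))
  invisible(x)
}

#' Read set container
#'
#' Uniquely mapped read intervals of one sample plus the total mapped-read
#' count used for RPKM normalization.
#'
#' @param starts,ends 1-based inclusive read coordinates (equal length).
#' @param sample_label Sample name, e.g. "IP" or "control".
#' @param total_mapped Total mapped reads for normalization; defaults to
#'   the number of reads supplied (they are equal when no reads have been
#'   filtered after loading).
#'
#' @return An object of class `read_set`: list with `sample_label`,
#'   `ranges` (an [IRanges::IRanges]) and `total_mapped`.
#' @export
#' @examples
#' read_set(c(100, 200), c(134, 234), "IP")
read_set <- function(starts, ends, sample_label, total_mapped = length(starts)) {
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (length(starts) != length(ends)) stop("starts and ends differ in length")
  if (any(ends < starts)) stop("read end < start")
  total_mapped <- as.integer(total_mapped)
  if (total_mapped < length(starts)) {
    stop("total_mapped must be >= number of retained reads")
  }
  if (total_mapped < 0) stop("total_mapped must be non-negative")
  structure(
    list(sample_label = as.character(sample_label),
         ranges = IRanges::IRanges(start = starts, end = ends),
         total_mapped = total_mapped),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", x$sample_label, "-", length(x$ranges), "reads,",
      "total_mapped =", x$total_mapped, "\n")
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$ranges)
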