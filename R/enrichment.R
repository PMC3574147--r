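#' Count reads overlapping a peak
#'
#' A read is counted when its interval overlaps the peak by at least one
#' base. Reads (~35 nt) are short relative to peaks (>= 50 nt), so the
#' any-overlap rule is a simple, monotone counting rule.
#'
#' @param reads A [read_set()].
#' @param peak One-row peak data.frame (or list with `start`, `end`).
#' @return Integer read count.
#' @export
count_reads_in_peak <- function(reads, peak) {
  stopifnot(inherits(reads, "read_set"))
  IRanges::countOverlaps(
    IRanges::IRanges(start = as.integer(peak$start), end = as.integer(peak$end)),
    reads$ranges
  )
}

#' RPKM: reads per kilobase per million mapped reads
#'
#' `count * 1e9 / (length * total_mapped)`, the library-size- and
#' length-normalized abundance used to score peaks.
#'
#' @param count Reads in the region.
#' @param length Region length in bp (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @export
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
rpkm <- function(count, length, total_mapped) {
  if (any(length <= 0)) stop("region length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  count * 1e9 / (length * total_mapped)
}

#' Score peaks by IP/control RPKM ratio
#'
#' Quantifies each peak in both samples and computes
#' `rpkm_ratio = rpkm_ip / rpkm(max(count_ctrl, control_pseudocount))`.
#' The pseudocount keeps ratios finite for peaks absent from the control,
#' consistent with the finite ">1,000" ratios reported for the most
#' enriched RNAs.
#'
#' @param peaks Peak data.frame from [call_peaks()] or [peak_union()].
#' @param ip,ctrl [read_set()]s for the IP and mock-control samples.
#' @param config A [pipeline_config()].
#' @return `peaks` with columns `count_ip`, `count_ctrl`, `rpkm_ip`,
#'   `rpkm_ctrl`, `rpkm_ratio` added.
#' @export
score_peaks <- function(peaks, ip, ctrl, config = pipeline_config()) {
  stopifnot(inherits(ip, "read_set"), inherits(ctrl, "read_set"))
  if (nrow(peaks) == 0) {
    peaks$count_ip <- integer(0)
    peaks$count_ctrl <- integer(0)
    peaks$rpkm_ip <- numeric(0)
    peaks$rpkm_ctrl <- numeric(0)
    peaks$rpkm_ratio <- numeric(0)
    return(peaks)
  }
  ir <- IRanges::IRanges(start = peaks$start, end = peaks$end)
  peaks$count_ip <- IRanges::countOverlaps(ir, ip$ranges)
  peaks$count_ctrl <- IRanges::countOverlaps(ir, ctrl$ranges)
  len <- peaks$end - peaks$start + 1
  peaks$rpkm_ip <- rpkm(peaks$count_ip, len, ip$total_mapped)
  peaks$rpkm_ctrl <- rpkm(peaks$count_ctrl, len, ctrl$total_mapped)
  denom <- rpkm(pmax(peaks$count_ctrl, config$control_pseudocount), len,
                ctrl$total_mapped)
  peaks$rpkm_ratio <- peaks$rpkm_ip / denom
  peaks
}

#' Partition scored peaks at the enrichment cutoff
#'
#' Peaks with `rpkm_ratio >= ratio_threshold` (default 2, the published
#' cutoff; the boundary value counts as enriched so the partition is
#' exhaustive) are enriched, the rest are background.
#'
#' @param peaks Scored peak data.frame.
#' @param config A [pipeline_config()].
#' @return list with elements `enriched` and `background` (disjoint,
#'   exhaustive).
#' @export
filter_enriched <- function(peaks, config = pipeline_config()) {
  if (is.null(peaks$rpkm_ratio)) stop("peaks must be scored first")
  sel <- peaks$rpkm_ratio >= config$ratio_threshold
  list(enriched = peaks[sel, , drop = FALSE],
       background = peaks[!sel, , drop = FALSE])
}
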