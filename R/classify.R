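PEAK_CATEGORIES <- c("trna_rrna", "srna", "leader", "orf_full", "orf_start",
                     "orf_stop", "orf_internal", "unknown")

#' Infer peak strand from TSS evidence
#'
#' The sequencing library is unstranded, so directionality is inferred
#' from an independently mapped TSS table: a TSS oriented into the peak
#' and located within `tss_window` bp upstream of it (or inside it)
#' supports its strand. A plus-strand TSS supports the peak when its
#' position lies in `[start - tss_window, end]`; a minus-strand TSS when
#' it lies in `[start, end + tss_window]`. If exactly one strand is
#' supported that strand is returned, otherwise `"ambiguous"`.
#'
#' @param peak One-row peak data.frame (or list with `start`, `end`).
#' @param tss data.frame with columns `position`, `strand`.
#' @param config A [pipeline_config()].
#' @return `"+"`, `"-"` or `"ambiguous"`.
#' @export
infer_strand <- function(peak, tss, config = pipeline_config()) {
  s <- as.integer(peak$start)
  e <- as.integer(peak$end)
  w <- config$tss_window
  plus <- any(tss$strand == "+" & tss$position >= s - w & tss$position <= e)
  minus <- any(tss$strand == "-" & tss$position >= s & tss$position <= e + w)
  if (plus && !minus) "+" else if (minus && !plus) "-" else "ambiguous"
}

#' Classify a peak into a functional category
#'
#' First matching rule wins:
#' 1. `trna_rrna` -- overlaps any tRNA or rRNA feature (housekeeping RNAs
#'    are filtered before interpreting the remaining peaks);
#' 2. `srna` -- overlaps an annotated sRNA feature;
#' 3. `leader` -- the inferred strand matches a TSS whose nearest
#'    downstream same-strand CDS starts within `leader_max_length` bp,
#'    the CDS start lies downstream of the peak, and the peak lies within
#'    the TSS-to-CDS interval;
#' 4. ORF rules against strand-compatible (or, for ambiguous peaks, any)
#'    overlapping CDSs: `orf_full` when the peak contains the whole CDS;
#'    `orf_start` when it overlaps the start codon (first three coding
#'    bases in strand orientation) but not the stop codon; `orf_stop` for
#'    the converse; `orf_internal` when it lies strictly inside the CDS
#'    touching neither codon;
#' 5. `unknown` otherwise (including peaks that touch both codons without
#'    containing the CDS, and intergenic peaks without TSS support).
#'
#' @param peak One-row peak data.frame (or list with `start`, `end`).
#' @param annotation A [genome_annotation()].
#' @param strand Inferred peak strand (`"+"`, `"-"` or `"ambiguous"`),
#'   usually from [infer_strand()].
#' @param tss TSS data.frame (`position`, `strand`); used by the leader
#'   rule.
#' @param config A [pipeline_config()].
#' @return A category string (one of `trna_rrna`, `srna`, `leader`,
#'   `orf_full`, `orf_start`, `orf_stop`, `orf_internal`, `unknown`).
#' @export
classify_peak <- function(peak, annotation, strand, tss,
                          config = pipeline_config()) {
  stopifnot(inherits(annotation, "genome_annotation"))
  s <- as.integer(peak$start)
  e <- as.integer(peak$end)
  f <- annotation$features
  olap <- f$start <= e & f$end >= s

  if (any(olap & f$kind %in% c("tRNA", "rRNA"))) return("trna_rrna")
  if (any(olap & f$kind == "sRNA")) return("srna")

  cds <- f[f$kind == "CDS", , drop = FALSE]

  # (3) 5' leader: peak inside a TSS -> CDS-start interval on its strand
  if (strand %in% c("+", "-") && nrow(tss) > 0 && nrow(cds) > 0) {
    for (t in tss$position[tss$strand == strand]) {
      if (strand == "+") {
        down <- cds$start[cds$strand == "+" & cds$start > t]
        if (length(down) == 0) next
        cstart <- min(down)
        if (cstart - t <= config$leader_max_length &&
            s >= t && e <= cstart - 1 && cstart > e) {
          return("leader")
        }
      } else {
        down <- cds$end[cds$strand == "-" & cds$end < t]
        if (length(down) == 0) next
        cstart <- max(down)  # 5' end of a minus-strand CDS
        if (t - cstart <= config$leader_max_length &&
            e <= t && s >= cstart + 1 && cstart < s) {
          return("leader")
        }
      }
    }
  }

  # (4) ORF subclasses
  hit <- cds[cds$start <= e & cds$end >= s, , drop = FALSE]
  if (strand %in% c("+", "-")) {
    hit <- hit[hit$strand == strand, , drop = FALSE]
  }
  if (nrow(hit) > 0) {
    # codon coordinates are genomic; start/stop labels follow CDS strand
    first3_s <- hit$start
    first3_e <- hit$start + 2L
    last3_s <- hit$end - 2L
    last3_e <- hit$end
    hits_first <- s <= first3_e & e >= first3_s
    hits_last <- s <= last3_e & e >= last3_s
    start_olap <- ifelse(hit$strand == "+", hits_first, hits_last)
    stop_olap <- ifelse(hit$strand == "+", hits_last, hits_first)
    contains <- s <= hit$start & e >= hit$end
    internal <- s > first3_e & e < last3_s
    if (any(contains)) return("orf_full")
    if (any(start_olap & !stop_olap)) return("orf_start")
    if (any(stop_olap & !start_olap)) return("orf_stop")
    if (any(internal)) return("orf_internal")
  }
  "unknown"
}

#' Infer strands and classify a table of peaks
#'
#' Convenience wrapper applying [infer_strand()] and [classify_peak()]
#' row-wise; adds `strand` and `category` columns.
#'
#' @param peaks Peak data.frame (typically scored).
#' @param annotation A [genome_annotation()].
#' @param tss TSS data.frame (`position`, `strand`).
#' @param config A [pipeline_config()].
#' @return `peaks` with `strand` and `category` columns.
#' @export
classify_peaks <- function(peaks, annotation, tss, config = pipeline_config()) {
  n <- nrow(peaks)
  strand <- character(n)
  category <- character(n)
  for (i in seq_len(n)) {
    pk <- peaks[i, ]
    strand[i] <- infer_strand(pk, tss, config)
    category[i] <- classify_peak(pk, annotation, strand[i], tss, config)
  }
  peaks$strand <- strand
  peaks$category <- category
  peaks
}

#' Summarize classified peaks by category
#'
#' Per category: count, proportion of total, min/max/mean length, and
#' median RPKM ratio. Overall median ratios are reported separately for
#' the enriched and background partitions.
#'
#' @param peaks Scored and classified peak data.frame.
#' @param config A [pipeline_config()] (supplies the enrichment cutoff for
#'   the partition medians).
#' @return list of class `peak_summary` with `by_category` and `overall`
#'   data.frames.
#' @export
summarize_categories <- function(peaks, config = pipeline_config()) {
  if (nrow(peaks) == 0) {
    return(structure(list(
      by_category = data.frame(
        category = character(0), count = integer(0), proportion = numeric(0),
        min_length = integer(0), max_length = integer(0),
        mean_length = numeric(0), median_rpkm_ratio = numeric(0)
      ),
      overall = data.frame(partition = character(0), count = integer(0),
                           median_rpkm_ratio = numeric(0))
    ), class = "peak_summary"))
  }
  cats <- unique(peaks$category)
  by_cat <- do.call(rbind, lapply(cats, function(cc) {
    p <- peaks[peaks$category == cc, ]
    data.frame(
      category = cc, count = nrow(p), proportion = nrow(p) / nrow(peaks),
      min_length = min(p$length), max_length = max(p$length),
      mean_length = mean(p$length),
      median_rpkm_ratio = stats::median(p$rpkm_ratio)
    )
  }))
  by_cat <- by_cat[order(-by_cat$count, by_cat$category), ]
  rownames(by_cat) <- NULL
  parts <- filter_enriched(peaks, config)
  overall <- data.frame(
    partition = c("enriched", "background"),
    count = c(nrow(parts$enriched), nrow(parts$background)),
    median_rpkm_ratio = c(
      if (nrow(parts$enriched) > 0) stats::median(parts$enriched$rpkm_ratio) else NA_real_,
      if (nrow(parts$background) > 0) stats::median(parts$background$rpkm_ratio) else NA_real_
    )
  )
  structure(list(by_category = by_cat, overall = overall),
            class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat("Peaks by category:\n")
  print(x$by_category, row.names = FALSE)
  cat("\nPartition medians:\n")
  print(x$overall, row.names = FALSE)
  invisible(x)
}
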