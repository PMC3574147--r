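#' Run the full enrichment pipeline
#'
#' Orchestrates coverage -> peak calling -> scoring -> strand inference ->
#' classification -> summary as one deterministic run. Peaks are called
#' independently on the IP and control coverage tracks; by default the
#' union of intervals called in either sample is quantified in both
#' (`ip_only = TRUE` restricts to IP-called intervals). Outputs, when
#' `out_dir` is given: the classified peak table, enriched/background
#' tables, a category summary, bedGraph coverage for both samples, and a
#' JSON run manifest with the configuration snapshot, input digests and
#' per-stage record counts.
#'
#' @param ip,ctrl [read_set()]s or paths to SAM/BED files.
#' @param annotation A [genome_annotation()] or a GFF3 path.
#' @param tss TSS data.frame or a TSV path.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param ip_only Quantify only IP-called intervals.
#' @param seed Optional integer recorded in the manifest (the pipeline
#'   itself is deterministic; a seed only matters for upstream
#'   simulation).
#' @return list of class `rip_run` with elements `peaks` (classified,
#'   scored), `enriched`, `background`, `summary`, `tracks` and
#'   `manifest`.
#' @export
run_pipeline <- function(ip, ctrl, annotation, tss,
                         config = pipeline_config(), out_dir = NULL,
                         ip_only = FALSE, seed = NULL) {
  digests <- list()
  take <- function(x, reader, label) {
    if (is.character(x)) {
      digests[[label]] <<- unname(tools::md5sum(x))
      reader(x)
    } else {
      digests[[label]] <<- "in-memory"
      x
    }
  }
  annotation <- take(annotation, read_annotation, "annotation")
  tss <- take(tss, read_tss, "tss")
  ip <- take(ip, function(p) read_reads(p, "IP"), "ip")
  ctrl <- take(ctrl, function(p) read_reads(p, "control"), "ctrl")
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(ip, "read_set"), inherits(ctrl, "read_set"))

  glen <- annotation$genome_length
  gid <- annotation$genome_id
  track_ip <- compute_coverage(ip, glen, gid)
  track_ctrl <- compute_coverage(ctrl, glen, gid)
  peaks_ip <- call_peaks(track_ip, config, id_prefix = "ip")
  peaks_ctrl <- call_peaks(track_ctrl, config, id_prefix = "ctrl")
  peaks <- peak_union(peaks_ip, peaks_ctrl, ip_only = ip_only)
  peaks <- score_peaks(peaks, ip, ctrl, config)
  peaks <- classify_peaks(peaks, annotation, tss, config)
  parts <- filter_enriched(peaks, config)
  summ <- summarize_categories(peaks, config)

  cat_counts <- as.list(table(parts$enriched$category))
  manifest <- list(
    tool = "ripenrich",
    version = as.character(utils::packageVersion("ripenrich")),
    seed = seed,
    config = unclass(config),
    inputs = digests,
    counts = list(
      reads_ip = length(ip), reads_ctrl = length(ctrl),
      total_mapped_ip = ip$total_mapped, total_mapped_ctrl = ctrl$total_mapped,
      peaks_called_ip = nrow(peaks_ip), peaks_called_ctrl = nrow(peaks_ctrl),
      peaks_quantified = nrow(peaks), peaks_enriched = nrow(parts$enriched),
      enriched_by_category = cat_counts
    )
  )
  stopifnot(manifest$counts$peaks_enriched <= manifest$counts$peaks_quantified)

  res <- structure(
    list(peaks = peaks, enriched = parts$enriched,
         background = parts$background, summary = summ,
         tracks = list(ip = track_ip, ctrl = track_ctrl),
         manifest = manifest),
    class = "rip_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peak_table(peaks, file.path(out_dir, "peaks.tsv"))
    write_peak_table(parts$enriched, file.path(out_dir, "peaks_enriched.tsv"))
    utils::write.table(summ$by_category,
                       file.path(out_dir, "category_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$overall,
                       file.path(out_dir, "partition_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph(track_ip, file.path(out_dir, "ip.bedGraph"))
    write_bedgraph(track_ctrl, file.path(out_dir, "ctrl.bedGraph"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' @export
print.rip_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("RIP-seq enrichment run\n")
  cat("  reads: IP", cnt$reads_ip, "/ control", cnt$reads_ctrl, "\n")
  cat("  peaks: IP-called", cnt$peaks_called_ip,
      ", control-called", cnt$peaks_called_ctrl,
      ", quantified", cnt$peaks_quantified,
      ", enriched", cnt$peaks_enriched, "\n")
  print(x$summary)
  invisible(x)
}

#' Compare enriched peaks with ground-truth regions
#'
#' For each non-housekeeping truth region, finds the enriched peak with
#' the largest positional Jaccard index (intersection over union) and
#' reports whether the region was recovered, the inferred strand and the
#' assigned category.
#'
#' @param run A `rip_run` from [run_pipeline()].
#' @param truth Truth table from [generate_annotation()].
#' @param min_jaccard Jaccard threshold counting a region as recovered.
#' @return data.frame, one row per enriched truth region: `region_id`,
#'   `category`, `fold`, `jaccard`, `recovered`, `peak_strand`,
#'   `peak_category`, `strand_ok`, `category_ok`.
#' @export
evaluate_recovery <- function(run, truth, min_jaccard = 0.5) {
  truth <- truth[truth$category != "trna_rrna", , drop = FALSE]
  pk <- run$enriched
  out <- truth[, c("region_id", "category", "fold", "strand")]
  out$jaccard <- 0
  out$peak_strand <- NA_character_
  out$peak_category <- NA_character_
  for (i in seq_len(nrow(truth))) {
    if (nrow(pk) == 0) break
    inter <- pmax(0, pmin(truth$end[i], pk$end) - pmax(truth$start[i], pk$start) + 1)
    uni <- (truth$end[i] - truth$start[i] + 1) + pk$length - inter
    j <- inter / uni
    b <- which.max(j)
    out$jaccard[i] <- j[b]
    if (j[b] > 0) {
      out$peak_strand[i] <- pk$strand[b]
      out$peak_category[i] <- pk$category[b]
    }
  }
  out$recovered <- out$jaccard >= min_jaccard
  out$strand_ok <- !is.na(out$peak_strand) & out$peak_strand == out$strand
  out$category_ok <- !is.na(out$peak_category) & out$peak_category == out$category
  out
}
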