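#' Read a genome annotation from GFF3
#'
#' Parses a GFF3 file (1-based inclusive coordinates) into a
#' [genome_annotation()]. Only CDS, tRNA, rRNA and sRNA features are kept;
#' records of any other type are skipped with a warning. The genome length
#' is taken from the `##sequence-region` pragma when present.
#'
#' @param path GFF3 file path.
#' @param genome_length Optional genome length in bp, required when the
#'   file carries no `##sequence-region` pragma.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, genome_length = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields")
    }
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e)) {
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    }
    if (e < s) stop("invalid GFF3 line ", i, ": end < start")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  # ##sequence-region <seqid> <start> <end> carries the genome length
  region_id <- NA_character_
  region <- grep("^##sequence-region", lines, value = TRUE)
  if (length(region) >= 1) {
    tok <- strsplit(trimws(region[1]), "[ \t]+")[[1]]
    if (length(tok) >= 4) {
      region_id <- tok[2]
      if (is.null(genome_length)) {
        genome_length <- suppressWarnings(as.integer(tok[4]))
      }
    }
  }
  if (is.null(genome_length) || is.na(genome_length)) {
    if (length(gr) > 0) {
      genome_length <- max(IRanges::end(gr))
    } else {
      stop("genome_length not given and no ##sequence-region pragma present")
    }
  }
  genome_id <- if (length(gr) > 0) {
    as.character(GenomicRanges::seqnames(gr)[1])
  } else if (!is.na(region_id)) {
    region_id
  } else {
    "genome"
  }
  if (length(gr) > 0 && length(unique(as.character(GenomicRanges::seqnames(gr)))) > 1) {
    stop("multi-chromosome annotation not supported (single replicon only)")
  }
  type <- as.character(gr$type)
  keep <- type %in% FEATURE_KINDS
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " feature(s) of unrecognized type: ",
            paste(unique(type[!keep]), collapse = ", "))
  }
  gr <- gr[keep]
  id <- if (length(gr) > 0 && !is.null(gr$ID)) as.character(gr$ID) else character(0)
  if (length(gr) > 0 && (length(id) == 0 || anyNA(id))) {
    stop("GFF3 features must carry unique ID attributes")
  }
  feats <- data.frame(
    id = id,
    kind = as.character(gr$type),
    start = IRanges::start(gr),
    end = IRanges::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
  genome_annotation(feats, genome_id = genome_id, genome_length = genome_length)
}

#' Write a genome annotation to GFF3
#'
#' Inverse of [read_annotation()]; emits a `##sequence-region` pragma so
#' the genome length round-trips.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  f <- annotation$features
  lines <- c(
    "##gff-version 3",
    paste("##sequence-region", annotation$genome_id, 1, annotation$genome_length)
  )
  if (nrow(f) > 0) {
    lines <- c(lines, sprintf(
      "%s\tripenrich\t%s\t%d\t%d\t.\t%s\t%s\tID=%s",
      annotation$genome_id, f$kind, f$start, f$end, f$strand,
      ifelse(f$kind == "CDS", "0", "."), f$id
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSS table
#'
#' Transcription start sites as a two-column TSV (`position`, `strand`),
#' 1-based coordinates.
#'
#' @param path TSV file path.
#' @param genome_length Optional; when given, positions are checked to lie
#'   in `[1, genome_length]`.
#' @return data.frame with integer `position` and character `strand`.
#' @export
read_tss <- function(path, genome_length = NULL) {
  tss <- utils::read.delim(path, colClasses = c("integer", "character"))
  if (!identical(names(tss), c("position", "strand"))) {
    stop("TSS table must have columns: position, strand")
  }
  if (!all(tss$strand %in% c("+", "-"))) stop("TSS strand must be '+' or '-'")
  if (!is.null(genome_length) &&
      any(tss$position < 1 | tss$position > genome_length)) {
    stop("TSS position outside [1, genome_length]")
  }
  tss
}

#' Write a TSS table
#' @param tss data.frame with columns `position`, `strand`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tss <- function(tss, path) {
  utils::write.table(tss[, c("position", "strand")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read mapped reads from SAM or BED
#'
#' Loads uniquely mapped read intervals into a [read_set()]. SAM records
#' with the unmapped flag, or with mapping quality 0 (multi-mapped under
#' common aligner conventions; the published analysis keeps only reads
#' "unambiguously matched" to the genome), are excluded. BED intervals
#' (0-based half-open) are converted to 1-based inclusive coordinates.
#' `total_mapped` is the number of retained reads.
#'
#' @param path Input file; dialect chosen by extension (`.sam`/`.bed`)
#'   unless `format` is given.
#' @param sample_label Sample name stored in the read set.
#' @param format Optional explicit dialect, `"sam"` or `"bed"`.
#' @return A [read_set()].
#' @export
read_reads <- function(path, sample_label, format = NULL) {
  if (!file.exists(path)) stop("read file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("sam", "bed")) {
      stop("unknown read-file extension '", ext,
           "'; pass format = \"sam\" or \"bed\"")
    }
    format <- ext
  }
  format <- match.arg(tolower(format), c("sam", "bed"))
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    aln <- GenomicAlignments::readGAlignments(
      bam,
      param = Rsamtools::ScanBamParam(what = "mapq")
    )
    mapq <- S4Vectors::mcols(aln)$mapq
    aln <- aln[is.na(mapq) | mapq > 0]  # MAPQ 0 = ambiguous placement
    chroms <- unique(as.character(GenomicRanges::seqnames(aln)))
    if (length(chroms) > 1) {
      stop("multi-chromosome input not supported (single replicon only)")
    }
    starts <- GenomicAlignments::start(aln)
    ends <- GenomicAlignments::end(aln)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
    if (length(chroms) > 1) {
      stop("multi-chromosome input not supported (single replicon only)")
    }
    starts <- IRanges::start(gr)
    ends <- IRanges::end(gr)
  }
  read_set(starts, ends, sample_label = sample_label)
}

#' Write mapped reads to SAM or BED
#'
#' Counterpart of [read_reads()], used mainly to export simulated read
#' sets. SAM output carries a minimal header (`@HD`, `@SQ`), flag 0, MAPQ
#' 60 and a fully aligned CIGAR; BED output is 0-based half-open.
#'
#' @param reads A [read_set()].
#' @param path Output file; dialect chosen by extension unless `format`
#'   is given.
#' @param genome_id Reference sequence name.
#' @param genome_length Reference length for the SAM `@SQ` line.
#' @param format Optional explicit dialect, `"sam"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, genome_id, genome_length, format = NULL) {
  stopifnot(inherits(reads, "read_set"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("sam", "bed")) {
      stop("unknown read-file extension '", ext,
           "'; pass format = \"sam\" or \"bed\"")
    }
    format <- ext
  }
  format <- match.arg(tolower(format), c("sam", "bed"))
  s <- IRanges::start(reads$ranges)
  e <- IRanges::end(reads$ranges)
  if (format == "sam") {
    header <- c(
      "@HD\tVN:1.6\tSO:coordinate",
      paste0("@SQ\tSN:", genome_id, "\tLN:", as.integer(genome_length))
    )
    ord <- order(s, e)
    rec <- sprintf("read%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                   seq_along(s), genome_id, s[ord], e[ord] - s[ord] + 1L)
    writeLines(c(header, rec), path)
  } else {
    writeLines(sprintf("%s\t%d\t%d", genome_id, s - 1L, e), path)
  }
  invisible(path)
}

PEAK_TABLE_COLS <- c("id", "start", "end", "length", "strand", "category",
                     "count_ip", "count_ctrl", "rpkm_ip", "rpkm_ctrl",
                     "rpkm_ratio")

#' Write a peak table to TSV
#'
#' Columns: id, start, end, length, strand, category, count_ip,
#' count_ctrl, rpkm_ip, rpkm_ctrl, rpkm_ratio. Coordinates are 1-based
#' inclusive (so `length == end - start + 1`, matching the printed peak
#' tables); the RPKM ratio is formatted to 3 significant figures.
#'
#' @param peaks Scored and classified peak data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  missing_cols <- setdiff(PEAK_TABLE_COLS, names(peaks))
  if (length(missing_cols) > 0) {
    stop("peak table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- peaks[, PEAK_TABLE_COLS]
  out$rpkm_ratio <- signif(out$rpkm_ratio, 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak table written by [write_peak_table()]
#' @param path TSV file path.
#' @return Peak data.frame.
#' @export
read_peak_table <- function(path) {
  utils::read.delim(path, colClasses = c(
    id = "character", start = "integer", end = "integer", length = "integer",
    strand = "character", category = "character",
    count_ip = "integer", count_ctrl = "integer",
    rpkm_ip = "numeric", rpkm_ctrl = "numeric", rpkm_ratio = "numeric"
  ))
}

#' Write a coverage track as bedGraph
#'
#' Collapses consecutive equal-depth positions into 0-based half-open
#' intervals; zero-depth intervals are omitted. The sum of
#' `interval length * depth` over the file equals the sum of the track.
#'
#' @param track A coverage track from [compute_coverage()].
#' @param path Output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts0 <- ends - r$lengths  # already 0-based
  keep <- r$values > 0
  writeLines(
    sprintf("%s\t%d\t%d\t%d", track$genome_id,
            starts0[keep], ends[keep], r$values[keep]),
    path
  )
  invisible(path)
}
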