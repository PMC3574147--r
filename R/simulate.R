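SYN_GENOME_ID <- "synthgenome"

# sample() treats a length-1 x as 1:x; this never does
rint <- function(lo, hi, n = 1) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

#' Generate a synthetic annotated genome with ground truth
#'
#' Places non-overlapping CDS, tRNA, rRNA and sRNA features on random
#' strands separated by random intergenic gaps, emits a TSS at the 5' end
#' of every CDS and sRNA (leader-designated CDSs instead get a TSS 150-400
#' bp upstream), and records a ground-truth table of transcribed regions:
#' housekeeping tRNA/rRNA regions (always fold 1), annotated sRNAs, 5'
#' leader intervals, and ORF-derived fragments cycling through the four
#' ORF subclasses. Fold enrichments from `config$enrichment_folds` are
#' cycled over the non-housekeeping regions in genomic order; each truth
#' region is labelled with the category the classifier should recover.
#'
#' CDS lengths are multiples of 3 between 150 and 450 bp; ORF fragment
#' lengths follow the size ranges reported for each subclass in real data
#' (start-codon fragments 54-178 nt, stop-codon 70-271 nt, internal
#' 52-425 nt, capped by the host CDS).
#'
#' @param config A [sim_config()].
#' @return list with elements `annotation` ([genome_annotation()]), `tss`
#'   (data.frame `position`, `strand`) and `truth` (data.frame
#'   `region_id`, `start`, `end`, `strand`, `fold`, `category`).
#' @export
#' @examples
#' g <- generate_annotation(sim_config(seed = 7))
#' table(g$truth$category)
generate_annotation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  plan <- data.frame(
    kind = c(rep("CDS", config$n_cds + config$n_leaders),
             rep("tRNA", config$n_trna),
             rep("rRNA", config$n_rrna),
             rep("sRNA", config$n_srna)),
    leader = c(rep(FALSE, config$n_cds), rep(TRUE, config$n_leaders),
               rep(FALSE, config$n_trna + config$n_rrna + config$n_srna))
  )
  n <- nrow(plan)
  empty_tss <- data.frame(position = integer(0), strand = character(0))
  empty_truth <- data.frame(
    region_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), fold = numeric(0), category = character(0)
  )
  if (n == 0) {
    return(list(
      annotation = genome_annotation(NULL, SYN_GENOME_ID, config$genome_length),
      tss = empty_tss, truth = empty_truth
    ))
  }
  plan <- plan[sample.int(n), , drop = FALSE]
  plan$strand <- sample(c("+", "-"), n, replace = TRUE)
  plan$length <- vapply(plan$kind, function(k) {
    switch(k,
      CDS = 3L * rint(50L, 150L),
      tRNA = 76L,
      rRNA = 1500L,
      sRNA = rint(50L, 300L)
    )
  }, integer(1))

  cursor <- 0L
  fstart <- fend <- integer(n)
  tss_pos <- rep(NA_integer_, n)
  truth_rows <- list()
  for (i in seq_len(n)) {
    gap <- rint(config$gap_min, config$gap_max)
    len <- plan$length[i]
    if (plan$leader[i]) {
      offset <- rint(150L, 400L)
      if (plan$strand[i] == "+") {
        tss_pos[i] <- cursor + gap
        fstart[i] <- tss_pos[i] + offset
        fend[i] <- fstart[i] + len - 1L
        cursor <- fend[i]
        leader_region <- c(tss_pos[i], fstart[i] - 1L)
      } else {
        fstart[i] <- cursor + gap
        fend[i] <- fstart[i] + len - 1L
        tss_pos[i] <- fend[i] + offset
        cursor <- tss_pos[i]
        leader_region <- c(fend[i] + 1L, tss_pos[i])
      }
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        start = leader_region[1], end = leader_region[2],
        strand = plan$strand[i], category = "leader"
      )
    } else {
      fstart[i] <- cursor + gap
      fend[i] <- fstart[i] + len - 1L
      cursor <- fend[i]
      if (plan$kind[i] %in% c("CDS", "sRNA")) {
        tss_pos[i] <- if (plan$strand[i] == "+") fstart[i] else fend[i]
      }
      if (plan$kind[i] %in% c("tRNA", "rRNA")) {
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          start = fstart[i], end = fend[i], strand = plan$strand[i],
          category = "trna_rrna"
        )
      } else if (plan$kind[i] == "sRNA") {
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          start = fstart[i], end = fend[i], strand = plan$strand[i],
          category = "srna"
        )
      }
    }
  }
  # pads and upstream leader TSSs never extend more than gap_min - 100 bp
  # past the last feature, but the genome must still hold everything
  if (cursor + 100L > config$genome_length) {
    stop("insufficient genome space for the requested features; ",
         "need > ", cursor + 100L, " bp, have ", config$genome_length)
  }

  # enriched ORF fragments on a subset of the ordinary CDSs
  regular_idx <- which(plan$kind == "CDS" & !plan$leader)
  if (config$n_orf_fragments > 0) {
    frag_idx <- sort(regular_idx[sample.int(length(regular_idx), config$n_orf_fragments)])
    subcat <- rep_len(c("orf_full", "orf_start", "orf_stop", "orf_internal"),
                      config$n_orf_fragments)
    for (j in seq_along(frag_idx)) {
      i <- frag_idx[j]
      fs <- fstart[i]; fe <- fend[i]; len <- plan$length[i]
      plus <- plan$strand[i] == "+"
      region <- switch(subcat[j],
        orf_full = c(fs - rint(20L, 60L), fe + rint(20L, 60L)),
        orf_start = {
          fl <- rint(54L, min(178L, len - 43L))
          if (plus) c(fs - 30L, fs - 30L + fl - 1L) else c(fe + 30L - fl + 1L, fe + 30L)
        },
        orf_stop = {
          fl <- rint(70L, min(271L, len - 43L))
          if (plus) c(fe + 30L - fl + 1L, fe + 30L) else c(fs - 30L, fs - 30L + fl - 1L)
        },
        orf_internal = {
          fl <- rint(52L, min(425L, len - 26L))
          rs <- rint(fs + 10L, fe - 9L - fl)
          c(rs, rs + fl - 1L)
        }
      )
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        start = region[1], end = region[2], strand = plan$strand[i],
        category = subcat[j]
      )
    }
  }

  feats <- data.frame(
    id = paste0(tolower(plan$kind), "_", sprintf("%03d", seq_len(n))),
    kind = plan$kind, start = as.integer(fstart), end = as.integer(fend),
    strand = plan$strand
  )
  ord <- order(feats$start)
  feats <- feats[ord, ]

  tss <- data.frame(position = tss_pos, strand = plan$strand)
  tss <- tss[!is.na(tss$position), ]
  tss <- tss[order(tss$position), ]
  rownames(tss) <- NULL

  truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else empty_truth
  if (nrow(truth) > 0) {
    truth <- truth[order(truth$start), ]
    truth$fold <- 1
    enriched <- truth$category != "trna_rrna"
    truth$fold[enriched] <- rep_len(config$enrichment_folds, sum(enriched))
    truth$region_id <- sprintf("region_%03d", seq_len(nrow(truth)))
    truth <- truth[, c("region_id", "start", "end", "strand", "fold", "category")]
    rownames(truth) <- NULL
  }

  list(
    annotation = genome_annotation(feats, SYN_GENOME_ID, config$genome_length),
    tss = tss, truth = truth
  )
}

#' Simulate matched IP and mock-control read sets
#'
#' For each ground-truth region the read count in each library is drawn
#' as `Poisson(rate * region_kb * library_size / 1e5)`, where the rate is
#' `housekeeping_rate` for tRNA/rRNA regions and `base_rate` otherwise,
#' and is multiplied by the region's fold in the IP sample only. Read
#' starts are uniform within the region; lengths are normal
#' (`read_length_mean`, `read_length_sd`) truncated at 20 bp and clipped
#' to the region, so reads never span region boundaries. A uniform
#' genome-wide noise floor (`background_rate`) is added to both samples.
#' Realized totals are recorded as `total_mapped`.
#'
#' @param annotation A [genome_annotation()] from [generate_annotation()].
#' @param truth Ground-truth region table from [generate_annotation()].
#' @param config The same [sim_config()].
#' @return list with [read_set()] elements `ip` and `ctrl`.
#' @export
simulate_reads <- function(annotation, truth, config = sim_config()) {
  stopifnot(inherits(annotation, "genome_annotation"))
  set.seed(config$seed + 1L)
  glen <- annotation$genome_length

  draw_region_reads <- function(n, rstart, rend) {
    if (n == 0) return(NULL)
    start <- rstart + as.integer(floor(runif(n) * (rend - rstart + 1L)))
    len <- pmax(20, round(rnorm(n, config$read_length_mean, config$read_length_sd)))
    end <- pmin(start + as.integer(len) - 1L, rend)
    cbind(start, end)
  }

  one_sample <- function(lib_size, use_fold) {
    lsf <- lib_size / 1e5
    chunks <- list()
    for (i in seq_len(nrow(truth))) {
      rate <- if (truth$category[i] == "trna_rrna") config$housekeeping_rate else config$base_rate
      mu <- rate * (truth$end[i] - truth$start[i] + 1) / 1000 * lsf
      if (use_fold) mu <- mu * truth$fold[i]
      n <- rpois(1, mu)
      chunks[[length(chunks) + 1]] <- draw_region_reads(n, truth$start[i], truth$end[i])
    }
    n_bg <- rpois(1, config$background_rate * glen / 1000 * lsf)
    if (n_bg > 0) {
      start <- as.integer(floor(runif(n_bg) * glen)) + 1L
      len <- pmax(20, round(rnorm(n_bg, config$read_length_mean, config$read_length_sd)))
      end <- pmin(start + as.integer(len) - 1L, glen)
      chunks[[length(chunks) + 1]] <- cbind(start, end)
    }
    do.call(rbind, chunks)
  }

  ip_mat <- one_sample(config$ip_library_size, use_fold = TRUE)
  ctrl_mat <- one_sample(config$ctrl_library_size, use_fold = FALSE)
  if (is.null(ip_mat)) ip_mat <- matrix(integer(0), ncol = 2)
  if (is.null(ctrl_mat)) ctrl_mat <- matrix(integer(0), ncol = 2)
  list(
    ip = read_set(ip_mat[, 1], ip_mat[, 2], "IP"),
    ctrl = read_set(ctrl_mat[, 1], ctrl_mat[, 2], "control")
  )
}

#' Generate a complete synthetic study
#'
#' Runs [generate_annotation()] and [simulate_reads()] and optionally
#' writes all external representations: GFF3 annotation, TSS TSV, a truth
#' BED (0-based half-open; name `region_id:category`, fold in the score
#' column) and SAM (or BED) read files for both samples.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param read_format `"sam"` or `"bed"` for the read files.
#' @return list with `annotation`, `tss`, `truth`, `ip`, `ctrl`, `config`
#'   and, when written, `files`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL,
                           read_format = c("sam", "bed")) {
  read_format <- match.arg(read_format)
  g <- generate_annotation(config)
  reads <- simulate_reads(g$annotation, g$truth, config)
  res <- list(annotation = g$annotation, tss = g$tss, truth = g$truth,
              ip = reads$ip, ctrl = reads$ctrl, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      annotation = file.path(out_dir, "annotation.gff3"),
      tss = file.path(out_dir, "tss.tsv"),
      truth = file.path(out_dir, "truth.bed"),
      ip = file.path(out_dir, paste0("ip.", read_format)),
      ctrl = file.path(out_dir, paste0("ctrl.", read_format))
    )
    write_annotation(g$annotation, files$annotation)
    write_tss(g$tss, files$tss)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s", SYN_GENOME_ID,
                       g$truth$start - 1L, g$truth$end,
                       paste0(g$truth$region_id, ":", g$truth$category),
                       g$truth$fold, g$truth$strand),
               files$truth)
    write_reads(reads$ip, files$ip, SYN_GENOME_ID, config$genome_length)
    write_reads(reads$ctrl, files$ctrl, SYN_GENOME_ID, config$genome_length)
    res$files <- files
  }
  res
}
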