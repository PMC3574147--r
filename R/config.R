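#' Pipeline configuration
#'
#' Thresholds and windows used by peak calling, enrichment scoring and
#' classification. Defaults reproduce the published analysis settings: a
#' peak is at least `min_depth` reads over at least `min_run` consecutive
#' positions, and a peak is called enriched when its IP/control RPKM ratio
#' is at least `ratio_threshold`.
#'
#' @param min_depth Minimum per-position read depth inside a peak (reads;
#'   inclusive, so depth equal to `min_depth` qualifies). Default 5.
#' @param min_run Minimum number of consecutive qualifying positions (bp).
#'   Default 50.
#' @param ratio_threshold RPKM-ratio cutoff separating enriched peaks from
#'   background (dimensionless, inclusive). Default 2.
#' @param control_pseudocount Read count substituted for the control count
#'   when it is below this value, so that ratios stay finite. Default 1.
#' @param leader_max_length Maximum distance (bp) from a TSS to its
#'   downstream CDS start for the intervening region to count as a 5'
#'   leader. Default 500 (leaders are typically 150-400 nt).
#' @param tss_window Distance (bp) upstream of a peak within which a TSS
#'   oriented into the peak assigns it a strand. Default 500.
#'
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' pipeline_config(min_depth = 10)
pipeline_config <- function(min_depth = 5,
                            min_run = 50,
                            ratio_threshold = 2,
                            control_pseudocount = 1,
                            leader_max_length = 500,
                            tss_window = 500) {
  cfg <- list(
    min_depth = as.numeric(min_depth),
    min_run = as.numeric(min_run),
    ratio_threshold = as.numeric(ratio_threshold),
    control_pseudocount = as.numeric(control_pseudocount),
    leader_max_length = as.numeric(leader_max_length),
    tss_window = as.numeric(tss_window)
  )
  bad <- names(cfg)[vapply(cfg, function(x) !is.finite(x) || x <= 0, logical(1))]
  if (length(bad) > 0) {
    stop("pipeline_config values must be positive: ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Synthetic-study configuration
#'
#' Parameters of the synthetic genome and read simulator. Defaults emulate
#' the study conditions at 1/100 library scale: ~35 nt unstranded
#' single-end reads, unequal library sizes (100,000 IP vs 15,000 control
#' mirroring ~10M vs ~1.5M uniquely mapped reads), abundant non-enriched
#' housekeeping RNAs (tRNA/rRNA), and enriched regions whose IP read rate
#' is multiplied by a per-region fold.
#'
#' Expected read counts follow the generative model
#' `count ~ Poisson(rate * region_kb * library_size / 1e5)`, with the rate
#' multiplied by the region's fold in the IP sample only. `base_rate` is
#' the per-kb rate of ordinary transcribed regions, `housekeeping_rate`
#' that of tRNA/rRNA; `background_rate` adds a uniform genome-wide noise
#' floor to both libraries (default equivalent to 1% of the default IP
#' library scale). The default 200:1 housekeeping excess mirrors real
#' total-RNA libraries, where rRNA and tRNA dominate both the IP and the
#' mock pull-down; because RPKM divides by the realized mapped total,
#' this dominance is what keeps enrichment of the remaining regions from
#' deflating every ratio. Realized totals are Poisson outcomes that scale
#' with the library sizes but exceed them when housekeeping RNAs are
#' abundant; the IP:control total ratio stays at the configured ~6.7:1
#' asymmetry up to the extra reads drawn into fold-enriched regions.
#'
#' @param genome_length Genome size in bp.
#' @param n_cds,n_trna,n_rrna,n_srna Feature counts for ordinary CDSs,
#'   tRNAs, rRNAs and annotated sRNAs.
#' @param n_leaders Number of additional CDSs given a TSS 150-400 bp
#'   upstream; the TSS-to-CDS interval is an enriched "leader" truth region.
#' @param n_orf_fragments Number of ordinary CDSs carrying one enriched
#'   ORF-derived truth region, cycling through the four ORF subclasses
#'   (full, start-codon, stop-codon, internal).
#' @param read_length_mean,read_length_sd Read length distribution in bp
#'   (normal, truncated at 20, clipped to the transcribed region).
#' @param ip_library_size,ctrl_library_size Library scale factors in reads;
#'   realized totals are Poisson outcomes around these scales.
#' @param background_rate Expected background reads per kb per unit library.
#' @param base_rate,housekeeping_rate Expected reads per kb per unit
#'   library for ordinary transcribed regions and tRNA/rRNA respectively.
#' @param enrichment_folds Fold enrichments cycled over the enriched truth
#'   regions in genomic order (all > 0; housekeeping regions always fold 1).
#' @param gap_min,gap_max Intergenic gap range in bp (>= 100).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' sim_config(seed = 42, enrichment_folds = 1)  # null (no enrichment)
sim_config <- function(genome_length = 200000,
                       n_cds = 20,
                       n_trna = 6,
                       n_rrna = 2,
                       n_srna = 6,
                       n_leaders = 6,
                       n_orf_fragments = 8,
                       read_length_mean = 35,
                       read_length_sd = 5,
                       ip_library_size = 100000,
                       ctrl_library_size = 15000,
                       background_rate = 5,
                       base_rate = 1500,
                       housekeeping_rate = 300000,
                       enrichment_folds = c(5, 20, 100),
                       gap_min = 200,
                       gap_max = 800,
                       seed = 1) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_cds = as.integer(n_cds), n_trna = as.integer(n_trna),
    n_rrna = as.integer(n_rrna), n_srna = as.integer(n_srna),
    n_leaders = as.integer(n_leaders),
    n_orf_fragments = as.integer(n_orf_fragments),
    read_length_mean = as.numeric(read_length_mean),
    read_length_sd = as.numeric(read_length_sd),
    ip_library_size = as.numeric(ip_library_size),
    ctrl_library_size = as.numeric(ctrl_library_size),
    background_rate = as.numeric(background_rate),
    base_rate = as.numeric(base_rate),
    housekeeping_rate = as.numeric(housekeeping_rate),
    enrichment_folds = as.numeric(enrichment_folds),
    gap_min = as.integer(gap_min), gap_max = as.integer(gap_max),
    seed = as.integer(seed)
  )
  counts <- c("n_cds", "n_trna", "n_rrna", "n_srna", "n_leaders", "n_orf_fragments")
  if (any(vapply(cfg[counts], function(x) x < 0, logical(1)))) {
    stop("feature counts must be >= 0")
  }
  if (cfg$ip_library_size <= 0 || cfg$ctrl_library_size <= 0) {
    stop("library sizes must be > 0")
  }
  if (any(cfg$enrichment_folds <= 0)) stop("enrichment folds must be > 0")
  if (cfg$n_orf_fragments > cfg$n_cds) {
    stop("n_orf_fragments cannot exceed n_cds")
  }
  if (cfg$gap_min < 100 || cfg$gap_max < cfg$gap_min) {
    stop("gaps must satisfy 100 <= gap_min <= gap_max")
  }
  structure(cfg, class = "sim_config")
}
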