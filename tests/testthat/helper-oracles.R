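# Independent brute-force oracles, kept deliberately naive so they share
# no code path with the implementation they check.

# depth at every position by direct containment counting
brute_coverage <- function(starts, ends, genome_length) {
  vapply(seq_len(genome_length),
         function(p) sum(starts <= p & p <= ends),
         numeric(1))
}

# maximal runs of depth >= min_depth, scanned position by position
brute_peaks <- function(depth, min_depth, min_run) {
  runs <- list()
  run_start <- NA
  for (p in seq_along(depth)) {
    if (depth[p] >= min_depth) {
      if (is.na(run_start)) run_start <- p
    } else if (!is.na(run_start)) {
      runs[[length(runs) + 1]] <- c(run_start, p - 1)
      run_start <- NA
    }
  }
  if (!is.na(run_start)) runs[[length(runs) + 1]] <- c(run_start, length(depth))
  runs <- Filter(function(r) r[2] - r[1] + 1 >= min_run, runs)
  if (length(runs) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], end = m[, 2])
}

# any-overlap read counting by exhaustive enumeration
brute_count <- function(starts, ends, peak_start, peak_end) {
  sum(starts <= peak_end & ends >= peak_start)
}

# small synthetic study used by several files; trimmed genome for speed
small_config <- function(seed = 101, ...) {
  args <- list(genome_length = 60000, n_cds = 6, n_trna = 2, n_rrna = 1,
               n_srna = 2, n_leaders = 2, n_orf_fragments = 4, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# random read set over a short genome
random_read_set <- function(n, genome_length, label = "IP", read_len = 35) {
  starts <- sample.int(genome_length - read_len + 1, n, replace = TRUE)
  read_set(starts, starts + read_len - 1, label)
}
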