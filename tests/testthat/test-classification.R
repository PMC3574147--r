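# a hand-built genome exercising every classification rule
fixture_annotation <- function() {
  genome_annotation(
    data.frame(
      id = c("trnaA", "FsrA", "cdsP", "cdsM", "cdsL"),
      kind = c("tRNA", "sRNA", "CDS", "CDS", "CDS"),
      start = c(500L, 1483560L, 5000L, 9000L, 20000L),
      end = c(575L, 1483632L, 5299L, 9299L, 20299L),
      strand = c("+", "+", "+", "-", "+")
    ),
    genome_id = "toy", genome_length = 2000000
  )
}

fixture_tss <- function() {
  data.frame(
    position = c(5000L, 9299L, 19700L),  # cdsP 5', cdsM 5', cdsL leader TSS
    strand = c("+", "-", "+")
  )
}

test_that("strand inference follows the oriented TSS window rule", {
  cfg <- pipeline_config()
  tss <- data.frame(position = c(900L, 5000L), strand = c("+", "-"))
  # + TSS 100 bp upstream, no - TSS nearby
  expect_equal(infer_strand(list(start = 1000, end = 1200), tss["1", ], cfg), "+")
  # no TSS within the window on either side
  expect_equal(infer_strand(list(start = 3000, end = 3200), tss, cfg), "ambiguous")
  # support from both strands
  expect_equal(infer_strand(list(start = 1000, end = 4600), tss, cfg), "ambiguous")
  # - TSS downstream of the peak, oriented into it
  expect_equal(infer_strand(list(start = 4400, end = 4700), tss["2", ], cfg), "-")
  # a + TSS strictly downstream of the peak end gives no support
  expect_equal(infer_strand(list(start = 700, end = 850), tss["1", ], cfg),
               "ambiguous")
})

test_that("classification priority: housekeeping, then sRNA, then leader", {
  ann <- fixture_annotation()
  tss <- fixture_tss()
  cfg <- pipeline_config()
  # overlapping a tRNA wins over everything
  expect_equal(classify_peak(list(start = 560, end = 700), ann, "+", tss, cfg),
               "trna_rrna")
  # the annotated sRNA FsrA
  expect_equal(classify_peak(list(start = 1483560, end = 1483632), ann, "+",
                             tss, cfg), "srna")
  # inside [TSS, CDS start - 1] on the matching strand -> leader
  expect_equal(classify_peak(list(start = 19750, end = 19950), ann, "+",
                             tss, cfg), "leader")
  # same interval without strand support is not a leader
  expect_equal(classify_peak(list(start = 19750, end = 19950), ann,
                             "ambiguous", tss, cfg), "unknown")
  # a TSS too far from its CDS start does not create a leader
  far <- pipeline_config(leader_max_length = 200)
  expect_equal(classify_peak(list(start = 19750, end = 19950), ann, "+",
                             tss, far), "unknown")
})

test_that("ORF subclasses follow codon overlap in strand orientation", {
  ann <- fixture_annotation()
  tss <- fixture_tss()
  cfg <- pipeline_config()
  # contains the whole CDS
  expect_equal(classify_peak(list(start = 4950, end = 5350), ann, "+", tss, cfg),
               "orf_full")
  # overlaps only the first codon of the + strand CDS
  expect_equal(classify_peak(list(start = 4980, end = 5002), ann, "+", tss, cfg),
               "orf_start")
  # overlaps only the stop codon
  expect_equal(classify_peak(list(start = 5290, end = 5340), ann, "+", tss, cfg),
               "orf_stop")
  # strictly internal, touching neither codon
  expect_equal(classify_peak(list(start = 5050, end = 5250), ann, "+", tss, cfg),
               "orf_internal")
  # on the minus strand the start codon sits at the right-hand CDS edge
  expect_equal(classify_peak(list(start = 9280, end = 9350), ann, "-", tss, cfg),
               "orf_start")
  expect_equal(classify_peak(list(start = 8950, end = 9010), ann, "-", tss, cfg),
               "orf_stop")
  # ambiguous strand can still receive a positional ORF category
  expect_equal(classify_peak(list(start = 5050, end = 5250), ann, "ambiguous",
                             tss, cfg), "orf_internal")
  # touching both codons without containing the CDS stays unknown
  expect_equal(classify_peak(list(start = 5001, end = 5298), ann, "+", tss, cfg),
               "unknown")
  # intergenic peak with no support
  expect_equal(classify_peak(list(start = 40000, end = 40200), ann, "+", tss, cfg),
               "unknown")
})

test_that("strand recovery on synthetic genomes reaches 90%", {
  hits <- 0L; total <- 0L
  for (sd in 1:3) {
    st <- simulate_study(small_config(seed = 400 + sd))
    cfg <- pipeline_config()
    truth <- st$truth[st$truth$category != "trna_rrna", ]  # regions with a TSS
    for (i in seq_len(nrow(truth))) {
      got <- infer_strand(list(start = truth$start[i], end = truth$end[i]),
                          st$tss, cfg)
      total <- total + 1L
      if (got == truth$strand[i]) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("category summaries conserve counts and match a sort-based median", {
  set.seed(71)
  n <- 40
  pk <- data.frame(
    id = sprintf("p%02d", 1:n), start = 1:n * 100L, end = 1:n * 100L + 59L,
    length = 60L, strand = "+",
    category = sample(c("srna", "leader", "orf_internal"), n, replace = TRUE),
    count_ip = 10L, count_ctrl = 2L, rpkm_ip = 1, rpkm_ctrl = 1,
    rpkm_ratio = round(rexp(n, 1 / 4), 3)
  )
  summ <- summarize_categories(pk, pipeline_config())
  expect_equal(sum(summ$by_category$count), n)
  expect_equal(sum(summ$by_category$proportion), 1)
  for (i in seq_len(nrow(summ$by_category))) {
    cc <- summ$by_category$category[i]
    v <- sort(pk$rpkm_ratio[pk$category == cc])
    m <- if (length(v) %% 2 == 1) v[(length(v) + 1) / 2] else
      mean(v[length(v) / 2 + 0:1])
    expect_equal(summ$by_category$median_rpkm_ratio[i], m)
  }
  expect_equal(sum(summ$overall$count), n)

  # single category -> proportion 1; empty input -> empty summary
  one <- summarize_categories(pk[pk$category == "srna", ], pipeline_config())
  expect_equal(one$by_category$proportion, 1)
  empty <- summarize_categories(pk[0, ], pipeline_config())
  expect_equal(nrow(empty$by_category), 0L)
})
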