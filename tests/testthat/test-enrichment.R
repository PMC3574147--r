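test_that("read-in-peak counting uses the any-overlap rule", {
  rs <- read_set(c(100, 200, 300), c(134, 234, 334), "IP")
  expect_equal(count_reads_in_peak(rs, list(start = 500, end = 600)), 0L)
  expect_equal(count_reads_in_peak(rs, list(start = 100, end = 134)), 1L)
  expect_equal(count_reads_in_peak(rs, list(start = 134, end = 200)), 2L)  # 1 bp suffices

  set.seed(6)
  starts <- sample.int(10000, 5000, replace = TRUE)
  ends <- starts + sample(20:50, 5000, replace = TRUE)
  rs <- read_set(starts, ends, "IP")
  for (rep in 1:10) {
    ps <- sample.int(9000, 1)
    pe <- ps + sample(50:400, 1)
    expect_equal(count_reads_in_peak(rs, list(start = ps, end = pe)),
                 brute_count(starts, ends, ps, pe))
  }
})

test_that("rpkm implements reads per kb per million mapped", {
  expect_identical(rpkm(10, 1000, 1e6), 10)
  expect_identical(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(5, 50, 1.5e6), 5 * 1e9 / (50 * 1.5e6))
  expect_error(rpkm(5, 0, 1e6), "length")
  expect_error(rpkm(5, 50, 0), "total_mapped")
})

test_that("peak scoring fills counts, RPKMs and a finite ratio", {
  ip <- read_set(c(100, 110, 120, 500), c(150, 160, 170, 540), "IP",
                 total_mapped = 10)
  ctrl <- read_set(c(105, 600), c(140, 640), "control", total_mapped = 10)
  pk <- data.frame(id = "p1", start = 100L, end = 180L, length = 81L)
  sc <- score_peaks(pk, ip, ctrl)
  expect_equal(sc$count_ip, 3L)
  expect_equal(sc$count_ctrl, 1L)
  expect_equal(sc$rpkm_ip, 3 * 1e9 / (81 * 10))
  expect_equal(sc$rpkm_ratio, 3)  # identical totals -> count ratio

  # zero control reads fall back to the pseudocount and stay finite
  pk2 <- data.frame(id = "p2", start = 490L, end = 560L, length = 71L)
  sc2 <- score_peaks(pk2, ip, ctrl)
  expect_equal(sc2$count_ctrl, 0L)
  expect_equal(sc2$rpkm_ratio, sc2$rpkm_ip / rpkm(1, 71, 10))
  expect_true(is.finite(sc2$rpkm_ratio))
})

test_that("scoring matches the hand-computed formula on random inputs", {
  set.seed(33)
  ip <- random_read_set(2000, 20000, "IP")
  ctrl <- random_read_set(400, 20000, "control")
  starts <- sample.int(19000, 20)
  pk <- data.frame(id = sprintf("p%d", 1:20), start = starts,
                   end = starts + sample(50:300, 20, replace = TRUE))
  pk$length <- pk$end - pk$start + 1
  sc <- score_peaks(pk, ip, ctrl)
  for (i in seq_len(nrow(sc))) {
    ci <- brute_count(IRanges::start(ip$ranges), IRanges::end(ip$ranges),
                      pk$start[i], pk$end[i])
    cc <- brute_count(IRanges::start(ctrl$ranges), IRanges::end(ctrl$ranges),
                      pk$start[i], pk$end[i])
    expect_equal(sc$count_ip[i], ci)
    want <- (ci * 1e9 / (pk$length[i] * 2000)) /
      (max(cc, 1) * 1e9 / (pk$length[i] * 400))
    expect_equal(sc$rpkm_ratio[i], want)
  }
})

test_that("RPKM and the ratio are invariant to duplicating a library", {
  set.seed(44)
  ip <- random_read_set(1000, 10000, "IP")
  ctrl <- random_read_set(200, 10000, "control")
  dup <- read_set(rep(IRanges::start(ip$ranges), 2),
                  rep(IRanges::end(ip$ranges), 2), "IP")
  pk <- data.frame(id = "p", start = 2000L, end = 2400L, length = 401L)
  a <- score_peaks(pk, ip, ctrl)
  b <- score_peaks(pk, dup, ctrl)
  expect_equal(b$count_ip, 2L * a$count_ip)
  expect_equal(b$rpkm_ip, a$rpkm_ip)
  expect_equal(b$rpkm_ratio, a$rpkm_ratio)
})

test_that("adding IP reads inside a peak never decreases its ratio", {
  set.seed(55)
  ip <- random_read_set(500, 10000, "IP")
  ctrl <- random_read_set(100, 10000, "control")
  pk <- data.frame(id = "p", start = 3000L, end = 3300L, length = 301L)
  base <- score_peaks(pk, ip, ctrl)$rpkm_ratio
  more <- read_set(c(IRanges::start(ip$ranges), rep(3100L, 50)),
                   c(IRanges::end(ip$ranges), rep(3134L, 50)), "IP")
  # note: total_mapped grows too, so this checks the net effect
  expect_gte(score_peaks(pk, more, ctrl)$rpkm_ratio, base)
})

test_that("the enrichment cutoff is inclusive and the partition exhaustive", {
  pk <- data.frame(id = c("a", "b", "c"), start = c(1, 100, 200),
                   end = c(60, 160, 260), length = rep(61, 3),
                   rpkm_ratio = c(53.6, 2.0, 1.2))
  parts <- filter_enriched(pk, pipeline_config())
  expect_equal(parts$enriched$id, c("a", "b"))   # 53.6 enriched; 2.0 boundary in
  expect_equal(parts$background$id, "c")
  expect_equal(nrow(parts$enriched) + nrow(parts$background), nrow(pk))

  none <- filter_enriched(pk[pk$rpkm_ratio < 2, ], pipeline_config())
  expect_equal(nrow(none$enriched), 0L)
})

test_that("median called-peak ratio increases with simulated fold", {
  st <- simulate_study(small_config(seed = 303, enrichment_folds = c(1, 10, 100)))
  pk <- data.frame(id = st$truth$region_id, start = st$truth$start,
                   end = st$truth$end,
                   length = st$truth$end - st$truth$start + 1)
  sc <- score_peaks(pk, st$ip, st$ctrl)
  sc$fold <- st$truth$fold
  sc <- sc[st$truth$category != "trna_rrna", ]
  med <- tapply(sc$rpkm_ratio, sc$fold, median)
  expect_true(all(diff(med[order(as.numeric(names(med)))]) > 0))
})
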