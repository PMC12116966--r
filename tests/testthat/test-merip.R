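test_that("window RPKM follows the depth/library scaling", {
  track <- rep(1, 500)
  expect_equal(window_rpkm(track, 0, 100, 1e6), 1000)
  expect_equal(window_rpkm(track, 200, 500, 1e6), 1000)
  expect_equal(window_rpkm(rep(0, 100), 0, 50, 1e6), 0)
  # doubling the library total halves the rpkm
  expect_equal(window_rpkm(track, 0, 100, 2e6),
               window_rpkm(track, 0, 100, 1e6) / 2)
  expect_error(window_rpkm(track, 10, 10, 1e6), "zero-length")
  expect_error(window_rpkm(track, 0, 100, 0), "library_total")
})

test_that("window grid enumerates full and terminal truncated windows", {
  pair <- coverage_pair("tx1", rep(1, 230), rep(1, 230))
  w <- window_enrichment(pair, window_nt = 100, step_nt = 50)
  expect_equal(w$start, c(0, 50, 100, 150))
  expect_equal(w$end, c(100, 150, 200, 230))  # [200,230) dropped: 30 < 50
  expect_warning(window_enrichment(coverage_pair("t", rep(1, 30), rep(1, 30)),
                                   window_nt = 100, step_nt = 50),
                 "shorter than step_nt")
})

test_that("pseudocounted fold reproduces hand arithmetic and the null case", {
  # ip_rpkm 42, input_rpkm 10: depth 42 and 10 with library totals 1e9
  pair <- coverage_pair("tx1", rep(42, 100), rep(10, 100),
                        ip_total = 1e9, input_total = 1e9)
  w <- window_enrichment(pair, window_nt = 100, step_nt = 50,
                         pseudo_rpkm = 0.5)
  expect_equal(w$fold[1], 42.5 / 10.5, tolerance = 1e-12)
  expect_true(all(w$enriched))  # 4.0476 >= 4
  # identical IP and input with equal totals: fold exactly 1, nothing called
  set.seed(42)
  depth <- rpois(600, 20)
  pair2 <- coverage_pair("tx1", depth, depth)
  w2 <- window_enrichment(pair2)
  expect_true(all(abs(w2$fold - 1) < 1e-12))
  expect_equal(nrow(call_peaks(w2)), 0)
})

test_that("low-coverage windows are gated regardless of fold", {
  ip <- c(rep(4, 100), rep(0, 100))
  input <- rep(0, 200)
  pair <- coverage_pair("tx1", ip, input, ip_total = 1e6, input_total = 1e6)
  w <- window_enrichment(pair, min_window_reads = 1000)
  expect_true(all(!w$gate_pass[1:2] | w$fold[1:2] < 4 | FALSE) ||
                all(!w$enriched))
  expect_true(all(!w$enriched))
  # same data with a permissive gate is enriched
  w2 <- window_enrichment(pair, min_window_reads = 10)
  expect_true(any(w2$enriched))
})

test_that("threshold is inclusive at exactly min_fold", {
  wins <- data.frame(transcript = "tx1", start = c(0, 200), end = c(100, 300),
                     ip_rpkm = 0, input_rpkm = 0,
                     fold = c(4, 4 - 1e-9), gate_pass = TRUE,
                     enriched = NA)
  pk <- call_peaks(wins, min_fold = 4)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 0)
  expect_equal(pk$end, 100)
})

test_that("adjacent enriched windows merge; gaps split; merging is idempotent", {
  mk <- function(start, end, fold)
    data.frame(transcript = "tx1", start = start, end = end, ip_rpkm = 0,
               input_rpkm = 0, fold = fold, gate_pass = TRUE, enriched = NA)
  # overlapping windows -> one peak over the union
  pk <- call_peaks(mk(c(0, 50), c(100, 150), c(5, 6)))
  expect_equal(pk[, c("start", "end", "score", "n_windows")],
               data.frame(start = 0, end = 150, score = 6, n_windows = 2L))
  # book-ended windows merge too (gap <= 0)
  pk2 <- call_peaks(mk(c(0, 100), c(100, 200), c(4, 4)))
  expect_equal(nrow(pk2), 1)
  # positive gap separates peaks
  pk3 <- call_peaks(mk(c(0, 200), c(100, 300), c(5, 5)))
  expect_equal(nrow(pk3), 2)
  # no enriched windows -> empty
  expect_equal(nrow(call_peaks(mk(0, 100, 2))), 0)
  # unsorted input is an error
  expect_error(call_peaks(mk(c(100, 0), c(200, 100), c(5, 5))), "unsorted")
  # idempotence: re-calling on the member windows of merged peaks
  again <- call_peaks(mk(c(0, 50), c(100, 150), c(5, 6)))
  expect_identical(pk, again)
})

test_that("caller matches the brute-force enumerator on short transcripts", {
  set.seed(101)
  for (rep in 1:15) {
    len <- sample(80:500, 1)
    n_peaks <- sample(0:2, 1)
    planted <- NULL
    if (n_peaks > 0 && len >= 250) {
      s <- sample(0:(len - 120), n_peaks)
      planted <- data.frame(transcript = "tx1", start = s,
                            end = pmin(s + sample(c(60, 100), n_peaks,
                                                  replace = TRUE), len),
                            enrichment = sample(c(4, 6, 10), n_peaks,
                                                replace = TRUE))
      planted <- planted[!duplicated(planted$start), ]
      o <- order(planted$start)
      planted <- planted[o, ]
      keep <- c(TRUE, planted$start[-1] >= head(planted$end, -1))
      planted <- planted[keep, ]
    }
    sim <- simulate_merip_coverage(c(tx1 = len), planted,
                                   background_depth = 25, seed = rep)
    pair <- sim$pairs$tx1
    mine <- call_peaks(suppressWarnings(window_enrichment(pair)))
    oracle <- oracle_call_peaks(pair)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(mine)) {
      expect_equal(mine$start, oracle$start)
      expect_equal(mine$end, oracle$end)
      expect_equal(mine$score, oracle$score, tolerance = 1e-12)
      expect_equal(mine$n_windows, oracle$n_windows)
    }
  }
})

test_that("peak-coverage summaries use union semantics", {
  pair <- coverage_pair("tx1", c(rep(50, 100), rep(10, 100)), rep(10, 200),
                        ip_total = 1e6, input_total = 1e6)
  none <- transcript_peak_coverage(NULL, pair)
  expect_equal(unlist(none[, -1]),
               c(n_peaks = 0, peak_nt = 0, mean_ip_rpkm = 0, mean_fold = 0))
  one <- transcript_peak_coverage(
    data.frame(transcript = "tx1", start = 0L, end = 100L, score = 5), pair)
  split <- transcript_peak_coverage(
    data.frame(transcript = "tx1", start = c(0L, 40L), end = c(40L, 100L),
               score = c(5, 5)), pair)
  expect_equal(one$n_peaks, 1)
  expect_equal(split$n_peaks, 1)  # adjacent pieces cover the same union
  expect_equal(one[, -1], split[, -1])
  expect_error(transcript_peak_coverage(
    data.frame(transcript = "other", start = 0L, end = 10L, score = 1), pair),
    "foreign")
})

test_that("uniform five-fold enrichment over half a transcript reports ~5x", {
  set.seed(202)
  lens <- c(tx1 = 2000L)
  planted <- data.frame(transcript = "tx1", start = 0, end = 1000,
                        enrichment = 5)
  sim <- simulate_merip_coverage(lens, planted, background_depth = 100,
                                 seed = 8)
  pair <- sim$pairs$tx1
  # score against matched library totals so composition does not dilute fold
  pair$ip_total <- sum(pair$input)
  pair$input_total <- sum(pair$input)
  summ <- transcript_peak_coverage(
    data.frame(transcript = "tx1", start = 0L, end = 1000L, score = 5), pair)
  expect_equal(summ$mean_fold, 5, tolerance = 0.1)
})
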