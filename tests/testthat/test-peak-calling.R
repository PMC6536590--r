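test_that("rolling mean reproduces closed-form cases", {
  const <- coverage_track("c", rep(20, 500))
  sm <- rolling_mean(const)
  expect_true(all(sm$values == 20))
  expect_equal(diff(sm$positions), rep(10L, length(sm$positions) - 1L))

  spike <- rep(0, 500)
  spike[200] <- 50
  sm2 <- rolling_mean(coverage_track("c", spike))
  covering <- sm2$positions - 25L <= 199L & sm2$positions - 25L + 50L > 199L
  expect_true(all(sm2$values[covering] == 1.0))
  expect_true(all(sm2$values[!covering][
    sm2$positions[!covering] + 25L <= 500L] == 0))

  expect_error(rolling_mean(coverage_track("c", rep(1, 10))),
               "shorter than smoothing window")
})

test_that("rolling mean equals the loop-based oracle exactly", {
  set.seed(1)
  values <- rpois(10000, 20)
  sm <- rolling_mean(coverage_track("c", values))
  oracle <- oracle_rolling_mean(values, 50L, 10L)
  expect_identical(sm$positions, oracle$positions)
  expect_identical(sm$values, oracle$values)
})

test_that("genome mean is length-weighted over contigs", {
  expect_equal(genome_mean(coverage_track("a", c(1, 2, 3))), 2)
  two <- list(coverage_track("a", rep(4, 10)),
              coverage_track("b", rep(8, 30)))
  expect_equal(genome_mean(two), 7)
  zero <- coverage_track("a", rep(0, 100))
  expect_equal(genome_mean(zero), 0)
  sm <- rolling_mean(coverage_track("a", rep(0, 100)))
  expect_error(call_peaks(sm, genome_mean(zero)), "must be positive")
})

test_that("peak calling matches a brute-force segmentation oracle", {
  # flat background with one rectangular enriched region
  values <- rep(20, 50000)
  values[10001:10200] <- 200
  tr <- coverage_track("c", values)
  sm <- rolling_mean(tr)
  gm <- genome_mean(tr)
  peaks <- call_peaks(sm, gm, contig_length = 50000L)
  expect_equal(nrow(peaks), 1L)
  oracle <- oracle_call_peaks(sm$positions, sm$values, gm, 50L, 10L,
                              contig_length = 50000L)
  expect_equal(peaks$start, oracle$start)
  expect_equal(peaks$end, oracle$end)
  expect_equal(peaks$summit, oracle$summit)
  expect_equal(peaks$max_smoothed, oracle$max_smoothed)
  # summit sits inside the enriched rectangle
  expect_true(peaks$summit >= 10000L && peaks$summit < 10200L)
})

test_that("constant coverage yields no peaks", {
  tr <- coverage_track("c", rep(20, 5000))
  peaks <- call_peaks(rolling_mean(tr), genome_mean(tr),
                      contig_length = 5000L)
  expect_equal(nrow(peaks), 0L)
})

test_that("raising the fold threshold never adds peaks or span", {
  set.seed(7)
  values <- rpois(30000, 20)
  for (s in c(5000, 12000, 21000)) {
    values[s:(s + 150)] <- values[s:(s + 150)] + rpois(151, 120)
  }
  tr <- coverage_track("c", values)
  sm <- rolling_mean(tr)
  gm <- genome_mean(tr)
  p3 <- call_peaks(sm, gm, peak_call_params(fold_threshold = 3),
                   contig_length = 30000L)
  p5 <- call_peaks(sm, gm, peak_call_params(fold_threshold = 5),
                   contig_length = 30000L)
  expect_lte(nrow(p5), nrow(p3))
  expect_lte(sum(p5$end - p5$start), sum(p3$end - p3$start))
  expect_true(all(p3$fold_over_mean > 3))
  expect_true(all(p5$fold_over_mean > 5))
})

test_that("summit windows are 100 bp, clipped on linear contigs and wrapped on circular", {
  seqc <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  lin <- list(chr = contig("chr", seqc))
  circ <- list(chr = contig("chr", seqc, circular = TRUE))

  mid <- peaks_at(500L)
  w <- extract_peak_windows(mid, lin)
  expect_equal(w$window_start, 450L)
  expect_equal(w$window_end, 550L)
  expect_equal(nchar(w$window_seq), 100L)
  expect_false(w$truncated)
  expect_equal(w$window_seq, substr(seqc, 451, 550))

  edge <- peaks_at(30L)
  wl <- extract_peak_windows(edge, lin)
  expect_equal(wl$window_start, 0L)
  expect_equal(wl$window_end, 80L)
  expect_true(wl$truncated)

  near0 <- peaks_at(10L)
  wc <- extract_peak_windows(near0, circ)
  expect_equal(nchar(wc$window_seq), 100L)
  expect_false(wc$truncated)
  expect_equal(wc$window_seq,
               paste0(substr(seqc, 961, 1000), substr(seqc, 1, 60)))
})

test_that("smoothing and segmentation match the oracles on random tracks", {
  set.seed(99)
  for (rep in 1:100) {
    L <- sample(500:20000, 1)
    lambda <- sample(5:40, 1)
    values <- rpois(L, lambda)
    n_bumps <- sample(0:3, 1)
    for (b in seq_len(n_bumps)) {
      s <- sample(L - 200, 1)
      values[s:(s + 199)] <- values[s:(s + 199)] + rpois(200, 8 * lambda)
    }
    tr <- coverage_track("c", values)
    sm <- rolling_mean(tr)
    expect_identical(sm$values, oracle_rolling_mean(values, 50L, 10L)$values)
    gm <- genome_mean(tr)
    if (gm <= 0) next
    peaks <- call_peaks(sm, gm, contig_length = L)
    oracle <- oracle_call_peaks(sm$positions, sm$values, gm, 50L, 10L,
                                contig_length = L)
    if (is.null(oracle)) {
      expect_equal(nrow(peaks), 0L)
    } else {
      expect_equal(nrow(peaks), nrow(oracle))
      expect_equal(peaks$start, oracle$start)
      expect_equal(peaks$end, oracle$end)
      expect_equal(peaks$summit, oracle$summit)
      expect_equal(peaks$n_windows, oracle$n_windows)
    }
  }
})
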