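test_that("fragment pileup counts per-position overlaps exactly", {
  one <- depth_from_fragments(data.frame(start = 10, end = 20), 50,
                              circular = FALSE)
  expect_equal(one$values, c(rep(0, 10), rep(1, 10), rep(0, 30)))
  two <- depth_from_fragments(data.frame(start = c(10, 10), end = c(20, 20)),
                              50, circular = FALSE)
  expect_equal(two$values[11:20], rep(2, 10))

  withr::with_seed(8, {
    L <- 300
    fr <- data.frame(start = sample(0:(L - 1), 100, TRUE))
    fr$end <- fr$start + sample(1:80, 100, TRUE)
    expect_equal(depth_from_fragments(fr, L, circular = TRUE)$values,
                 oracle_pileup(fr, L, circular = TRUE))
    fr_lin <- fr
    fr_lin$end <- pmin(fr_lin$end, L)
    expect_equal(depth_from_fragments(fr_lin, L, circular = FALSE)$values,
                 oracle_pileup(fr_lin, L, circular = FALSE))
  })
  expect_error(depth_from_fragments(data.frame(start = -1, end = 5), 50),
               "non-negative")
  expect_error(depth_from_fragments(data.frame(start = 45, end = 55), 50,
                                    circular = FALSE), "linear")
})

test_that("log2 smoothing reproduces the brute-force windowed mean", {
  params <- peak_params(window_bp = 50)
  const <- coverage_track(rep(3, 200), circular = TRUE)
  expect_equal(log2_smooth(const, params)$values, rep(2, 200))  # log2(3+1)
  zeros <- coverage_track(rep(0, 200), circular = TRUE)
  expect_equal(log2_smooth(zeros, params)$values, rep(0, 200))

  withr::with_seed(15, {
    v <- rpois(400, 5)
    for (circ in c(TRUE, FALSE)) {
      tr <- coverage_track(v, circular = circ)
      got <- log2_smooth(tr, peak_params(window_bp = 21))$values
      expect_equal(got, oracle_rollmean(log2(v + 1), 21, circ))
      got50 <- log2_smooth(tr, peak_params(window_bp = 50))$values
      expect_equal(got50, oracle_rollmean(log2(v + 1), 50, circ))
    }
  })
  expect_error(log2_smooth(coverage_track(rep(1, 10)), peak_params(window_bp = 50)),
               "larger than the genome")
})

test_that("background subtraction is an exact position-wise difference", {
  a <- coverage_track(c(1, 2, 3), stage = "smoothed", circular = FALSE)
  b <- coverage_track(c(1, 2, 3), stage = "smoothed", circular = FALSE)
  expect_equal(subtract_background(a, b)$values, c(0, 0, 0))
  z <- coverage_track(c(0, 0, 0), stage = "smoothed", circular = FALSE)
  expect_equal(subtract_background(a, z)$values, a$values)
  withr::with_seed(2, {
    x <- coverage_track(rnorm(50), stage = "smoothed")
    y <- coverage_track(rnorm(50), stage = "smoothed")
    expect_equal(subtract_background(x, y)$values, x$values - y$values)
  })
  short <- coverage_track(c(1, 2), stage = "smoothed")
  expect_error(subtract_background(a, short), "length")
  raw <- coverage_track(c(1, 2, 3), stage = "raw", circular = FALSE)
  expect_error(subtract_background(a, raw), "stage")
})

test_that("mode baseline finds the dominant histogram bin", {
  dom <- coverage_track(c(rep(1.0, 90), seq(0, 5, length.out = 10)),
                        stage = "bg_subtracted")
  expect_lt(abs(mode_baseline(dom) - 1.0), 0.05 + 1e-9)
  const <- coverage_track(rep(2.73, 40), stage = "bg_subtracted")
  expect_lt(abs(mode_baseline(const) - 2.73), 0.05 + 1e-9)

  withr::with_seed(30, {  # mode of the majority mixture component
    v <- c(rnorm(8000, 0, 0.1), rnorm(2000, 5, 0.1))
    mix <- coverage_track(v, stage = "bg_subtracted")
    expect_lt(abs(mode_baseline(mix)), 0.15)
  })
})

test_that("sigma estimate is robust and flags degenerate tracks", {
  withr::with_seed(44, {
    v <- rnorm(1e5, 0, 0.5)
    tr <- coverage_track(v, stage = "baseline_subtracted")
    s <- estimate_track_sigma(tr)
    expect_lt(abs(s - 0.5) / 0.5, 0.02)
    # 5% outliers at +10 move the estimate by < 10%
    v_out <- v
    v_out[sample(1e5, 5e3)] <- 10
    s_out <- estimate_track_sigma(coverage_track(v_out,
                                                 stage = "baseline_subtracted"))
    expect_lt(abs(s_out - s) / s, 0.10)
  })
  expect_warning(
    s0 <- estimate_track_sigma(coverage_track(rep(1, 10),
                                              stage = "baseline_subtracted")),
    "degenerate")
  expect_equal(s0, 0)
})

test_that("peak calling needs positive sigma and returns nothing on flat tracks", {
  flat <- coverage_track(rep(0, 1000), stage = "baseline_subtracted")
  expect_equal(nrow(call_peaks(flat, sigma = 1)), 0)
  expect_error(call_peaks(flat, sigma = 0), "sigma")
})

test_that("a planted bump is called once with an accurate summit", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      L <- 50000
      v <- rnorm(L, 0, 0.5)
      bump <- 5 * exp(-((seq_len(L) - 5001)^2) / (2 * 40^2))  # 10 sigma
      tr <- coverage_track(v + bump, stage = "baseline_subtracted")
      pk <- call_peaks(tr, sigma = estimate_track_sigma(tr))
      nrow(pk) >= 1 && abs(pk$summit[which.max(pk$intensity)] - 5000) <= 25
    })
  }, logical(1))
  expect_true(all(hits))
})

test_that("two local maxima closer than the separation collapse to the higher", {
  v <- rep(0, 2000)
  v[1001] <- 5      # summit at 0-based 1000
  v[1031] <- 4      # 30 bp away, lower
  # widen into narrow plateaus so each is a genuine local max shape
  tr <- coverage_track(v, stage = "baseline_subtracted", circular = FALSE)
  pk <- call_peaks(tr, sigma = 1, params = peak_params(window_bp = 50))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$summit, 1000)

  # exact ties resolve to the leftmost position
  v2 <- rep(0, 2000); v2[c(501, 521)] <- 5
  pk2 <- call_peaks(coverage_track(v2, stage = "baseline_subtracted",
                                   circular = FALSE), sigma = 1)
  expect_equal(pk2$summit, 500)
})

test_that("doubling raw depth shifts the baseline but not the peak calls", {
  gt <- genome_truth(length_bp = 20000,
                     planted_peaks = data.frame(position = c(5000, 15000),
                                                fold_enrichment = 10,
                                                motif = "TATAAT"),
                     background_mean_depth = 20, seed = 12)
  ch <- gen_chip_tracks(gt)
  res1 <- chip_peak_pipeline(ch$target, ch$nonspecific)
  # doubling both tracks adds ~1 to each log2 track; the difference track and
  # hence peak calls are unchanged up to the log2 pseudocount's small effect
  t2 <- coverage_track(ch$target$values * 2, circular = TRUE)
  n2 <- coverage_track(ch$nonspecific$values * 2, circular = TRUE)
  res2 <- chip_peak_pipeline(t2, n2)
  expect_equal(res2$peaks$summit, res1$peaks$summit, tolerance = 1e-8)

  # adding a constant on the log2 scale moves the mode baseline by it
  sm <- log2_smooth(ch$target, peak_params())
  shifted <- coverage_track(sm$values + 2, stage = "smoothed")
  b0 <- mode_baseline(coverage_track(sm$values, stage = "bg_subtracted"))
  b2 <- mode_baseline(coverage_track(shifted$values, stage = "bg_subtracted"))
  expect_lt(abs((b2 - b0) - 2), 0.1 + 1e-9)
})

test_that("reported summits audit as local maxima above threshold", {
  gt <- genome_truth(length_bp = 30000,
                     planted_peaks = data.frame(position = c(8000, 21000),
                                                fold_enrichment = 6,
                                                motif = "TATAAT"),
                     background_mean_depth = 20, seed = 33)
  ch <- gen_chip_tracks(gt)
  res <- chip_peak_pipeline(ch$target, ch$nonspecific)
  v <- res$track$values
  L <- length(v)
  for (i in seq_len(nrow(res$peaks))) {
    p <- res$peaks$summit[i]
    expect_gte(v[p + 1], 3 * res$sigma)
    win <- ((p - 25):(p + 24)) %% L
    expect_equal(v[p + 1], max(v[win + 1]))
  }
})
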