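test_that("poisson_upper_tail matches brute-force summation and edge rules", {
  expect_equal(poisson_upper_tail(0, 5.0), 1.0)
  expect_equal(poisson_upper_tail(3, 0.0), 0.0)
  expect_equal(poisson_upper_tail(0, 0.0), 1.0)
  expect_equal(poisson_upper_tail(10, 2.0), naive_poisson_upper(10, 2.0),
               tolerance = 1e-12)
  expect_lt(poisson_upper_tail(30, 2.0), 1e-20)
  expect_equal(poisson_upper_tail(30, 2.0), naive_poisson_upper(30, 2.0),
               tolerance = 1e-12)
  expect_error(poisson_upper_tail(-1, 2), "non-negative")
  expect_error(poisson_upper_tail(1, -2), "non-negative")
})

test_that("candidate windows follow the step arithmetic and read floor", {
  prof <- fixture_profile(50L, len = 200L)
  cand <- scan_candidates(prof, peak_params(min_reads = 0L))
  expect_equal(cand$start, seq(0L, 175L, by = 25L))
  expect_equal(cand$end, pmin(cand$start + 50L, 200L))
  # 9 reads never emitted, 10 reads emitted
  p9 <- fixture_profile(rep(1000L, 9L))
  expect_equal(nrow(scan_candidates(p9, peak_params())), 0L)
  p10 <- fixture_profile(rep(1000L, 10L))
  expect_gt(nrow(scan_candidates(p10, peak_params())), 0L)
})

test_that("flank counts scale by w/flank_width with half-away rounding", {
  # candidate [1000,1050) with 30 reads; left flank [800,1000) has 7,
  # right flank [1050,1250) has 9 -> lambdas round(7/4)=2, round(9/4)=2
  prof <- fixture_profile(c(rep(1005L, 30L),
                            sample(800:999, 7L),
                            sample(1050:1249, 9L)))
  cand <- scan_candidates(prof, peak_params())
  row <- cand[cand$start == 1000L, ]
  expect_equal(row$left_flank_count, 7L)
  expect_equal(row$right_flank_count, 9L)
  expect_equal(row$lambda_left, 2)
  expect_equal(row$lambda_right, 2)
  expect_true(test_window(row, peak_params()))
  # 10 reads against the same flanks: tails ~8e-6 >> 1e-20 -> rejected
  prof10 <- fixture_profile(c(rep(1005L, 10L),
                              sample(800:999, 7L),
                              sample(1050:1249, 9L)))
  cand10 <- scan_candidates(prof10, peak_params())
  expect_false(test_window(cand10[cand10$start == 1000L, ], peak_params()))
  # zero flanks: degenerate lambda forces rejection of the null
  prof0 <- fixture_profile(rep(5000L, 12L))
  cand0 <- scan_candidates(prof0, peak_params())
  expect_true(all(test_window(cand0, peak_params())))
})

test_that("require_both demands rejection by both flanks", {
  # heavy left flank keeps the left test non-significant
  prof <- fixture_profile(c(rep(1005L, 30L), rep(900L, 120L)))
  cand <- scan_candidates(prof, peak_params())
  row <- cand[cand$start == 1000L, ]
  expect_true(test_window(row, peak_params()))
  expect_false(test_window(row, peak_params(require_both = TRUE)))
})

test_that("trim_window tightens to the nonzero span and is idempotent", {
  prof <- fixture_profile(c(210L, 230L))
  expect_equal(trim_window("chr1", "+", 200L, 250L, prof), c(210L, 231L))
  expect_equal(trim_window("chr1", "+", 210L, 231L, prof), c(210L, 231L))
  single <- fixture_profile(205L)
  expect_equal(trim_window("chr1", "+", 200L, 250L, single), c(205L, 206L))
  expect_null(trim_window("chr1", "+", 300L, 350L, prof))
})

test_that("merge_windows separation rule is strict and transitive", {
  iv <- data.frame(start = c(100L, 150L), end = c(121L, 171L))
  expect_equal(merge_windows(iv, 30L),
               data.frame(start = 100L, end = 171L))
  iv30 <- data.frame(start = c(100L, 151L), end = c(121L, 171L))
  expect_equal(nrow(merge_windows(iv30, 30L)), 2L)
  ovl <- data.frame(start = c(100L, 125L), end = c(150L, 175L))
  expect_equal(merge_windows(ovl, 30L),
               data.frame(start = 100L, end = 175L))
  # chains merge transitively
  chain <- data.frame(start = c(0L, 25L, 50L), end = c(10L, 35L, 60L))
  expect_equal(merge_windows(chain, 30L),
               data.frame(start = 0L, end = 60L))
  expect_error(merge_windows(data.frame(start = 1L, end = 2L,
                                        chrom = c("a")), 30L), NA)
  expect_error(merge_windows(data.frame(start = c(1L, 5L), end = c(2L, 6L),
                                        chrom = c("a", "b")), 30L),
               "single chromosome")
})

test_that("call_peaks recovers a planted cluster with exact boundaries", {
  set.seed(1)
  prof <- fixture_profile(sample(1000:1009, 50L, replace = TRUE))
  pk <- call_peaks(prof)
  expect_equal(nrow(pk), 1L)
  e <- prof$counts[["chr1\t+"]]
  expect_equal(pk$start, min(e$pos))
  expect_equal(pk$end, max(e$pos) + 1L)
  expect_equal(pk$total_count, 50L)
  expect_true(pk$summit >= pk$start && pk$summit < pk$end)
})

test_that("clusters merge under the 30-base rule and not over it", {
  near <- fixture_profile(c(rep(1000:1004, 10L), rep(1030:1034, 10L)))
  expect_equal(nrow(call_peaks(near)), 1L)   # separation 25 < 30
  # two clusters both inside one 50-base candidate window are inevitably
  # joined by that window's trimmed span, whatever the merge gap; only
  # clusters that no window covers jointly can stay apart
  joint <- fixture_profile(c(rep(1000:1004, 10L), rep(1045:1049, 10L)))
  expect_equal(nrow(call_peaks(joint)), 1L)
  far <- fixture_profile(c(rep(1000:1004, 10L), rep(1060:1064, 10L)))
  expect_equal(nrow(call_peaks(far)), 2L)    # separation 55 >= 30
})

test_that("peaks satisfy the structural invariants", {
  prof <- fixture_random_profile(7, n_clusters = 4L, cluster_reads = 50L)
  pk <- call_peaks(prof)
  expect_gt(nrow(pk), 0L)
  params <- peak_params()
  for (i in seq_len(nrow(pk))) {
    expect_gte(pk$total_count[i], params$min_reads)
    # boundary bases nonzero
    expect_gt(profile_count_range(prof, pk$chrom[i], pk$strand[i],
                                  pk$start[i], pk$start[i] + 1L), 0)
    expect_gt(profile_count_range(prof, pk$chrom[i], pk$strand[i],
                                  pk$end[i] - 1L, pk$end[i]), 0)
    expect_true(pk$summit[i] >= pk$start[i] && pk$summit[i] < pk$end[i])
  }
  # per-strand pairwise separation >= merge_gap
  for (strand in c("+", "-")) {
    ps <- pk[pk$strand == strand, ]
    if (nrow(ps) > 1L)
      expect_true(all(ps$start[-1L] - ps$end[-nrow(ps)] >=
                        params$merge_gap))
  }
  # determinism: identical input -> bit-identical output
  expect_identical(pk, call_peaks(prof))
})

test_that("significance is monotone in the candidate count", {
  params <- peak_params()
  for (lam in c(1, 3, 7, 15)) {
    cand <- data.frame(count = 10:80, lambda_left = lam,
                       lambda_right = lam)
    pass <- test_window(cand, params)
    expect_true(all(diff(as.integer(pass)) >= 0L))
  }
})

test_that("empty profile yields an empty peak list", {
  prof <- read_start_profile(c(chr1 = 1000L))
  expect_equal(nrow(call_peaks(prof)), 0L)
})
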