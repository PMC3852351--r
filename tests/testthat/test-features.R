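peak_row <- function(start, end, strand = "+", chrom = "chr1",
                     total_count = NULL) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             total_count = if (is.null(total_count)) NA_integer_
                           else total_count)
}

test_that("peak_summit takes the max count, ties to the 5' side", {
  prof <- fixture_profile(c(rep(100L, 3L), rep(105L, 7L), rep(110L, 2L)))
  expect_equal(peak_summit(peak_row(100L, 111L), prof), 105L)
  tie <- fixture_profile(c(rep(100L, 5L), rep(110L, 5L)))
  expect_equal(peak_summit(peak_row(100L, 111L), prof = tie), 100L)
  tie_m <- fixture_profile(c(rep(100L, 5L), rep(110L, 5L)), strand = "-")
  expect_equal(peak_summit(peak_row(100L, 111L, strand = "-"), tie_m), 110L)
  single <- fixture_profile(205L)
  expect_equal(peak_summit(peak_row(200L, 210L), single), 205L)
})

test_that("kurtosis matches the expanded-observation oracle", {
  # symmetric two-point distribution attains the Pearson minimum of 1
  two <- fixture_profile(c(rep(0L, 5L), rep(10L, 5L)))
  expect_equal(compute_kurtosis(peak_row(0L, 11L), two), 1.0)
  pos <- c(0L, 10L, 5L); cnt <- c(2L, 1L, 2L)
  prof <- fixture_profile(rep(pos, cnt))
  expect_equal(compute_kurtosis(peak_row(0L, 11L), prof),
               naive_kurtosis(pos, cnt))
  # all reads at one base: zero variance -> NA sentinel path
  degen <- fixture_profile(rep(7L, 12L))
  expect_true(is.na(compute_kurtosis(peak_row(0L, 20L), degen)))
  expect_error(compute_kurtosis(peak_row(500L, 600L), degen), "empty")
  # Pearson bound on random fixtures
  set.seed(3)
  for (i in 1:20) {
    pp <- fixture_profile(sample(0:50, 30L, replace = TRUE))
    expect_gte(compute_kurtosis(peak_row(0L, 51L), pp), 1.0)
  }
})

test_that("read density is count over width", {
  expect_equal(compute_read_density(peak_row(0L, 50L, total_count = 100L)),
               2.0)
  expect_equal(compute_read_density(peak_row(0L, 1L, total_count = 10L)),
               10.0)
})

test_that("conservation averages scored bases only; imputation fills NA", {
  tr <- score_track(c("chr1", "chr1"), c(100L, 101L), c(101L, 102L),
                    c(0.5, 1.5))
  expect_equal(compute_conservation(peak_row(100L, 102L), tr), 1.0)
  expect_true(is.na(compute_conservation(peak_row(500L, 520L), tr)))
  half <- score_track(c("chr1", "chr1"), c(100L, 102L), c(101L, 103L),
                      c(2.0, 4.0))
  expect_equal(compute_conservation(peak_row(100L, 110L), half), 3.0)

  fm <- data.frame(cell_line = "a", conservation = c(0.2, 0.8, NA))
  expect_equal(impute_missing_conservation(fm)$conservation[3], 0.2)
  neg <- data.frame(cell_line = "a", conservation = c(-1.5, 0.3, NA))
  expect_equal(impute_missing_conservation(neg)$conservation[3], -1.5)
  done <- data.frame(cell_line = "a", conservation = c(0.2, 0.8))
  expect_identical(impute_missing_conservation(done), done)
  allna <- data.frame(cell_line = "a", conservation = c(NA_real_, NA_real_))
  expect_error(impute_missing_conservation(allna), "all conservation")
})

test_that("max-score features use any-overlap over the extended window", {
  tr <- score_track(c("chr1", "chr1"), c(940L, 1090L), c(960L, 1110L),
                    c(3, 7))
  expect_equal(compute_max_score_feature(peak_row(1000L, 1050L), tr), 7)
  expect_equal(compute_max_score_feature(peak_row(5000L, 5050L), tr), 0)
  # interval straddling the extension boundary still counts
  straddle <- score_track("chr1", 890L, 910L, 5)
  expect_equal(compute_max_score_feature(peak_row(1000L, 1050L), straddle),
               5)
  # monotone in extension
  vals <- vapply(c(0L, 50L, 100L, 200L), function(ext)
    compute_max_score_feature(peak_row(1000L, 1050L), tr, ext), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("4-mer windows count overlapping occurrences around the summit", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 2000L)))
  v <- compute_kmer_features(1000L, "+", "chr1", genome)
  expect_equal(length(v), 512L)
  expect_equal(unname(v[["up_AAAA"]]), 497L)   # 500 - 4 + 1
  expect_equal(unname(v[["down_AAAA"]]), 497L)
  expect_equal(sum(v), 2L * 497L)
  # overlapping occurrences on mixed sequence, totals conserve positions
  set.seed(5)
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 2000L, replace = TRUE), collapse = "")))
  v2 <- compute_kmer_features(1000L, "+", "chr1", g2)
  up <- v2[grep("^up_", names(v2))]
  expect_equal(sum(up), 497L)
  # and the up-window counts equal direct string counting
  s <- as.character(Biostrings::subseq(g2[["chr1"]], 501L, 1000L))
  expect_equal(unname(up[["up_ACGT"]]),
               length(gregexpr("(?=ACGT)", s, perl = TRUE)[[1]]) *
                 (gregexpr("(?=ACGT)", s, perl = TRUE)[[1]][1] != -1))
})

test_that("k-mer features are invariant under genome mirror + strand flip", {
  set.seed(11)
  len <- 3000L
  g <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
  g_rc <- Biostrings::reverseComplement(g)
  names(g_rc) <- "chr1"
  summit <- 1200L
  v_plus <- compute_kmer_features(summit, "+", "chr1", g)
  v_minus <- compute_kmer_features(len - 1L - summit, "-", "chr1", g_rc)
  expect_equal(v_plus, v_minus)
})

test_that("RNA-seq difference is the Poisson lower tail of the flanks", {
  empty <- read_start_profile(c(chr1 = 10000L))
  expect_equal(compute_rnaseq_difference(peak_row(1000L, 1050L), empty), 1.0)
  down10 <- profile_add(empty, "chr1", "+",
                        1050L + sample(0:99, 10L, replace = TRUE))
  expect_equal(compute_rnaseq_difference(peak_row(1000L, 1050L), down10),
               exp(-10), tolerance = 1e-12)
  both5 <- profile_add(down10, "chr1", "-", rep(950L, 10L))
  # upstream 10, downstream 10 on the pooled strands
  expect_equal(compute_rnaseq_difference(peak_row(1000L, 1050L), both5),
               naive_poisson_lower(10L, 10), tolerance = 1e-12)
  # minus-strand peak swaps the flanks
  expect_equal(compute_rnaseq_difference(
    peak_row(1000L, 1050L, strand = "-"), down10),
    naive_poisson_lower(10L, 0), tolerance = 1e-12)
})

test_that("build_feature_matrix assembles the scenario columns", {
  set.seed(21)
  prof <- fixture_profile(c(rep(1000:1002, 20L), rep(3000:3020, 2L)))
  pk <- call_peaks(prof)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 10000L, replace = TRUE), collapse = "")))
  fm <- build_feature_matrix(pk, prof, genome = genome)
  expect_equal(sum(grepl("^(up|down)_", names(fm))), 512L)
  expect_true(all(c("kurtosis", "read_density") %in% names(fm)))
  tracks <- list(tfbs = score_track("chr1", 900L, 1100L, 5),
                 dnase = score_track("chr1", 900L, 1100L, 2),
                 h3k4me3 = score_track("chr1", 900L, 1100L, 9),
                 conservation = score_track("chr1", 1000L, 1003L, 1.5))
  fm2 <- build_feature_matrix(pk, prof, genome = genome, tracks = tracks)
  expect_true(all(c("tfbs", "dnase", "h3k4me3", "conservation") %in%
                    names(fm2)))
  expect_false(anyNA(fm2$conservation))
  # zero peaks -> empty matrix with the full header
  fm0 <- build_feature_matrix(pk[0, ], prof, genome = genome)
  expect_equal(nrow(fm0), 0L)
  expect_equal(sum(grepl("^(up|down)_", names(fm0))), 512L)
})
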