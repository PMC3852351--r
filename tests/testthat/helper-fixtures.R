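# Fixture builders shared across test files.

# profile with counts at given positions (possibly repeated) on one strand
fixture_profile <- function(positions, strand = "+", chrom = "chr1",
                            len = 10000L) {
  p <- read_start_profile(setNames(as.integer(len), chrom))
  profile_add(p, chrom, strand, positions)
}

# a random profile: homogeneous background plus planted clusters
fixture_random_profile <- function(seed, len = 10000L, bg_rate = 0.01,
                                   n_clusters = 3L, cluster_reads = 40L) {
  set.seed(seed)
  p <- read_start_profile(c(chr1 = as.integer(len)))
  for (strand in c("+", "-")) {
    n_bg <- rpois(1, len * bg_rate)
    if (n_bg > 0)
      p <- profile_add(p, "chr1", strand,
                       sample.int(len, n_bg, replace = TRUE) - 1L)
    if (n_clusters > 0) {
      centers <- sample.int(len - 200L, n_clusters) + 100L
      for (ctr in centers)
        p <- profile_add(p, "chr1", strand,
                         ctr + sample(0:9, cluster_reads, replace = TRUE))
    }
  }
  p
}

# write a minimal GTF with transcript records (1-based inclusive coords)
fixture_gtf <- function(path, df) {
  lines <- sprintf(
    '%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "g%d"; transcript_id "t%d";',
    df$chrom, df$start1, df$end1, df$strand, seq_len(nrow(df)),
    seq_len(nrow(df)))
  writeLines(lines, path)
  path
}

# two-class Gaussian feature fixture for SVM tests
fixture_gaussians <- function(seed, n_tss, n_non, mu_tss = c(2, 2),
                              mu_non = c(0, 0), sd = 1) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n_tss, mu_tss[1], sd), rnorm(n_tss, mu_tss[2], sd)),
             cbind(rnorm(n_non, mu_non[1], sd), rnorm(n_non, mu_non[2], sd)))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c("TSS", "nonTSS"), c(n_tss, n_non)))
}
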