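# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops, direct pmf summation, eigendecomposition of
# the covariance matrix.

# P(X >= x) by direct summation of the upper-tail pmf
naive_poisson_upper <- function(x, lam) {
  if (lam == 0) return(if (x == 0) 1 else 0)
  kmax <- as.integer(x + max(2000, 20 * lam))
  sum(dpois(x:kmax, lam))
}

# P(Y <= y) by direct summation of the lower-tail pmf
naive_poisson_lower <- function(y, lam) {
  if (lam == 0) return(1)
  sum(dpois(0:y, lam))
}

naive_round_nearest <- function(x) floor(x + 0.5)  # x >= 0 here

# Enumerate-every-window reference peak caller: per-base count vectors,
# explicit loops, direct pmf summation. Mirrors the published procedure
# but not the package's code paths.
naive_call_peaks <- function(profile, params) {
  out <- list()
  for (key in names(profile$counts)) {
    parts <- strsplit(key, "\t", fixed = TRUE)[[1]]
    chrom <- parts[1]; strand <- parts[2]
    len <- profile$chrom_lengths[[chrom]]
    cnt <- integer(len)
    e <- profile$counts[[key]]
    cnt[e$pos + 1L] <- e$count
    passing <- list()
    for (s in seq(0L, len - 1L, by = params$step)) {
      en <- min(s + params$w, len)
      c_cand <- sum(cnt[(s + 1L):en])
      if (c_cand < params$min_reads) next
      lf_s <- max(s - params$flank_width, 0L)
      rf_e <- min(en + params$flank_width, len)
      lraw <- if (s > lf_s) sum(cnt[(lf_s + 1L):s]) else 0L
      rraw <- if (rf_e > en) sum(cnt[(en + 1L):rf_e]) else 0L
      lam_l <- if (s > lf_s)
        naive_round_nearest(lraw * params$w / (s - lf_s)) else 0
      lam_r <- if (rf_e > en)
        naive_round_nearest(rraw * params$w / (rf_e - en)) else 0
      p_l <- naive_poisson_upper(c_cand, lam_l)
      p_r <- naive_poisson_upper(c_cand, lam_r)
      ok <- if (params$require_both)
        p_l < params$p_threshold && p_r < params$p_threshold
      else p_l < params$p_threshold || p_r < params$p_threshold
      if (!ok) next
      nz <- which(cnt[(s + 1L):en] > 0L) + s  # 1-based genomic
      passing[[length(passing) + 1L]] <-
        c(min(nz) - 1L, max(nz))              # 0-based half-open
    }
    if (length(passing) == 0L) next
    iv <- do.call(rbind, passing)
    iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
    merged <- list(iv[1, ])
    if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[i, 1] - last[2] < params$merge_gap)
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
      else merged[[length(merged) + 1L]] <- iv[i, ]
    }
    for (m in merged) {
      nz <- which(cnt[(m[1] + 1L):m[2]] > 0L) + m[1]
      st <- min(nz) - 1L; en2 <- max(nz)
      seg <- cnt[(st + 1L):en2]
      tot <- sum(seg)
      cand <- which(seg == max(seg)) + st - 1L  # 0-based positions
      summit <- if (strand == "+") min(cand) else max(cand)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = as.integer(st), end = as.integer(en2),
        strand = strand, total_count = as.integer(tot),
        summit = as.integer(summit), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      total_count = integer(0), summit = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# kurtosis by expanding counts into an observation list
naive_kurtosis <- function(positions, counts) {
  obs <- rep(positions, counts)
  mu <- mean(obs)
  m2 <- mean((obs - mu)^2)
  m4 <- mean((obs - mu)^4)
  m4 / m2^2
}

# variable-PC1 correlation and covariance via explicit eigendecomposition
naive_pc1_stats <- function(x) {
  cv <- cov(x)
  eg <- eigen(cv, symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  scores <- scale(x, center = TRUE, scale = FALSE) %*% v1
  list(eigenvalue = eg$values[1],
       correlation = as.numeric(cor(x, scores)),
       covariance = as.numeric(cov(x, scores)))
}
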