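#' Summit of a peak
#'
#' The position with the maximum single-base read-start count; ties are
#' broken by the 5'-most position on the peak's strand.
#'
#' @param peak one-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param profile a [read_start_profile()].
#' @return 0-based summit position.
#' @export
peak_summit <- function(peak, profile) {
  summit_of(profile, peak$chrom, peak$strand, peak$start, peak$end)
}

#' Pearson's kurtosis of a peak's read-start distribution
#'
#' Each read start is one observation of its genomic position
#' (count-weighted); the statistic is the fourth central moment divided by
#' the squared variance, with population moments (divide by n). Values are
#' bounded below by 1; the normal distribution attains 3. A peak whose
#' reads all fall on one base has zero variance and returns `NA`
#' (the caller substitutes the zero-variance sentinel, see
#' [build_feature_matrix()]).
#'
#' @inheritParams peak_summit
#' @return kurtosis, or `NA` for a zero-variance peak.
#' @export
compute_kurtosis <- function(peak, profile) {
  s <- profile_slice(profile, peak$chrom, peak$strand, peak$start, peak$end)
  if (length(s$pos) == 0L) stop("empty peak: no read starts in interval")
  n <- sum(s$count)
  mu <- sum(s$pos * s$count) / n
  m2 <- sum(s$count * (s$pos - mu)^2) / n
  if (m2 == 0) return(NA_real_)
  m4 <- sum(s$count * (s$pos - mu)^4) / n
  m4 / m2^2
}

#' Read density of a peak
#' @param peak one-row data.frame with `start`, `end`, `total_count`.
#' @return reads per base: `total_count / (end - start)`.
#' @export
compute_read_density <- function(peak) {
  peak$total_count / (peak$end - peak$start)
}

# per-base score vector over [start, end); NA where no interval covers the
# base; bases covered by several intervals take the mean of their scores
track_base_scores <- function(track, chrom, start, end) {
  width <- end - start
  acc <- numeric(width)
  cov <- integer(width)
  hits <- track$chrom == chrom & track$start < end & track$end > start
  for (i in which(hits)) {
    lo <- max(track$start[i], start) - start + 1L
    hi <- min(track$end[i], end) - start
    acc[lo:hi] <- acc[lo:hi] + track$score[i]
    cov[lo:hi] <- cov[lo:hi] + 1L
  }
  out <- rep(NA_real_, width)
  out[cov > 0L] <- acc[cov > 0L] / cov[cov > 0L]
  out
}

#' Mean per-base conservation over a peak
#'
#' Averages single-base scores over the bases of the peak that carry a
#' score; returns `NA` when no peak base is scored (such peaks take the
#' imputed minimum, see [impute_missing_conservation()]).
#'
#' @param peak one-row data.frame with `chrom`, `start`, `end`.
#' @param track a `ScoreTrack` of per-base (or interval) conservation.
#' @return mean score over scored bases, or `NA`.
#' @export
compute_conservation <- function(peak, track) {
  v <- track_base_scores(track, peak$chrom, peak$start, peak$end)
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Impute missing conservation values
#'
#' Replaces each missing conservation entry with the minimum observed
#' conservation mean of the same cell line; no other column is altered.
#'
#' @param fm a feature matrix from [build_feature_matrix()] with a
#'   `conservation` column and a `cell_line` column.
#' @return the feature matrix with no missing conservation values.
#' @export
impute_missing_conservation <- function(fm) {
  if (!"conservation" %in% names(fm)) return(fm)
  for (cl in unique(fm$cell_line)) {
    sel <- fm$cell_line == cl
    v <- fm$conservation[sel]
    if (all(is.na(v)))
      stop("all conservation values missing for cell line ", cl)
    v[is.na(v)] <- min(v, na.rm = TRUE)
    fm$conservation[sel] <- v
  }
  fm
}

#' Maximum track score near a peak
#'
#' The maximum score of any track interval overlapping the peak extended
#' by `extension` bases on both sides; 0 when nothing overlaps.
#'
#' @param peak one-row data.frame with `chrom`, `start`, `end`.
#' @param track a `ScoreTrack`.
#' @param extension bases added on each side (default 100).
#' @return maximum overlapping score, or 0.
#' @export
compute_max_score_feature <- function(peak, track, extension = 100L) {
  if (extension < 0L) stop("extension must be >= 0")
  qs <- peak$start - extension
  qe <- peak$end + extension
  hits <- track$chrom == peak$chrom & track$start < qe & track$end > qs
  if (!any(hits)) 0 else max(track$score[hits])
}

#' K-mer counts in windows flanking a summit
#'
#' A `window`-base sequence window is taken on each side of the summit,
#' strand-aware: upstream is 5' (cap-proximal) of the summit, downstream is
#' 3'. For minus-strand peaks both windows are read as the reverse
#' complement, so upstream counts describe promoter-proximal sequence in
#' transcriptional orientation. Overlapping k-mer occurrences are counted;
#' k-mers containing non-ACGT letters are skipped. The summit base itself
#' belongs to neither window. Windows truncated at a chromosome end simply
#' yield fewer counts.
#'
#' @param summit 0-based summit position.
#' @param strand `"+"` or `"-"`.
#' @param chrom chromosome name.
#' @param genome a `DNAStringSet` (names = chromosomes).
#' @param k k-mer width (default 4).
#' @param window flank width in bases (default 500).
#' @return named integer vector of length `2 * 4^k` with names
#'   `up_<kmer>` then `down_<kmer>`.
#' @export
compute_kmer_features <- function(summit, strand, chrom, genome, k = 4L,
                                  window = 500L) {
  if (k < 1L) stop("k must be >= 1")
  if (window < k) stop("window must be >= k")
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (is.na(len)) stop("chromosome not in genome: ", chrom)
  seq_in <- function(s, e) {   # 0-based half-open, clipped
    s <- max(s, 0L); e <- min(e, len)
    if (e <= s) return(Biostrings::DNAString(""))
    Biostrings::subseq(genome[[chrom]], s + 1L, e)
  }
  if (strand == "+") {
    up <- seq_in(summit - window, summit)
    down <- seq_in(summit + 1L, summit + 1L + window)
  } else {
    up <- Biostrings::reverseComplement(seq_in(summit + 1L,
                                               summit + 1L + window))
    down <- Biostrings::reverseComplement(seq_in(summit - window, summit))
  }
  cu <- Biostrings::oligonucleotideFrequency(up, width = k)
  cd <- Biostrings::oligonucleotideFrequency(down, width = k)
  stats::setNames(c(cu, cd),
                  c(paste0("up_", names(cu)), paste0("down_", names(cd))))
}

#' RNA-seq flank asymmetry of a peak
#'
#' Read starts are counted in `flank`-base windows immediately upstream of
#' the peak's 5' edge and downstream of its 3' edge (strand-aware, both
#' strands of the RNA-seq profile pooled). The feature is the Poisson
#' lower tail P(Y <= y) with y the upstream count and the rate equal to
#' the downstream count: values near 0 mean many more reads downstream
#' than upstream, as expected at a true TSS.
#'
#' @param peak one-row data.frame with `chrom`, `start`, `end`, `strand`.
#' @param rnaseq_profile a [read_start_profile()] of RNA-seq read starts.
#' @param flank flank width (default 100).
#' @return probability in `[0, 1]`.
#' @export
compute_rnaseq_difference <- function(peak, rnaseq_profile, flank = 100L) {
  count_both <- function(s, e) {
    s <- max(s, 0L)
    profile_count_range(rnaseq_profile, peak$chrom, "+", s, e) +
      profile_count_range(rnaseq_profile, peak$chrom, "-", s, e)
  }
  if (peak$strand == "+") {
    y_up <- count_both(peak$start - flank, peak$start)
    lam_down <- count_both(peak$end, peak$end + flank)
  } else {
    y_up <- count_both(peak$end, peak$end + flank)
    lam_down <- count_both(peak$start - flank, peak$start)
  }
  stats::ppois(y_up, lam_down)
}

kmer_names <- function(k = 4L) {
  base <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  c(paste0("up_", base), paste0("down_", base))
}

#' Assemble the peak feature matrix
#'
#' One row per peak. Internal features (kurtosis, read density, 4-mer
#' counts) need only the CAGE profile and genome; external features
#' (max-score tracks, conservation, RNA-seq difference) are added when the
#' corresponding input is supplied in `tracks` / `rnaseq_profile`.
#' Zero-variance kurtosis (single-base peaks) is replaced by the maximum
#' kurtosis among non-degenerate peaks of the same cell line; missing
#' conservation is imputed with the per-cell-line minimum.
#'
#' @param peaks data.frame from [call_peaks()].
#' @param profile the CAGE [read_start_profile()] the peaks came from.
#' @param genome `DNAStringSet`, required for 4-mer features.
#' @param tracks named list with any of `tfbs`, `dnase`, `h3k4me3`,
#'   `conservation` (`ScoreTrack`s).
#' @param rnaseq_profile optional RNA-seq [read_start_profile()].
#' @param cell_line cell-line identifier stored per row.
#' @param k,kmer_window,extension,rnaseq_flank feature geometry knobs
#'   (defaults 4, 500, 100, 100).
#' @return data.frame with meta columns `peak_id`, `cell_line`, `chrom`,
#'   `start`, `end`, `strand` and one column per feature.
#' @export
build_feature_matrix <- function(peaks, profile, genome = NULL,
                                 tracks = list(), rnaseq_profile = NULL,
                                 cell_line = "cell1", k = 4L,
                                 kmer_window = 500L, extension = 100L,
                                 rnaseq_flank = 100L) {
  n <- nrow(peaks)
  meta <- data.frame(
    peak_id = if (n) paste0(cell_line, "_peak_", seq_len(n)) else character(0),
    cell_line = rep(cell_line, n),
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    strand = peaks$strand, stringsAsFactors = FALSE)

  one <- function(i) peaks[i, , drop = FALSE]
  kurt <- if (n) vapply(seq_len(n), function(i)
    compute_kurtosis(one(i), profile), numeric(1)) else numeric(0)
  if (any(is.na(kurt))) {
    if (all(is.na(kurt)))
      kurt[is.na(kurt)] <- 1  # every peak single-base: Pearson minimum
    else kurt[is.na(kurt)] <- max(kurt, na.rm = TRUE)
  }
  dens <- if (n) vapply(seq_len(n), function(i)
    compute_read_density(one(i)), numeric(1)) else numeric(0)
  fm <- cbind(meta, kurtosis = kurt, read_density = dens)

  if (!is.null(genome)) {
    km <- matrix(0L, nrow = n, ncol = 2 * 4^k,
                 dimnames = list(NULL, kmer_names(k)))
    for (i in seq_len(n)) {
      p <- one(i)
      v <- compute_kmer_features(peak_summit(p, profile), p$strand,
                                 p$chrom, genome, k, kmer_window)
      km[i, names(v)] <- v
    }
    fm <- cbind(fm, as.data.frame(km))
  }
  for (tn in c("tfbs", "dnase", "h3k4me3")) {
    if (!is.null(tracks[[tn]])) {
      fm[[tn]] <- if (n) vapply(seq_len(n), function(i)
        compute_max_score_feature(one(i), tracks[[tn]], extension),
        numeric(1)) else numeric(0)
    }
  }
  if (!is.null(tracks$conservation)) {
    fm$conservation <- if (n) vapply(seq_len(n), function(i)
      compute_conservation(one(i), tracks$conservation), numeric(1))
      else numeric(0)
    if (n) fm <- impute_missing_conservation(fm)
  }
  if (!is.null(rnaseq_profile)) {
    fm$rnaseq_diff <- if (n) vapply(seq_len(n), function(i)
      compute_rnaseq_difference(one(i), rnaseq_profile, rnaseq_flank),
      numeric(1)) else numeric(0)
  }
  fm
}

#' Names of the non-feature (meta) columns of a feature matrix
#' @param fm a feature matrix.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(fm) {
  setdiff(names(fm), c("peak_id", "cell_line", "chrom", "start", "end",
                       "strand", "label"))
}
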