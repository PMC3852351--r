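#' Peak-calling parameters
#'
#' Defaults follow the published sliding-window procedure: 50-base candidate
#' windows slid in half-window steps, 200-base flanks, a 10-read floor, a
#' Poisson tail threshold of 1e-20 and a 30-base merge distance.
#'
#' @param w candidate window width in bases.
#' @param step slide increment; defaults to `w / 2`.
#' @param flank_width width of each flanking window.
#' @param min_reads candidate windows with fewer reads are immediately
#'   discarded.
#' @param p_threshold significance cutoff on the Poisson upper tail.
#' @param merge_gap peak windows separated by less than this many bases are
#'   merged.
#' @param mapq_min mapping-quality cutoff applied when reading alignments.
#' @param require_both if `TRUE`, both flank tests (rather than at least
#'   one) must reject for a candidate to become a peak window.
#' @return a `PeakCallingParams` list.
#' @export
peak_params <- function(w = 50L, step = NULL, flank_width = 200L,
                        min_reads = 10L, p_threshold = 1e-20,
                        merge_gap = 30L, mapq_min = 20L,
                        require_both = FALSE) {
  if (is.null(step)) step <- as.integer(w / 2)
  w <- as.integer(w); step <- as.integer(step)
  flank_width <- as.integer(flank_width)
  min_reads <- as.integer(min_reads); merge_gap <- as.integer(merge_gap)
  if (w <= 0L || step <= 0L || flank_width <= 0L)
    stop("w, step and flank_width must be positive")
  if (min_reads < 0L || merge_gap < 0L)
    stop("min_reads and merge_gap must be non-negative")
  if (!(p_threshold > 0 && p_threshold < 1))
    stop("p_threshold must be in (0, 1)")
  structure(list(w = w, step = step, flank_width = flank_width,
                 min_reads = min_reads, p_threshold = p_threshold,
                 merge_gap = merge_gap, mapq_min = as.integer(mapq_min),
                 require_both = isTRUE(require_both)),
            class = "PeakCallingParams")
}

#' Poisson upper-tail probability P(X >= x)
#'
#' Computed in log space so tails far below 1e-20 remain finite and
#' ordered. The degenerate `lam = 0` Poisson gives 1 when `x = 0` and 0
#' otherwise.
#'
#' @param x non-negative integer count(s).
#' @param lam non-negative Poisson mean(s).
#' @param log if `TRUE`, return the natural log of the tail probability.
#' @return `P(X >= x)` (or its log), vectorised over `x`/`lam`.
#' @export
poisson_upper_tail <- function(x, lam, log = FALSE) {
  if (any(x < 0) || any(lam < 0)) stop("x and lam must be non-negative")
  n <- max(length(x), length(lam))
  x <- rep_len(x, n); lam <- rep_len(lam, n)
  lp <- numeric(n)
  zero <- lam == 0
  lp[zero] <- ifelse(x[zero] == 0, 0, -Inf)
  if (any(!zero))
    lp[!zero] <- stats::ppois(x[!zero] - 1, lam[!zero],
                              lower.tail = FALSE, log.p = TRUE)
  lp[x == 0] <- 0
  if (log) lp else exp(lp)
}

# "rounded to the nearest integer" with ties away from zero (7/4 -> 2,
# 10/4 -> 3), so the enumeration oracle can match bit-exactly.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Enumerate candidate windows over a read-start profile
#'
#' Windows `[i * step, i * step + w)` are generated per (chromosome,
#' strand), truncated at the chromosome end; windows below the `min_reads`
#' floor are dropped. Flank counts are scaled by `w / actual_flank_width`
#' (flanks are truncated at chromosome boundaries) and rounded half away
#' from zero to give the Poisson means `lambda_left`/`lambda_right`.
#'
#' @param profile a [read_start_profile()].
#' @param params a [peak_params()].
#' @return data.frame of candidate windows: `chrom`, `strand`, `start`,
#'   `end`, `count`, `left_flank_count`, `right_flank_count`,
#'   `lambda_left`, `lambda_right`.
#' @export
scan_candidates <- function(profile, params = peak_params()) {
  stopifnot(inherits(profile, "ReadStartProfile"),
            inherits(params, "PeakCallingParams"))
  res <- lapply(names(profile$counts), function(key) {
    parts <- strsplit(key, "\t", fixed = TRUE)[[1L]]
    chrom <- parts[1L]; strand <- parts[2L]
    len <- profile$chrom_lengths[[chrom]]
    starts <- seq.int(0L, len - 1L, by = params$step)
    ends <- pmin(starts + params$w, len)
    count <- profile_count_ranges(profile, chrom, strand, starts, ends)
    keep <- count >= params$min_reads
    if (!any(keep)) return(NULL)
    starts <- starts[keep]; ends <- ends[keep]; count <- count[keep]
    lf_start <- pmax(starts - params$flank_width, 0L)
    lf_w <- starts - lf_start
    rf_end <- pmin(ends + params$flank_width, len)
    rf_w <- rf_end - ends
    left <- profile_count_ranges(profile, chrom, strand, lf_start, starts)
    right <- profile_count_ranges(profile, chrom, strand, ends, rf_end)
    lam_l <- ifelse(lf_w > 0L, round_half_away(left * params$w / lf_w), 0)
    lam_r <- ifelse(rf_w > 0L, round_half_away(right * params$w / rf_w), 0)
    data.frame(chrom = chrom, strand = strand, start = starts, end = ends,
               count = count, left_flank_count = left,
               right_flank_count = right, lambda_left = lam_l,
               lambda_right = lam_r, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      count = integer(0), left_flank_count = integer(0),
                      right_flank_count = integer(0),
                      lambda_left = numeric(0), lambda_right = numeric(0))
  res
}

#' Significance test for candidate windows
#'
#' The candidate count is tested against two Poisson nulls, one per scaled
#' flank, in log space. By default a window passes when *either* tail is
#' below `p_threshold`; `require_both` demands both.
#'
#' @param cand data.frame of candidates from [scan_candidates()].
#' @param params a [peak_params()].
#' @return logical vector, `TRUE` for windows passing the test.
#' @export
test_window <- function(cand, params = peak_params()) {
  if (nrow(cand) == 0L) return(logical(0))
  log_thr <- log(params$p_threshold)
  lp_l <- poisson_upper_tail(cand$count, cand$lambda_left, log = TRUE)
  lp_r <- poisson_upper_tail(cand$count, cand$lambda_right, log = TRUE)
  if (params$require_both) lp_l < log_thr & lp_r < log_thr
  else lp_l < log_thr | lp_r < log_thr
}

#' Trim an interval to its outermost nonzero read-start positions
#'
#' @param chrom,strand,start,end interval to trim (0-based half-open).
#' @param profile a [read_start_profile()].
#' @return `c(start, end)` of the tight nonzero span, or `NULL` when the
#'   interval contains no read starts.
#' @export
trim_window <- function(chrom, strand, start, end, profile) {
  s <- profile_slice(profile, chrom, strand, start, end)
  if (length(s$pos) == 0L) return(NULL)
  c(s$pos[1L], s$pos[length(s$pos)] + 1L)
}

#' Merge intervals separated by less than a gap
#'
#' All intervals must lie on one (chromosome, strand). Two intervals merge
#' when `next_start - prev_end < merge_gap` (overlap counts as negative
#' separation); merging is transitive.
#'
#' @param intervals data.frame with `start`, `end`, and optionally
#'   `chrom`/`strand` (must then be constant).
#' @param merge_gap minimum separation that prevents merging.
#' @return data.frame of merged `start`/`end`, sorted.
#' @export
merge_windows <- function(intervals, merge_gap = 30L) {
  if (nrow(intervals) == 0L) return(intervals[, c("start", "end")])
  if ("chrom" %in% names(intervals) &&
      length(unique(intervals$chrom)) > 1L)
    stop("merge_windows requires a single chromosome")
  if ("strand" %in% names(intervals) &&
      length(unique(intervals$strand)) > 1L)
    stop("merge_windows requires a single strand")
  ord <- order(intervals$start, intervals$end)
  s <- intervals$start[ord]; e <- intervals$end[ord]
  run_end <- cummax(e)
  # a new group starts where the separation to everything before is >= gap
  new_grp <- c(TRUE, s[-1L] - run_end[-length(e)] >= merge_gap)
  grp <- cumsum(new_grp)
  data.frame(start = as.integer(tapply(s, grp, min)),
             end = as.integer(tapply(e, grp, max)), row.names = NULL)
}

summit_of <- function(profile, chrom, strand, start, end) {
  s <- profile_slice(profile, chrom, strand, start, end)
  if (length(s$pos) == 0L) return(NA_integer_)
  mx <- s$pos[s$count == max(s$count)]
  if (strand == "+") min(mx) else max(mx)  # ties -> 5'-most
}

#' Call CAGE read-start peaks
#'
#' Full sliding-window procedure per (chromosome, strand): enumerate
#' candidate windows, drop those under the read floor, test against both
#' flank Poisson nulls, trim passing windows to their nonzero span, merge
#' windows closer than `merge_gap`, re-trim, and annotate each peak with
#' its total read count and summit (maximum single-base count, ties broken
#' towards the 5' end of the peak's strand).
#'
#' @param profile a [read_start_profile()].
#' @param params a [peak_params()].
#' @return data.frame of peaks: `chrom`, `start`, `end`, `strand`,
#'   `total_count`, `summit`, sorted by chromosome and start.
#' @export
call_peaks <- function(profile, params = peak_params()) {
  cand <- scan_candidates(profile, params)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      total_count = integer(0), summit = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[test_window(cand, params), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  out <- lapply(split(cand, paste(cand$chrom, cand$strand, sep = "\t")),
                function(cc) {
    chrom <- cc$chrom[1L]; strand <- cc$strand[1L]
    trimmed <- lapply(seq_len(nrow(cc)), function(i)
      trim_window(chrom, strand, cc$start[i], cc$end[i], profile))
    trimmed <- do.call(rbind, trimmed)
    if (is.null(trimmed)) return(NULL)
    merged <- merge_windows(
      data.frame(start = trimmed[, 1L], end = trimmed[, 2L]),
      params$merge_gap)
    # re-trim (no-op for merges of trimmed windows, kept as an invariant)
    final <- lapply(seq_len(nrow(merged)), function(i)
      trim_window(chrom, strand, merged$start[i], merged$end[i], profile))
    final <- do.call(rbind, final)
    n <- nrow(final)
    data.frame(
      chrom = rep(chrom, n), start = final[, 1L], end = final[, 2L],
      strand = rep(strand, n),
      total_count = profile_count_ranges(profile, chrom, strand,
                                         final[, 1L], final[, 2L]),
      summit = vapply(seq_len(n), function(i)
        summit_of(profile, chrom, strand, final[i, 1L], final[i, 2L]),
        integer(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
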