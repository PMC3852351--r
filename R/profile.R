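#' Strand-specific read-start profiles
#'
#' A `ReadStartProfile` stores, per (chromosome, strand), a sparse map from
#' 0-based genomic position to the number of read 5' ends observed there.
#' Zero counts are never stored. It is the sole input to peak calling,
#' kurtosis and summit finding.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bases.
#' @return an empty `ReadStartProfile`.
#' @export
read_start_profile <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  chrom_lengths <- vapply(chrom_lengths, as.integer, integer(1))
  if (any(chrom_lengths <= 0L)) stop("chromosome lengths must be positive")
  structure(list(counts = list(), chrom_lengths = chrom_lengths),
            class = "ReadStartProfile")
}

profile_key <- function(chrom, strand) paste(chrom, strand, sep = "\t")

#' Add read-start positions to a profile
#'
#' Positions outside `[0, chrom_length)` are rejected with a warning, per
#' record; valid positions are tabulated and merged into the sparse store.
#'
#' @param profile a [read_start_profile()].
#' @param chrom chromosome name (must be declared in the profile).
#' @param strand `"+"` or `"-"`.
#' @param positions integer vector of 0-based read 5'-end positions; one
#'   count is added per element.
#' @return the updated profile.
#' @export
profile_add <- function(profile, chrom, strand, positions) {
  stopifnot(inherits(profile, "ReadStartProfile"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!chrom %in% names(profile$chrom_lengths))
    stop("unknown chromosome: ", chrom)
  len <- profile$chrom_lengths[[chrom]]
  positions <- as.integer(positions)
  bad <- positions < 0L | positions >= len
  if (any(bad)) {
    warning(sum(bad), " read start(s) outside [0, ", len, ") on ", chrom,
            " rejected")
    positions <- positions[!bad]
  }
  if (length(positions) == 0L) return(profile)
  tab <- table(positions)
  pos <- as.integer(names(tab))
  cnt <- as.integer(tab)
  key <- profile_key(chrom, strand)
  old <- profile$counts[[key]]
  if (!is.null(old)) {
    pos <- c(old$pos, pos)
    cnt <- c(old$count, cnt)
    agg <- rowsum(cnt, pos)
    pos <- as.integer(rownames(agg))
    cnt <- as.integer(agg[, 1L])
  }
  ord <- order(pos)
  profile$counts[[key]] <- list(pos = pos[ord], count = cnt[ord])
  profile
}

#' @export
print.ReadStartProfile <- function(x, ...) {
  cat("ReadStartProfile:", length(x$chrom_lengths), "chromosome(s),",
      profile_total(x), "read starts over", length(x$counts),
      "(chrom, strand) track(s)\n")
  invisible(x)
}

#' Total read-start mass of a profile
#' @param profile a [read_start_profile()].
#' @return total number of stored read starts.
#' @export
profile_total <- function(profile) {
  sum(vapply(profile$counts, function(e) sum(e$count), numeric(1)))
}

#' Query a read-start profile
#'
#' `profile_slice` returns the stored positions and counts inside
#' `[start, end)`; `profile_count_range` their total.
#'
#' @param profile a [read_start_profile()].
#' @param chrom,strand track to query.
#' @param start,end 0-based half-open query interval.
#' @return `profile_slice`: list with `pos` and `count` vectors;
#'   `profile_count_range`: a single count.
#' @export
profile_slice <- function(profile, chrom, strand, start, end) {
  e <- profile$counts[[profile_key(chrom, strand)]]
  if (is.null(e)) return(list(pos = integer(0), count = integer(0)))
  keep <- e$pos >= start & e$pos < end
  list(pos = e$pos[keep], count = e$count[keep])
}

#' @rdname profile_slice
#' @export
profile_count_range <- function(profile, chrom, strand, start, end) {
  s <- profile_slice(profile, chrom, strand, start, end)
  sum(s$count)
}

# Count read starts in many [starts, ends) ranges at once via cumulative sums.
profile_count_ranges <- function(profile, chrom, strand, starts, ends) {
  e <- profile$counts[[profile_key(chrom, strand)]]
  if (is.null(e)) return(integer(length(starts)))
  cum <- c(0, cumsum(e$count))
  hi <- findInterval(ends - 1L, e$pos)    # positions <= end - 1
  lo <- findInterval(starts - 1L, e$pos)  # positions <  start
  as.integer(cum[hi + 1L] - cum[lo + 1L])
}
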