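#' Load read 5'-start positions from a SAM/BAM file
#'
#' Each retained alignment contributes exactly one count at its 5'-most
#' aligned base: the leftmost aligned base for forward-strand reads, the
#' rightmost aligned base for reverse-strand reads (CAGE reads begin at the
#' 5' cap, so the cap-proximal end of a reverse read is its rightmost
#' genomic base). Unmapped, secondary and supplementary records are
#' excluded, then records with mapping quality below `mapq_min` are
#' discarded. No deduplication is performed.
#'
#' @param path path to a SAM or BAM file (SAM is converted on the fly).
#' @param mapq_min minimum mapping quality; records with MAPQ strictly below
#'   this are discarded (default 20). Records with missing MAPQ (255) are
#'   kept.
#' @return a [read_start_profile()] keyed by the header's `@SQ` chromosomes.
#' @export
load_read_starts <- function(path, mapq_min = 20L) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  if (mapq_min < 0L) stop("mapq_min must be >= 0")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            indexDestination = FALSE, overwrite = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (length(hdr) == 0L) stop("alignment file has no @SQ header: ", path)
  prof <- read_start_profile(hdr)

  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("rname", "strand", "pos", "mapq", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  if (length(rec$pos) == 0L) return(prof)

  mapq <- rec$mapq
  keep <- is.na(mapq) | mapq >= mapq_min
  chrom <- as.character(rec$rname)[keep]
  strand <- as.character(rec$strand)[keep]
  pos1 <- rec$pos[keep]                 # 1-based leftmost
  cigar <- rec$cigar[keep]
  if (length(pos1) == 0L) return(prof)

  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  start0 <- ifelse(strand == "+", pos1 - 1L, pos1 - 1L + refw - 1L)
  for (key in unique(paste(chrom, strand))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1L]]
    sel <- chrom == parts[1L] & strand == parts[2L]
    prof <- profile_add(prof, parts[1L], parts[2L], start0[sel])
  }
  prof
}

#' Load strand-aware transcript 5' start positions from GTF/GFF
#'
#' One entry per transcript-level record; the start is the annotated 5' end
#' (leftmost coordinate on `+`, rightmost on `-`), converted from 1-based
#' inclusive GTF coordinates to the internal 0-based convention.
#' Strandless transcript records are rejected with a warning.
#'
#' @param path path to a GTF or GFF annotation file.
#' @return data.frame with columns `chrom`, `position` (0-based), `strand`.
#' @export
load_transcript_starts <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  empty <- data.frame(chrom = character(0), position = integer(0),
                      strand = character(0))
  content <- readLines(path, warn = FALSE)
  if (!any(nzchar(content) & !startsWith(content, "#")))
    return(empty)
  gr <- rtracklayer::import(path)
  if (length(gr) > 0L && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type == "transcript"]
  if (length(gr) == 0L) return(empty)
  strand <- as.character(BiocGenerics::strand(gr))
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    warning(sum(bad), " transcript record(s) without strand rejected")
    gr <- gr[!bad]
    strand <- strand[!bad]
  }
  pos <- ifelse(strand == "+",
                BiocGenerics::start(gr) - 1L,   # 1-based -> 0-based
                BiocGenerics::end(gr) - 1L)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             position = as.integer(pos), strand = strand,
             stringsAsFactors = FALSE)
}

#' Load an interval score track (bedGraph / scored BED)
#'
#' Accepts bedGraph (`chrom start end score`) and BED-with-score
#' (`chrom start end name score [...]`) dialects; the dialect is sniffed per
#' line from column 4. Overlapping records are permitted. `track`, browser
#' and `#` comment lines are skipped.
#'
#' @param path path to the track file.
#' @return a `ScoreTrack`: data.frame of `chrom`, `start`, `end` (0-based
#'   half-open) and `score`.
#' @export
load_score_track <- function(path) {
  if (!file.exists(path)) stop("cannot read track file: ", path)
  lines <- readLines(path)
  out <- list(chrom = character(0), start = integer(0), end = integer(0),
              score = numeric(0))
  rows <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^(#|track|browser)", ln)) next
    f <- strsplit(ln, "[ \t]+")[[1L]]
    if (length(f) < 4L)
      stop("malformed track line ", i, " in ", path, ": fewer than 4 fields")
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end) || start < 0L || end <= start)
      stop("malformed track line ", i, " in ", path, ": bad interval")
    sc <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(sc)) {
      # BED dialect: col 4 is a name, the score is col 5
      sc <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else NA
      if (is.na(sc))
        stop("non-numeric score at track line ", i, " in ", path)
    }
    n <- n + 1L
    rows[[n]] <- list(chrom = f[1L], start = start, end = end, score = sc)
  }
  rows <- rows[seq_len(n)]
  tr <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  class(tr) <- c("ScoreTrack", "data.frame")
  tr
}

#' Construct a ScoreTrack from vectors
#' @param chrom,start,end,score parallel vectors (0-based half-open).
#' @return a `ScoreTrack` data.frame.
#' @export
score_track <- function(chrom = character(0), start = integer(0),
                        end = integer(0), score = numeric(0)) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(score))
  if (any(start < 0L) || any(end <= start)) stop("bad track intervals")
  tr <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  class(tr) <- c("ScoreTrack", "data.frame")
  tr
}

#' Write peaks as BED6
#'
#' Coordinates are written as-is (internal coordinates are already the
#' 0-based half-open BED convention); the score column carries the total
#' read count capped at 1000 for genome-browser compatibility.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `strand` and
#'   optionally `total_count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write BED file: ", path))
  on.exit(close(con))
  if (nrow(peaks) > 0L) {
    ord <- order(peaks$chrom, peaks$start)
    peaks <- peaks[ord, , drop = FALSE]
    score <- if ("total_count" %in% names(peaks))
      pmin(peaks$total_count, 1000L) else 0L
    bed <- data.frame(peaks$chrom, peaks$start, peaks$end,
                      paste0("peak_", seq_len(nrow(peaks))), score,
                      peaks$strand)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED6 peak file written by [write_peaks_bed()]
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `total_count`.
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("cannot read BED file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      total_count = integer(0)))
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1L]], start = as.integer(bed[[2L]]),
             end = as.integer(bed[[3L]]), strand = bed[[6L]],
             total_count = as.integer(bed[[5L]]), stringsAsFactors = FALSE)
}
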