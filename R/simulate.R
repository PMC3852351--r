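#' Specify a synthetic CAGE world
#'
#' Collects everything the desk-scale generators need: chromosome
#' lengths, planted peaks with ground-truth TSS flags, a homogeneous
#' Poisson background rate (the peak caller's own null model, so
#' synthetic performance is an upper bound), external-track signal
#' levels around true TSSs, and asymmetric RNA-seq flank rates. Defaults
#' emulate the stated world of the method: concentrated read starts at
#' TSSs (narrow spread), broader recapping-like non-TSS clusters inside
#' "exons" with symmetric RNA-seq signal and no promoter motif.
#'
#' @param seed integer seed; every generator is deterministic given it.
#' @param chrom_lengths named integer vector.
#' @param peaks data.frame with `chrom`, `position`, `strand`,
#'   `read_count`, `spread`, `is_tss`.
#' @param background_rate expected background read starts per base per
#'   strand (default 0).
#' @param track_level external-track score over TSS neighbourhoods
#'   (default 10); elsewhere tracks are silent.
#' @param rnaseq_downstream_rate,rnaseq_upstream_rate expected RNA-seq
#'   read starts in the 100-base flanks downstream/upstream of a TSS peak
#'   (defaults 20 and 1); non-TSS peaks get the upstream rate on both
#'   sides.
#' @return a `SimulationSpec` list.
#' @export
simulation_spec <- function(seed, chrom_lengths, peaks,
                            background_rate = 0, track_level = 10,
                            rnaseq_downstream_rate = 20,
                            rnaseq_upstream_rate = 1) {
  stopifnot(all(c("chrom", "position", "strand", "read_count", "spread",
                  "is_tss") %in% names(peaks)))
  if (background_rate < 0 || rnaseq_downstream_rate < 0 ||
      rnaseq_upstream_rate < 0)
    stop("rates must be non-negative")
  bad <- peaks$position < 0 |
    peaks$position + peaks$spread > chrom_lengths[peaks$chrom]
  if (any(bad)) stop("planted peaks outside genome bounds")
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 peaks = peaks, background_rate = background_rate,
                 track_level = track_level,
                 rnaseq_downstream_rate = rnaseq_downstream_rate,
                 rnaseq_upstream_rate = rnaseq_upstream_rate),
            class = "SimulationSpec")
}

#' Simulate a random genome with promoter cassettes at planted TSSs
#'
#' Uniform-random ACGT sequence; upstream of each true-TSS planted peak a
#' fixed promoter cassette (TATA box plus GC boxes) is written into the
#' sequence in transcriptional orientation, so 4-mer features carry class
#' signal. Non-TSS peaks get no motif.
#'
#' @param spec a [simulation_spec()].
#' @param path optional FASTA output path.
#' @return a `DNAStringSet` (written to `path` when given).
#' @export
simulate_genome <- function(spec, path = NULL) {
  set.seed(spec$seed)
  cassette <- paste0("TATAAAAGGGGCGGGGCTATAAAAGGGGCGGGGC",
                     "CCGCCCATTATAAGGGCGGTATAAAAGGGGCGGG")  # 68 bases
  seqs <- lapply(names(spec$chrom_lengths), function(chrom) {
    len <- spec$chrom_lengths[[chrom]]
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    pk <- spec$peaks[spec$peaks$chrom == chrom & spec$peaks$is_tss, ,
                     drop = FALSE]
    cas <- strsplit(cassette, "")[[1L]]
    for (i in seq_len(nrow(pk))) {
      p <- pk$position[i]
      if (pk$strand[i] == "+") {
        at <- p - 100L  # cassette in [-100, -32) upstream of the cap
        if (at >= 0L) s[(at + 1L):(at + length(cas))] <- cas
      } else {
        cap5 <- p + pk$spread[i] - 1L
        rc <- rev(chartr("ACGT", "TGCA", cas))
        at <- cap5 + 100L - length(cas)  # mirrored upstream placement
        if (at + length(cas) <= len) s[(at + 1L):(at + length(cas))] <- rc
      }
    }
    paste(s, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(spec$chrom_lengths)
  if (!is.null(path)) Biostrings::writeXStringSet(genome, path)
  genome
}

#' Simulate a CAGE read-start profile with planted peaks
#'
#' Each planted peak contributes `read_count` read starts drawn within
#' its `spread` (a geometric-like decay from the planted position, so
#' peaks have a summit); the background contributes homogeneous
#' Poisson(`background_rate`) starts per base per strand.
#'
#' @param spec a [simulation_spec()].
#' @return list with `profile` (a [read_start_profile()]) and `truth`
#'   (data.frame of planted spans with `is_tss` flags).
#' @export
simulate_cage_profile <- function(spec) {
  pk <- spec$peaks
  key <- paste(pk$chrom, pk$strand)
  for (kk in unique(key)) {
    sub <- pk[key == kk, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    if (nrow(sub) > 1L &&
        any(sub$position[-1L] <
            sub$position[-nrow(sub)] + sub$spread[-nrow(sub)]))
      stop("overlapping planted peaks on one strand: truth ambiguous")
  }
  set.seed(spec$seed + 1L)
  prof <- read_start_profile(spec$chrom_lengths)
  for (i in seq_len(nrow(pk))) {
    off <- if (pk$spread[i] == 1L) rep(0L, pk$read_count[i])
    else sample(0:(pk$spread[i] - 1L), pk$read_count[i], replace = TRUE,
                prob = 0.6^(0:(pk$spread[i] - 1L)))
    prof <- profile_add(prof, pk$chrom[i], pk$strand[i],
                        pk$position[i] + off)
  }
  if (spec$background_rate > 0) {
    for (chrom in names(spec$chrom_lengths)) {
      len <- spec$chrom_lengths[[chrom]]
      for (strand in c("+", "-")) {
        n <- stats::rpois(1L, len * spec$background_rate)
        if (n > 0L)
          prof <- profile_add(prof, chrom, strand,
                              sample.int(len, n, replace = TRUE) - 1L)
      }
    }
  }
  truth <- data.frame(chrom = pk$chrom, start = pk$position,
                      end = pk$position + pk$spread, strand = pk$strand,
                      is_tss = pk$is_tss, stringsAsFactors = FALSE)
  list(profile = prof, truth = truth)
}

#' Simulate external score tracks and an RNA-seq profile
#'
#' TFBS/DNase/H3K4me3 tracks receive `track_level` scores over
#' `[start - 100, end + 100)` of each true-TSS planted peak and are
#' silent elsewhere. Conservation covers TSS peaks with elevated scores
#' and leaves non-TSS peaks uncovered (exercising the imputation path).
#' The RNA-seq profile puts Poisson mass at the downstream rate 3' of
#' each TSS peak and the upstream rate 5'; non-TSS peaks get symmetric
#' upstream-rate flanks.
#'
#' @param spec a [simulation_spec()].
#' @param truth truth data.frame from [simulate_cage_profile()].
#' @return list with `tracks` (named list of `ScoreTrack`s: `tfbs`,
#'   `dnase`, `h3k4me3`, `conservation`) and `rnaseq`
#'   (a [read_start_profile()]).
#' @export
simulate_external_tracks <- function(spec, truth) {
  set.seed(spec$seed + 2L)
  tss <- truth[truth$is_tss, , drop = FALSE]
  mk <- function(level) {
    if (nrow(tss) == 0L) return(score_track())
    score_track(tss$chrom, pmax(tss$start - 100L, 0L),
                pmin(tss$end + 100L, spec$chrom_lengths[tss$chrom]),
                rep(level, nrow(tss)))
  }
  tracks <- list(tfbs = mk(spec$track_level), dnase = mk(spec$track_level),
                 h3k4me3 = mk(spec$track_level),
                 conservation = if (nrow(tss) == 0L) score_track() else
                   score_track(tss$chrom, tss$start, tss$end,
                               stats::runif(nrow(tss), 1, 3)))
  rnaseq <- read_start_profile(spec$chrom_lengths)
  scatter <- function(prof, chrom, strand, lo, hi, rate) {
    lo <- max(lo, 0L); hi <- min(hi, spec$chrom_lengths[[chrom]])
    if (hi <= lo) return(prof)
    n <- stats::rpois(1L, rate)
    if (n == 0L) return(prof)
    profile_add(prof, chrom, strand,
                sample(lo:(hi - 1L), n, replace = TRUE))
  }
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    down_rate <- if (r$is_tss) spec$rnaseq_downstream_rate
    else spec$rnaseq_upstream_rate
    up_rate <- spec$rnaseq_upstream_rate
    if (r$strand == "+") {
      rnaseq <- scatter(rnaseq, r$chrom, "+", r$end, r$end + 100L,
                        down_rate)
      rnaseq <- scatter(rnaseq, r$chrom, "+", r$start - 100L, r$start,
                        up_rate)
    } else {
      rnaseq <- scatter(rnaseq, r$chrom, "-", r$start - 100L, r$start,
                        down_rate)
      rnaseq <- scatter(rnaseq, r$chrom, "-", r$end, r$end + 100L,
                        up_rate)
    }
  }
  list(tracks = tracks, rnaseq = rnaseq)
}

#' Simulate a transcript annotation matching the planted truth
#'
#' One transcript per true-TSS planted peak, with its annotated 5' end at
#' the planted cap position, so labelling perfectly recovered peaks
#' against this annotation reproduces the `is_tss` flags.
#'
#' @param truth truth data.frame from [simulate_cage_profile()].
#' @param chrom_lengths named integer vector (bounds the transcript body).
#' @param path optional GTF output path.
#' @return a `GRanges` of transcript records (written when `path` given).
#' @export
simulate_annotation <- function(truth, chrom_lengths, path = NULL) {
  tss <- truth[truth$is_tss, , drop = FALSE]
  if (nrow(tss) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    # 5' end at the cap-proximal edge of the planted span
    start0 <- ifelse(tss$strand == "+", tss$start,
                     pmax(tss$end - 1L - 1000L, 0L))
    end0 <- ifelse(tss$strand == "+",
                   pmin(tss$start + 1000L, chrom_lengths[tss$chrom]),
                   tss$end)
    gr <- GenomicRanges::GRanges(
      seqnames = tss$chrom,
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      strand = tss$strand)
    S4Vectors::mcols(gr)$type <- "transcript"
    S4Vectors::mcols(gr)$source <- "cagepeakr_sim"
    S4Vectors::mcols(gr)$gene_id <- paste0("gene_", seq_len(nrow(tss)))
    S4Vectors::mcols(gr)$transcript_id <- paste0("tx_", seq_len(nrow(tss)))
  }
  if (!is.null(path)) rtracklayer::export(gr, path, format = "gtf")
  gr
}

#' Write a read-start profile as a SAM file
#'
#' Expands a profile into one 27M-aligned record per read start (the 5'
#' end of a reverse read is its rightmost aligned base, so minus-strand
#' alignments are placed to end at the stored position). Reads whose
#' alignment span would leave the chromosome are shifted to stay inside;
#' their 5' position is preserved.
#'
#' @param profile a [read_start_profile()].
#' @param path output SAM path.
#' @param read_length aligned read length (default 27).
#' @param mapq mapping quality written on every record (default 30).
#' @return `path`, invisibly.
#' @export
write_profile_sam <- function(profile, path, read_length = 27L,
                              mapq = 30L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (chrom in names(profile$chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom,
                       profile$chrom_lengths[[chrom]]), con)
  ridx <- 0L
  for (key in names(profile$counts)) {
    parts <- strsplit(key, "\t", fixed = TRUE)[[1L]]
    chrom <- parts[1L]; strand <- parts[2L]
    len <- profile$chrom_lengths[[chrom]]
    e <- profile$counts[[key]]
    starts5 <- rep(e$pos, e$count)
    for (p in starts5) {
      ridx <- ridx + 1L
      if (strand == "+") {
        left0 <- min(p, len - read_length)
        flag <- 0L
      } else {
        left0 <- max(p - read_length + 1L, 0L)
        flag <- 16L
      }
      writeLines(sprintf(
        "read%d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
        ridx, flag, chrom, left0 + 1L, mapq, read_length,
        strrep("A", read_length)), con)
    }
  }
  invisible(path)
}

#' Simulate one complete synthetic cell line
#'
#' Convenience wrapper producing all inputs of the full pipeline for one
#' cell line from a single spec: genome, CAGE profile with truth,
#' external tracks, RNA-seq profile and annotation.
#'
#' @param spec a [simulation_spec()].
#' @return list with `genome`, `profile`, `truth`, `tracks`, `rnaseq`,
#'   `annotation` (GRanges) and `transcript_starts` (data.frame).
#' @export
simulate_cell_line <- function(spec) {
  genome <- simulate_genome(spec)
  sim <- simulate_cage_profile(spec)
  ext <- simulate_external_tracks(spec, sim$truth)
  ann <- simulate_annotation(sim$truth, spec$chrom_lengths)
  ts <- if (length(ann) == 0L)
    data.frame(chrom = character(0), position = integer(0),
               strand = character(0))
  else {
    strand <- as.character(BiocGenerics::strand(ann))
    data.frame(chrom = as.character(GenomicRanges::seqnames(ann)),
               position = as.integer(ifelse(strand == "+",
                                            BiocGenerics::start(ann) - 1L,
                                            BiocGenerics::end(ann) - 1L)),
               strand = strand, stringsAsFactors = FALSE)
  }
  list(genome = genome, profile = sim$profile, truth = sim$truth,
       tracks = ext$tracks, rnaseq = ext$rnaseq, annotation = ann,
       transcript_starts = ts)
}

#' Random planted-peak layout for a synthetic cell line
#'
#' Places `n_tss` narrow TSS peaks and `n_non` broader non-TSS peaks at
#' well-separated random positions on alternating strands.
#'
#' @param seed integer seed.
#' @param chrom_length chromosome length (single chromosome `"chrS"`).
#' @param n_tss,n_non peak counts per class.
#' @param tss_reads,non_reads read counts per planted peak.
#' @param tss_spread,non_spread planted spreads in bases.
#' @return data.frame suitable for [simulation_spec()].
#' @export
random_peak_layout <- function(seed, chrom_length = 200000L, n_tss = 20L,
                               n_non = 20L, tss_reads = 60L,
                               non_reads = 40L, tss_spread = 3L,
                               non_spread = 25L) {
  set.seed(seed)
  n <- n_tss + n_non
  slot_w <- chrom_length %/% (n + 2L)
  if (slot_w < 2000L) stop("chromosome too short for requested layout")
  pos <- (seq_len(n)) * slot_w + sample.int(200L, n, replace = TRUE)
  idx <- sample.int(n)  # shuffle class assignment over slots
  is_tss <- rep(c(TRUE, FALSE), c(n_tss, n_non))[order(idx)]
  data.frame(
    chrom = "chrS", position = as.integer(pos),
    strand = sample(c("+", "-"), n, replace = TRUE),
    read_count = ifelse(is_tss, tss_reads, non_reads),
    spread = ifelse(is_tss, tss_spread, non_spread),
    is_tss = is_tss, stringsAsFactors = FALSE)
}
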