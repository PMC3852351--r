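#' Assemble and validate a pipeline run configuration
#'
#' Inputs may be file paths (SAM/BAM, FASTA, GTF, track files) or
#' in-memory objects (profiles, `DNAStringSet`, `ScoreTrack`s), so the
#' same orchestration serves both the command line and programmatic use.
#' Defaults are the published parameters throughout.
#'
#' @param cell_lines named list; each element a list with `cage` (SAM/BAM
#'   path or [read_start_profile()]) and optional `rnaseq` (same types).
#' @param genome FASTA path or `DNAStringSet`; required for 4-mers.
#' @param annotation GTF path, `GRanges`, or transcript-start data.frame.
#' @param tracks named list (`tfbs`, `dnase`, `h3k4me3`, `conservation`)
#'   of track paths or `ScoreTrack`s.
#' @param params a [peak_params()].
#' @param scenario `"internal"`, `"pooled"` or `"rnaseq"`.
#' @param threshold feature-selection |rho| cutoff.
#' @param cost_grid SVM cost values for [loocv()].
#' @param seed integer seed stamped into the manifest.
#' @param outdir output directory.
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(cell_lines, genome, annotation, tracks = list(),
                       params = peak_params(),
                       scenario = c("internal", "pooled", "rnaseq"),
                       threshold = 0.5, cost_grid = 10^seq(-6, 2),
                       seed = 1L, outdir = tempfile("cagepeakr_run_")) {
  scenario <- match.arg(scenario)
  if (length(cell_lines) < 1L || is.null(names(cell_lines)))
    stop("cell_lines must be a named list")
  for (nm in names(cell_lines)) {
    cl <- cell_lines[[nm]]
    if (is.null(cl$cage)) stop("cell line ", nm, " lacks a cage input")
    if (is.character(cl$cage) && !file.exists(cl$cage))
      stop("cage input for ", nm, " not found: ", cl$cage)
    if (scenario == "rnaseq" && is.null(cl$rnaseq))
      stop("scenario 'rnaseq' requires an rnaseq input for ", nm)
  }
  if (scenario == "pooled" &&
      !all(c("tfbs", "dnase", "h3k4me3") %in% names(tracks)))
    stop("scenario 'pooled' requires tfbs, dnase and h3k4me3 tracks")
  for (tn in names(tracks))
    if (is.character(tracks[[tn]]) && !file.exists(tracks[[tn]]))
      stop("track ", tn, " not found: ", tracks[[tn]])
  structure(list(cell_lines = cell_lines, genome = genome,
                 annotation = annotation, tracks = tracks,
                 params = params, scenario = scenario,
                 threshold = threshold, cost_grid = cost_grid,
                 seed = as.integer(seed), outdir = outdir),
            class = "RunConfig")
}

resolve_profile <- function(x, mapq_min) {
  if (inherits(x, "ReadStartProfile")) x else load_read_starts(x, mapq_min)
}

resolve_genome <- function(x) {
  if (is.null(x) || inherits(x, "DNAStringSet")) x
  else Biostrings::readDNAStringSet(x)
}

resolve_track <- function(x) {
  if (inherits(x, "ScoreTrack")) x else load_score_track(x)
}

resolve_transcript_starts <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "GRanges")) {
    strand <- as.character(BiocGenerics::strand(x))
    return(data.frame(
      chrom = as.character(GenomicRanges::seqnames(x)),
      position = as.integer(ifelse(strand == "+",
                                   BiocGenerics::start(x) - 1L,
                                   BiocGenerics::end(x) - 1L)),
      strand = strand, stringsAsFactors = FALSE))
  }
  load_transcript_starts(x)
}

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(
    config[setdiff(names(config), "outdir")], vec.len = 1e6)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full two-stage pipeline
#'
#' Stages, in order, each halting the run with a stage-named error on
#' failure: peak calling per cell line (BED per line), feature
#' extraction (TSV per line), pooled standardisation and PC1 feature
#' selection (JSON), annotation labelling, scenario rescaling, and
#' leave-one-cell-line-out SVM evaluation over the cost grid (TSV).
#' A manifest with the config hash and seed is written alongside;
#' rerunning an identical config reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return list with `peaks`, `features` (per cell line), `selection`,
#'   `evaluation` and `outdir`, invisibly mirroring the files on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)

  genome <- stage("load_genome", resolve_genome(config$genome))
  tracks <- stage("load_tracks",
                  lapply(config$tracks, resolve_track))
  ts <- stage("load_annotation",
              resolve_transcript_starts(config$annotation))

  peaks <- list(); features <- list()
  for (nm in names(config$cell_lines)) {
    cl <- config$cell_lines[[nm]]
    prof <- stage(paste0("load_cage[", nm, "]"),
                  resolve_profile(cl$cage, config$params$mapq_min))
    pk <- stage(paste0("callpeaks[", nm, "]"),
                call_peaks(prof, config$params))
    logf("callpeaks ", nm, ": ", nrow(pk), " peaks")
    write_peaks_bed(pk, file.path(config$outdir,
                                  paste0(nm, "_peaks.bed")))
    rnaseq <- if (!is.null(cl$rnaseq))
      stage(paste0("load_rnaseq[", nm, "]"),
            resolve_profile(cl$rnaseq, config$params$mapq_min)) else NULL
    fm <- stage(paste0("features[", nm, "]"),
                build_feature_matrix(pk, prof, genome = genome,
                                     tracks = tracks,
                                     rnaseq_profile = rnaseq,
                                     cell_line = nm))
    fm <- stage(paste0("labels[", nm, "]"), {
      lb <- label_peaks(pk, ts)
      fm$label <- lb$label
      fm
    })
    logf("labels ", nm, ": ", sum(fm$label == "TSS"), " TSS / ",
         sum(fm$label == "nonTSS"), " nonTSS")
    utils::write.table(fm, file.path(config$outdir,
                                     paste0(nm, "_features.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    peaks[[nm]] <- pk; features[[nm]] <- fm
  }

  pooled <- do.call(rbind, features)
  pooled_std <- stage("standardize", standardize_features(pooled))
  selection <- stage("select",
                     run_feature_selection(pooled_std, config$threshold))
  logf("select: ", length(selection$singles$selected), " single / ",
       length(selection$kmers$selected), " 4-mer features")
  jsonlite::write_json(
    list(singles = as.list(selection$singles$feature_correlations),
         kmers = as.list(selection$kmers$feature_correlations),
         selected_singles = selection$singles$selected,
         selected_kmers = selection$kmers$selected,
         threshold = config$threshold),
    file.path(config$outdir, "selection.json"), auto_unbox = TRUE,
    digits = NA)

  scen <- stage("rescale",
                rescale_for_scenario(pooled_std, selection,
                                     config$scenario))
  datasets <- lapply(split(scen, scen$cell_line), function(d)
    list(x = as.matrix(d[, feature_columns(scen), drop = FALSE]),
         y = d$label))
  evaluation <- stage("classify", loocv(datasets, config$cost_grid))
  for (i in seq_len(nrow(evaluation$folds)))
    logf("fold cell_line=", evaluation$folds$cell_line[i], " cost=",
         format(evaluation$folds$cost[i]), " precision=",
         format(evaluation$folds$precision[i]), " recall=",
         format(evaluation$folds$recall[i]))
  utils::write.table(evaluation$folds,
                     file.path(config$outdir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(
    list(config_md5 = config_digest(config), seed = config$seed,
         scenario = config$scenario,
         cell_lines = names(config$cell_lines),
         n_peaks = lapply(peaks, nrow)),
    file.path(config$outdir, "manifest.json"), auto_unbox = TRUE)
  invisible(list(peaks = peaks, features = features,
                 selection = selection, evaluation = evaluation,
                 outdir = config$outdir))
}
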