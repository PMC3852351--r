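#' Label peaks by annotation overlap
#'
#' A 2 x `half_window` labelling region is centred on each annotated
#' transcript 5' start; any peak whose interval intersects any region is a
#' TSS peak, all others are non-TSS. Strand is ignored unless
#' `stranded = TRUE`.
#'
#' @param peaks data.frame of peaks (`chrom`, `start`, `end`, `strand`).
#' @param transcript_starts data.frame from [load_transcript_starts()].
#' @param half_window half-width of the labelling region (default 500).
#' @param stranded require matching strand for a label.
#' @return `peaks` with an added `label` column (`"TSS"` / `"nonTSS"`).
#' @export
label_peaks <- function(peaks, transcript_starts, half_window = 500L,
                        stranded = FALSE) {
  if (half_window < 0L) stop("half_window must be >= 0")
  lab <- rep("nonTSS", nrow(peaks))
  if (nrow(transcript_starts) > 0L && nrow(peaks) > 0L) {
    for (i in seq_len(nrow(peaks))) {
      ts <- transcript_starts[transcript_starts$chrom == peaks$chrom[i], ,
                              drop = FALSE]
      if (stranded)
        ts <- ts[ts$strand == peaks$strand[i], , drop = FALSE]
      if (nrow(ts) == 0L) next
      # region [p - hw, p + hw) vs peak [start, end): any overlap
      if (any(ts$position - half_window < peaks$end[i] &
              ts$position + half_window > peaks$start[i]))
        lab[i] <- "TSS"
    }
  }
  peaks$label <- lab
  peaks
}

#' Class weights for imbalanced TSS classification
#'
#' The TSS class weight is the non-TSS count divided by the TSS count; the
#' non-TSS weight is 1.
#'
#' @param labels character vector of `"TSS"` / `"nonTSS"`.
#' @return named numeric vector `c(TSS = ..., nonTSS = 1)`.
#' @export
class_weights <- function(labels) {
  n_tss <- sum(labels == "TSS")
  n_non <- sum(labels == "nonTSS")
  if (n_tss == 0L || n_non == 0L)
    stop("both classes must be present to compute weights")
  c(TSS = n_non / n_tss, nonTSS = 1)
}

#' Rescale standardised features for a classification scenario
#'
#' With m selected 4-mers (each in [0, 1]), blocks are rescaled so they
#' carry equal total weight in the linear SVM: kurtosis to [0, m]; in the
#' pooled-external scenario each of TFBS/DNase/H3K4me3 to [0, 2m/3]; in
#' the RNA-seq scenario the RNA-seq difference to [0, 2m]. The feature
#' matrix must already be standardised to [0, 1].
#'
#' @param fm a standardised feature matrix.
#' @param selection result of [run_feature_selection()].
#' @param scenario `"internal"`, `"pooled"` or `"rnaseq"`.
#' @return feature matrix restricted to meta columns plus the scenario's
#'   (rescaled) features.
#' @export
rescale_for_scenario <- function(fm, selection,
                                 scenario = c("internal", "pooled",
                                              "rnaseq")) {
  scenario <- match.arg(scenario)
  m <- length(selection$kmers$selected)
  if (m == 0L) stop("no 4-mers selected; refusing to build a scenario")
  if (!"kurtosis" %in% names(fm)) stop("scenario requires kurtosis")
  keep <- c("kurtosis", selection$kmers$selected)
  fm$kurtosis <- fm$kurtosis * m
  if (scenario == "pooled") {
    ext <- c("tfbs", "dnase", "h3k4me3")
    missing_ext <- setdiff(ext, names(fm))
    if (length(missing_ext))
      stop("pooled scenario requires feature(s): ",
           paste(missing_ext, collapse = ", "))
    for (cn in ext) fm[[cn]] <- fm[[cn]] * (2 * m / 3)
    keep <- c(keep, ext)
  } else if (scenario == "rnaseq") {
    if (!"rnaseq_diff" %in% names(fm))
      stop("rnaseq scenario requires feature: rnaseq_diff")
    fm$rnaseq_diff <- fm$rnaseq_diff * (2 * m)
    keep <- c(keep, "rnaseq_diff")
  }
  meta <- intersect(c("peak_id", "cell_line", "chrom", "start", "end",
                      "strand", "label"), names(fm))
  fm[, c(meta, keep), drop = FALSE]
}

# primal objective and gradient of the class-weighted L2-regularised
# squared-hinge linear SVM; par = c(w, b), bias unregularised
svm_objective <- function(par, x, y, cost, cw) {
  d <- ncol(x)
  w <- par[seq_len(d)]; b <- par[d + 1L]
  margin <- 1 - y * (drop(x %*% w) + b)
  viol <- pmax(margin, 0)
  0.5 * sum(w^2) + cost * sum(cw * viol^2)
}

svm_gradient <- function(par, x, y, cost, cw) {
  d <- ncol(x)
  w <- par[seq_len(d)]; b <- par[d + 1L]
  margin <- 1 - y * (drop(x %*% w) + b)
  active <- margin > 0
  coef <- numeric(length(y))
  coef[active] <- -2 * cost * cw[active] * margin[active] * y[active]
  c(w + drop(crossprod(x, coef)), sum(coef))
}

#' Train a class-weighted L2-regularised squared-hinge linear SVM
#'
#' Solves the primal problem
#' `min_w,b 0.5 ||w||^2 + C * sum_i weight(y_i) max(0, 1 - y_i (w.x_i + b))^2`
#' by BFGS on the smooth objective (the squared hinge is continuously
#' differentiable), with an unregularised bias. Deterministic: the solver
#' always starts from the zero vector.
#'
#' @param x numeric feature matrix (rows = peaks).
#' @param y labels, `"TSS"` (positive class) / `"nonTSS"`.
#' @param cost the SVM cost parameter C (> 0).
#' @param weights named per-class error weights, e.g. from
#'   [class_weights()]; default 1 for both classes.
#' @return a `linear_svm` model (weight vector `w`, bias `b`).
#' @export
train_svm <- function(x, y, cost = 1, weights = c(TSS = 1, nonTSS = 1)) {
  x <- as.matrix(x)
  if (cost <= 0) stop("cost must be > 0")
  if (length(unique(y)) < 2L) stop("need both classes to train")
  yy <- ifelse(y == "TSS", 1, -1)
  cw <- unname(weights[y])
  if (any(is.na(cw)) || any(cw <= 0)) stop("invalid class weights")
  fit <- stats::optim(rep(0, ncol(x) + 1L), fn = svm_objective,
                      gr = svm_gradient, x = x, y = yy, cost = cost,
                      cw = cw, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  structure(list(w = stats::setNames(fit$par[seq_len(ncol(x))],
                                     colnames(x)),
                 b = fit$par[ncol(x) + 1L], cost = cost,
                 weights = weights, value = fit$value,
                 convergence = fit$convergence),
            class = "linear_svm")
}

#' Predict with a linear SVM
#' @param object a `linear_svm` from [train_svm()].
#' @param x feature matrix with the training columns.
#' @param decision return raw decision values instead of labels.
#' @param ... unused.
#' @return labels (`"TSS"`/`"nonTSS"`) or decision values.
#' @export
predict.linear_svm <- function(object, x, decision = FALSE, ...) {
  x <- as.matrix(x)
  if (!is.null(names(object$w)) && !is.null(colnames(x)))
    x <- x[, names(object$w), drop = FALSE]
  f <- drop(x %*% object$w) + object$b
  if (decision) f else ifelse(f > 0, "TSS", "nonTSS")
}

#' Precision and recall with TSS as the positive class
#'
#' Precision is TP / (TP + FP), recall TP / (TP + FN). A zero denominator
#' yields `NA`, never a silent 0.
#'
#' @param predictions,labels equal-length vectors of `"TSS"`/`"nonTSS"`.
#' @return named numeric vector `c(precision = ..., recall = ...)`.
#' @export
precision_recall <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  tp <- sum(predictions == "TSS" & labels == "TSS")
  fp <- sum(predictions == "TSS" & labels == "nonTSS")
  fn <- sum(predictions == "nonTSS" & labels == "TSS")
  c(precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
}

#' Leave-one-cell-line-out cross-validation over a cost grid
#'
#' For each cost and each held-out cell line, an SVM is trained on the
#' pooled peaks of the remaining lines (class weights computed on the
#' training pool only) and evaluated on the held-out line. Folds whose
#' training pool lacks a class are skipped with a warning.
#'
#' @param datasets named list, one entry per cell line, each a list with
#'   feature matrix `x` and label vector `y`.
#' @param cost_grid numeric vector of SVM cost values; default powers of
#'   10 from 1e-6 to 1e2.
#' @return list with `folds` (data.frame `cell_line`, `cost`, `precision`,
#'   `recall`) and `summary` (per-cost min/mean/max of both metrics).
#' @export
loocv <- function(datasets, cost_grid = 10^seq(-6, 2)) {
  if (length(datasets) < 2L) stop("need at least 2 cell lines")
  lines <- names(datasets)
  folds <- list()
  for (cost in cost_grid) {
    for (held in lines) {
      train_x <- do.call(rbind, lapply(setdiff(lines, held),
                                       function(l) datasets[[l]]$x))
      train_y <- unlist(lapply(setdiff(lines, held),
                               function(l) datasets[[l]]$y),
                        use.names = FALSE)
      if (length(unique(train_y)) < 2L) {
        warning("fold ", held, ": training pool lacks a class; skipped")
        next
      }
      model <- train_svm(train_x, train_y, cost = cost,
                         weights = class_weights(train_y))
      pr <- precision_recall(predict(model, datasets[[held]]$x),
                             datasets[[held]]$y)
      folds[[length(folds) + 1L]] <- data.frame(
        cell_line = held, cost = cost, precision = pr[["precision"]],
        recall = pr[["recall"]], stringsAsFactors = FALSE)
    }
  }
  folds <- do.call(rbind, folds)
  summary <- do.call(rbind, lapply(split(folds, folds$cost), function(f)
    data.frame(cost = f$cost[1L],
               precision_min = min(f$precision),
               precision_mean = mean(f$precision),
               precision_max = max(f$precision),
               recall_min = min(f$recall),
               recall_mean = mean(f$recall),
               recall_max = max(f$recall))))
  rownames(summary) <- NULL
  list(folds = folds, summary = summary[order(summary$cost), ])
}
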