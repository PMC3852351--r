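#' Standardise features to [0, 1] per cell line
#'
#' Each feature column is divided by its maximum within each cell line, so
#' the per-cell-line maximum becomes exactly 1. Columns whose maximum is
#' not positive are passed through unchanged with a warning.
#'
#' @param fm a feature matrix from [build_feature_matrix()].
#' @param cols columns to standardise; defaults to all feature columns.
#' @return the standardised feature matrix.
#' @export
standardize_features <- function(fm, cols = feature_columns(fm)) {
  for (cl in unique(fm$cell_line)) {
    sel <- fm$cell_line == cl
    for (cn in cols) {
      mx <- max(fm[[cn]][sel])
      if (is.na(mx) || mx <= 0) {
        if (!is.na(mx) && any(fm[[cn]][sel] != 0))
          warning("feature ", cn, " in ", cl,
                  " has non-positive maximum; left unscaled")
        else if (all(fm[[cn]][sel] == 0))
          warning("feature ", cn, " all zero in ", cl, "; left unscaled")
        next
      }
      fm[[cn]][sel] <- fm[[cn]][sel] / mx
    }
  }
  fm
}

#' Correlation of features with the first principal component
#'
#' Principal components are computed on the mean-centred (but not
#' rescaled) standardised matrix, pooling all cell lines. The default
#' correlation is the conventional variable-component correlation,
#' loading x sqrt(eigenvalue) / feature sd, which is bounded by 1 and
#' therefore commensurable with a 0.5 cutoff. `mode = "paper"` computes
#' loading x eigenvalue literally instead; note this quantity is the
#' covariance of the variable with PC1 (scale-dependent, typically far
#' below 0.5 on [0, 1]-standardised data), so with the default cutoff
#' it usually selects nothing. The sign of PC1 is fixed so the
#' largest-magnitude loading is negative (sign never affects selection,
#' which uses |rho|).
#'
#' @param fm a standardised feature matrix.
#' @param cols feature columns to include in the PCA block.
#' @param mode `"textbook"` (default) or `"paper"`.
#' @return named numeric vector of per-feature correlations rho.
#' @export
pca_feature_correlations <- function(fm, cols = feature_columns(fm),
                                     mode = c("textbook", "paper")) {
  mode <- match.arg(mode)
  x <- as.matrix(fm[, cols, drop = FALSE])
  if (nrow(x) < 3L || ncol(x) < 2L)
    stop("PCA needs at least 3 rows and 2 features")
  if (all(apply(x, 2L, stats::var) == 0))
    stop("constant feature matrix: no variance to decompose")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  loading <- pc$rotation[, 1L]
  if (loading[which.max(abs(loading))] > 0) loading <- -loading
  lambda1 <- pc$sdev[1L]^2
  rho <- if (mode == "paper") loading * lambda1
  else {
    sds <- apply(x, 2L, stats::sd)
    out <- loading * pc$sdev[1L] / sds
    out[sds == 0] <- 0
    out
  }
  stats::setNames(as.numeric(rho), cols)
}

#' Select features correlated with PC1
#'
#' @param correlations named vector from [pca_feature_correlations()].
#' @param threshold |rho| cutoff in (0, 1] (default 0.5).
#' @return a `SelectionResult`: list with `feature_correlations`,
#'   `selected` (names with |rho| >= threshold, by decreasing |rho|) and
#'   `threshold`.
#' @export
select_features <- function(correlations, threshold = 0.5) {
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  keep <- names(correlations)[abs(correlations) >= threshold]
  keep <- keep[order(-abs(correlations[keep]))]
  structure(list(feature_correlations = correlations, selected = keep,
                 threshold = threshold), class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("SelectionResult:", length(x$selected), "of",
      length(x$feature_correlations), "features with |rho| >=",
      x$threshold, "\n")
  invisible(x)
}

#' Run the two-block PC1 feature selection
#'
#' The single features (kurtosis, read density and whichever external
#' single features are present) and the 4-mer block are selected in two
#' independent PCA runs, as the combinatorial 4-mer block would otherwise
#' dominate the pooled variance.
#'
#' @param fm a standardised feature matrix pooled over all cell lines.
#' @param threshold |rho| cutoff (default 0.5).
#' @param mode correlation mode, see [pca_feature_correlations()].
#' @return list with `SelectionResult`s `singles` and `kmers`.
#' @export
run_feature_selection <- function(fm, threshold = 0.5,
                                  mode = c("textbook", "paper")) {
  mode <- match.arg(mode)
  cols <- feature_columns(fm)
  kmer_cols <- grep("^(up|down)_[ACGT]+$", cols, value = TRUE)
  single_cols <- setdiff(cols, c(kmer_cols, "rnaseq_diff"))
  singles <- if (length(single_cols) >= 2L)
    select_features(pca_feature_correlations(fm, single_cols, mode),
                    threshold)
  else structure(list(feature_correlations = stats::setNames(
    numeric(0), character(0)), selected = single_cols,
    threshold = threshold), class = "SelectionResult")
  kmers <- if (length(kmer_cols) >= 2L)
    select_features(pca_feature_correlations(fm, kmer_cols, mode),
                    threshold)
  else structure(list(feature_correlations = stats::setNames(
    numeric(0), character(0)), selected = kmer_cols,
    threshold = threshold), class = "SelectionResult")
  list(singles = singles, kmers = kmers)
}
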