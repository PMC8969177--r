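#' Assemble the 7-feature classification matrix
#'
#' Builds the observation-by-feature matrix used for PCA classification.
#' The seven features, in fixed column order, are: mean firing rate by
#' active electrodes, burst rate per minute, mean burst duration (s), mean
#' spike frequency in bursts (spikes / burst duration), mean spikes per
#' burst, percentage of spikes in bursts, and the well-mean STTC. The number
#' of active electrodes is deliberately not a feature (it only serves to
#' compute the others). Observations missing any feature are dropped with a
#' message; their count is recorded in the `n_dropped` attribute.
#'
#' @param stats_table Data frame with one row per well/timepoint, containing
#'   the seven feature columns (named as in [well_stats()]) plus any label
#'   columns (`well`, `div`, `group`, ...).
#' @return Numeric matrix (observations x 7) with attribute `labels` (the
#'   label columns of the retained rows) and `n_dropped`.
#' @export
assemble_features <- function(stats_table) {
  missing_cols <- setdiff(PCA_FEATURES, names(stats_table))
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(stats_table[, PCA_FEATURES, drop = FALSE])
  storage.mode(m) <- "double"
  complete <- rowSums(is.na(m)) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message(n_dropped, " observation(s) dropped: incomplete feature vector")
  }
  if (!any(complete)) stop("no complete observations to assemble")
  out <- m[complete, , drop = FALSE]
  labels <- stats_table[complete, setdiff(names(stats_table), PCA_FEATURES),
                        drop = FALSE]
  attr(out, "labels") <- labels
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Standard-score normalization
#'
#' Centers each column to mean 0 and scales to sample SD 1 (n - 1
#' denominator). All observations entering one PCA are pooled into a single
#' normalization.
#'
#' @param m Numeric matrix with >= 2 rows.
#' @return Normalized matrix; attributes `center` and `scale` hold the
#'   column means and SDs.
#' @export
zscore <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("zscore needs at least 2 observations")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  zero <- which(s == 0)
  if (length(zero)) {
    nm <- colnames(m)[zero]
    if (is.null(nm)) nm <- zero
    stop("zero-variance feature(s): ", paste(nm, collapse = ", "))
  }
  out <- sweep(sweep(m, 2, mu), 2, s, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- s
  out
}

#' Principal component analysis for well classification
#'
#' PCA of the (z-scored) feature matrix via singular value decomposition:
#' scores are the projections onto the top right-singular vectors, explained
#' variance fractions come from the singular values, and each loading
#' column's sign is fixed so that its largest-magnitude entry is positive
#' (preventing run-to-run mirror flips). Three components are retained by
#' default for 3-D classification plots.
#'
#' @param m Normalized feature matrix (observations >= `n_components`).
#' @param n_components Number of components to keep (default 3).
#' @return Object of class `mea_pca` with elements `scores`
#'   (obs x n_components), `loadings` (features x n_components),
#'   `explained` (variance fractions, all components), `labels`.
#' @export
mea_pca <- function(m, n_components = 3L) {
  m <- as.matrix(unclass(m))
  labels <- attr(m, "labels")
  if (nrow(m) < n_components) {
    stop("need at least ", n_components, " observations for ", n_components,
         " components")
  }
  mc <- sweep(m, 2, colMeans(m))
  sv <- svd(mc)
  explained <- sv$d^2 / sum(sv$d^2)
  k <- min(n_components, length(sv$d))
  v <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|entry| of each loading column is positive
  for (j in seq_len(k)) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  scores <- mc %*% v
  rownames(v) <- colnames(m)
  colnames(v) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = v, explained = explained,
                 labels = labels, n_components = k),
            class = "mea_pca")
}

#' @export
print.mea_pca <- function(x, ...) {
  cat("mea_pca: ", nrow(x$scores), " observations, ", x$n_components,
      " components\n", sep = "")
  ev <- x$explained[seq_len(x$n_components)]
  cat("  explained variance: ",
      paste(sprintf("%s %.1f%%", colnames(x$scores), 100 * ev), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
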