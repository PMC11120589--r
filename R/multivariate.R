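#' Pearson correlation matrix with p-values
#'
#' Product-moment correlations between response columns over the runs,
#' with two-sided p-values from the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' p-values are unadjusted. Constant columns yield `NA` correlations for
#' their pairs, with a warning.
#'
#' @param table an `od_design` table (or data frame).
#' @param columns response columns to correlate; defaults to all 13.
#' @return List of class `"od_correlation"`: `r` and `p` matrices and
#'   the sample count `n`.
#' @examples
#' ct <- pearson_matrix(load_design_table("table1"))
#' ct$r["DMC", "Ca"]
#' @export
pearson_matrix <- function(table, columns = od_response_names()) {
  missing <- setdiff(columns, names(table))
  if (length(missing) > 0L) {
    stop("unknown column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(table)[, columns])
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 runs for correlation p-values")
  const <- columns[apply(X, 2L, function(x) min(x) == max(x))]
  if (length(const) > 0L) {
    warning("constant column(s), correlations undefined: ",
            paste(const, collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "od_correlation")
}

#' @export
print.od_correlation <- function(x, ...) {
  cat(sprintf("Pearson correlations over %d runs\n", x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' Hierarchical clustering of runs
#'
#' Agglomerative clustering of the runs on their raw (unstandardized)
#' response vectors, by default with city-block (Manhattan) distances
#' and complete linkage, cut into `k` flat clusters. Raw units mean the
#' high-magnitude mineral columns dominate sample proximity, which is
#' the convention of the source analysis.
#'
#' @param table an `od_design` table.
#' @param columns response columns used for distances.
#' @param metric `"cityblock"` (alias `"manhattan"`) or `"euclidean"`.
#' @param linkage an agglomeration method accepted by [stats::hclust()].
#' @param k number of flat clusters.
#' @return List of class `"od_clusters"`: the `hclust` tree, merge
#'   `heights`, flat `labels` named by run id, and `members` (runs per
#'   cluster).
#' @examples
#' cl <- cluster_runs(load_design_table("table1"), k = 4)
#' cl$members
#' @export
cluster_runs <- function(table, columns = od_response_names(),
                         metric = c("cityblock", "manhattan", "euclidean"),
                         linkage = "complete", k = 4) {
  metric <- match.arg(metric)
  dist_method <- if (metric == "cityblock") "manhattan" else metric
  X <- as.matrix(as.data.frame(table)[, columns])
  rownames(X) <- as.character(table$run)
  if (k > nrow(X)) stop("k (", k, ") exceeds the number of runs (", nrow(X), ")")
  hc <- stats::hclust(stats::dist(X, method = dist_method), method = linkage)
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, heights = hc$height, labels = labels,
                 members = split(table$run, labels), k = k,
                 metric = metric, linkage = linkage),
            class = "od_clusters")
}

#' @export
print.od_clusters <- function(x, ...) {
  cat(sprintf("%s-linkage clustering (%s distance), k = %d\n",
              x$linkage, x$metric, x$k))
  for (i in seq_along(x$members)) {
    cat(sprintf("  cluster %d: %s\n", i, paste(x$members[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Principal component analysis on the correlation matrix
#'
#' Z-scores each column and eigendecomposes the correlation matrix, so
#' every variable contributes unit variance regardless of its measurement
#' unit. Loadings are the orthonormal eigenvectors, with each component's
#' sign fixed so its largest-magnitude loading is positive. The
#' contribution of a variable to a component is its squared loading as a
#' percent of that component's squared loadings (which sum to 1).
#'
#' @param table an `od_design` table.
#' @param columns columns to include; a constant column is an error.
#' @return List of class `"od_pca"`: `eigenvalues` (descending, summing
#'   to the number of variables), `loadings`, `percent_variance`,
#'   `contributions` (percent, columns sum to 100) and the run `scores`.
#' @examples
#' p <- pca_correlation(load_design_table("table1"))
#' sum(p$percent_variance[1:2])
#' @export
pca_correlation <- function(table, columns = od_response_names()) {
  X <- as.matrix(as.data.frame(table)[, columns])
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need at least 2 runs and 2 columns")
  const <- columns[apply(X, 2L, function(x) min(x) == max(x))]
  if (length(const) > 0L) {
    stop("constant column(s) cannot be z-scored: ", paste(const, collapse = ", "))
  }
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(columns, paste0("PC", seq_len(ncol(V))))
  lambda <- pmax(e$values, 0)
  structure(list(
    eigenvalues = lambda,
    loadings = V,
    percent_variance = 100 * lambda / sum(lambda),
    contributions = 100 * V^2,
    scores = scale(X) %*% V
  ), class = "od_pca")
}

#' @export
print.od_pca <- function(x, ...) {
  cat("Correlation-matrix PCA\n")
  pv <- x$percent_variance
  cat(sprintf("  PC1 %.2f%%, PC2 %.2f%% (cumulative %.1f%%)\n",
              pv[1], pv[2], pv[1] + pv[2]))
  invisible(x)
}
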