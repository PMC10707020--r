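#' Cell-mean matrix for multivariate trait analyses
#'
#' Arranges treatment-level cell means as a (genotype x treatment) by trait
#' matrix — the input the correlation, PCA and clustering analyses operate
#' on (14 rows by 17 traits in the full two-genotype, seven-treatment
#' design).
#'
#' @param means a `trait_means` data frame from [aggregate_means()].
#' @return Numeric matrix; rownames `genotype:treatment`, colnames traits.
#' @export
trait_matrix <- function(means) {
  w <- stats::reshape(means[c("genotype", "treatment", "trait", "mean")],
                      idvar = c("genotype", "treatment"), timevar = "trait",
                      direction = "wide")
  rn <- paste(w$genotype, w$treatment, sep = ":")
  m <- as.matrix(w[, -(1:2), drop = FALSE])
  colnames(m) <- sub("^mean\\.", "", colnames(m))
  rownames(m) <- rn
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Pearson correlation matrix with significance
#'
#' Product-moment correlation for every column pair, with the two-sided
#' p-value from the t-distribution on n - 2 degrees of freedom
#' (t = r * sqrt((n - 2) / (1 - r^2))). Constant columns yield `NA` r and p
#' for their pairs and are flagged. The number of significant distinct pairs
#' at p < 0.05 is reported.
#'
#' @param x numeric matrix, observations in rows (>= 3), variables in
#'   columns.
#' @param alpha significance level for the pair count (default 0.05).
#' @return Object of class `correlation_result`: list with `r`, `p`
#'   (symmetric matrices), `n` (rows used), `significant_pairs` (count over
#'   the upper triangle), `constant_columns`.
#' @export
pearson_matrix <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) {
    abort("mitieval_insufficient_data_error",
          "correlation needs at least 3 rows")
  }
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  # two-sided p from the t distribution; r = +/-1 -> p = 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  r[const, ] <- NA; r[, const] <- NA
  p[const, ] <- NA; p[, const] <- NA
  diag(r) <- ifelse(const, NA, 1)
  ut <- upper.tri(p)
  structure(
    list(r = r, p = p, n = n,
         significant_pairs = sum(p[ut] < alpha, na.rm = TRUE),
         constant_columns = colnames(x)[const] %||% which(const)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation over %d variables (n = %d)\n",
              ncol(x$r), x$n))
  cat(sprintf("Significant pairs (p < 0.05): %d\n", x$significant_pairs))
  if (length(x$constant_columns)) {
    cat("Constant columns (correlation undefined):",
        paste(x$constant_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Principal component analysis with eigenvalue-based retention
#'
#' Eigen-decomposition of the trait correlation matrix (columns
#' standardized; traits carry incommensurable units, so the correlation
#' matrix is the default) or of the covariance matrix. Components are
#' ordered by eigenvalue; the retained set is those with eigenvalue
#' strictly greater than 1.0 (the Kaiser rule on the correlation scale).
#' Loadings are the eigenvector entries, sign-fixed so the entry of largest
#' magnitude in each component is positive.
#'
#' @param x numeric matrix, observations in rows.
#' @param standardize `TRUE` (default) for correlation-matrix PCA, `FALSE`
#'   for covariance.
#' @param retain_threshold eigenvalue retention threshold, strict (default
#'   1.0; only meaningful on the correlation scale).
#' @return Object of class `pca_result`: `eigenvalues` (descending),
#'   `variance_percent`, `cumulative_percent`, `loadings` (variable x PC
#'   eigenvector matrix), `retained` (indices of PCs with eigenvalue >
#'   threshold), `standardized`.
#' @export
trait_pca <- function(x, standardize = TRUE, retain_threshold = 1.0) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort("mitieval_insufficient_data_error",
          "PCA needs >= 2 rows and >= 2 columns")
  }
  cm <- if (standardize) {
    const <- apply(x, 2, function(v) stats::sd(v) == 0)
    if (any(const)) {
      abort("mitieval_insufficient_data_error",
            sprintf("constant column(s) cannot be standardized: %s",
                    paste(colnames(x)[const], collapse = ", ")))
    }
    stats::cor(x)
  } else {
    stats::cov(x)
  }
  e <- eigen(cm, symmetric = TRUE)
  ev <- pmax(e$values, 0)  # clip tiny negative rounding of rank-deficient input
  vec <- e$vectors
  # deterministic sign: largest-|entry| positive
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- colnames(cm)
  colnames(vec) <- paste0("PC", seq_len(ncol(vec)))
  vp <- 100 * ev / sum(ev)
  structure(
    list(eigenvalues = ev, variance_percent = vp,
         cumulative_percent = cumsum(vp), loadings = vec,
         retained = which(ev > retain_threshold),
         standardized = standardize),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA on the", if (x$standardized) "correlation" else "covariance",
      "matrix\n")
  df <- data.frame(
    PC = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
    variance_pct = x$variance_percent, cumulative_pct = x$cumulative_percent
  )
  print(utils::head(df, 8), row.names = FALSE, digits = 4)
  cat("Retained (eigenvalue > 1):",
      if (length(x$retained)) paste0("PC", x$retained, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Between-group (average-linkage, UPGMA) hierarchical clustering
#'
#' Agglomerative clustering on the Euclidean distance between points with
#' the average (between-group) linkage criterion. Input rows are sorted by
#' label before clustering so the result is invariant to input order, with
#' ties resolved deterministically.
#'
#' @param x numeric matrix, one point (e.g. trait vector) per row; rownames
#'   are the leaf labels.
#' @param metric distance metric passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @return Object of class `upgma_dendrogram`: list with `hclust` (the
#'   [stats::hclust()] tree), `merges` (data frame of merge heights),
#'   `labels`.
#' @seealso [cut_dendrogram()], [write_newick()]
#' @export
upgma_cluster <- function(x, metric = "euclidean") {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    abort("mitieval_insufficient_data_error", "clustering needs >= 2 points")
  }
  if (any(!is.finite(x))) {
    abort("mitieval_parse_error", "non-finite coordinates")
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("p", seq_len(nrow(x)))
  x <- x[order(rownames(x)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(x, method = metric), method = "average")
  merges <- data.frame(
    step = seq_along(hc$height),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height
  )
  structure(list(hclust = hc, merges = merges, labels = hc$labels),
            class = "upgma_dendrogram")
}

#' Cut a dendrogram at a height or into k groups
#'
#' @param x an `upgma_dendrogram`.
#' @param height cut height (merges strictly above it are undone); cutting
#'   at 0 yields singletons for distinct points.
#' @param k number of groups (alternative to `height`).
#' @return Named integer vector of group memberships.
#' @export
cut_dendrogram <- function(x, height = NULL, k = NULL) {
  if (is.null(height) == is.null(k)) {
    abort("mitieval_config_error", "supply exactly one of height, k")
  }
  if (!is.null(height)) stats::cutree(x$hclust, h = height)
  else stats::cutree(x$hclust, k = k)
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram over %d leaves\n", length(x$labels)))
  cat("Merge heights:", paste(signif(x$merges$height, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a dendrogram as Newick text
#'
#' @param x an `upgma_dendrogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
  invisible(path)
}
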