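#' Drift-normalised principal component analysis
#'
#' Each marker column is centred by twice its sample allele frequency and
#' scaled by `sqrt(p(1-p))` where `p` is the shrunken frequency
#' `(alt_count + 1) / (2 n + 2)` (the normalisation that makes the expected
#' per-marker variance reflect genetic drift rather than allele frequency).
#' Missing entries are set to 0 after centring (mean imputation).
#' Coordinates are the sample projections on the top eigenvectors
#' (`U %*% D` of the SVD of the normalised matrix); variance fractions are
#' eigenvalues of the sample covariance divided by their total. Component
#' signs are fixed by making each component's largest-magnitude marker
#' loading positive.
#'
#' @param ds a [genotype_dataset()] with at least 2 samples and 2
#'   polymorphic markers.
#' @param n_components number of components to report.
#' @return a `pca_result`: list with `coordinates` (samples x components),
#'   `variance_fraction` (per reported component), `loadings` (markers x
#'   components), `eigenvalues` (all), `component_count`.
#' @export
run_pca <- function(ds, n_components = 10L) {
  f <- marker_freq(ds)
  g_all <- ds$geno
  colvar <- colMeans(g_all^2, na.rm = TRUE) - colMeans(g_all, na.rm = TRUE)^2
  poly <- !is.na(f) & f > 0 & f < 1 & colvar > 0
  if (sum(poly) < 2) stop("need at least 2 polymorphic markers for PCA")
  if (length(ds$samples) < 2) stop("need at least 2 samples for PCA")
  g <- ds$geno[, poly, drop = FALSE]
  nobs <- colSums(!is.na(g))
  cnt <- colSums(g, na.rm = TRUE)
  p_raw <- cnt / (2 * nobs)
  p_shrunk <- (cnt + 1) / (2 * nobs + 2)
  x <- sweep(g, 2, 2 * p_raw, "-")
  x <- sweep(x, 2, sqrt(p_shrunk * (1 - p_shrunk)), "/")
  x[is.na(x)] <- 0

  rank <- min(dim(x))
  k <- as.integer(n_components)
  if (k > rank) {
    warning(sprintf("n_components reduced from %d to the rank %d", k, rank))
    k <- rank
  }
  sv <- svd(x, nu = k, nv = k)
  # fix signs: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  ev <- sv$d^2
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(coords) <- list(ds$samples, paste0("PC", seq_len(k)))
  structure(list(coordinates = coords,
                 variance_fraction = ev[seq_len(k)] / sum(ev),
                 loadings = sv$v,
                 eigenvalues = ev,
                 component_count = k),
            class = "pca_result")
}

#' @method print pca_result
#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components\n",
              nrow(x$coordinates), x$component_count))
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}
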