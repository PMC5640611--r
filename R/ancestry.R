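#' Maximum-likelihood ancestry proportions by EM
#'
#' Fits the standard binomial admixture model: each individual i draws its
#' two allele copies at marker j from K ancestral populations with mixing
#' proportions `Q[i, ]` and ancestral alternate-allele frequencies
#' `P[, j]`, maximising
#' `sum_ij [ g_ij log(QP)_ij + (2 - g_ij) log(1 - (QP)_ij) ]`
#' over non-missing genotypes by EM (the FRAPPE-style updates, monotone in
#' the log-likelihood). Q rows start from a symmetric Dirichlet(1) draw and
#' P from Uniform(0.05, 0.95); P is clipped into `[1e-6, 1 - 1e-6]` each
#' iteration. Several seeded restarts are run and the best log-likelihood
#' kept.
#'
#' @param ds a [genotype_dataset()] with at least one polymorphic marker.
#' @param K number of ancestral populations (1 <= K <= sample count).
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @param max_iter maximum EM iterations per restart.
#' @param tol stop when the relative log-likelihood change drops below this.
#' @param n_restarts number of seeded restarts (best kept).
#' @return an `ancestry_fit`: list with `K`, `Q` (samples x K), `P`
#'   (K x markers), `loglik`, `loglik_trace`, `iterations`, `seed`.
#' @export
fit_ancestry <- function(ds, K, seed = 1L, max_iter = 500L, tol = 1e-6,
                         n_restarts = 5L) {
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K > length(ds$samples)) stop("K exceeds the number of samples")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .em_admixture(ds$geno, K, seed = seed + r - 1L,
                         max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$samples <- ds$samples
  dimnames(best$Q) <- list(ds$samples, paste0("K", seq_len(K)))
  dimnames(best$P) <- list(paste0("K", seq_len(K)), ds$markers$id)
  structure(best, class = "ancestry_fit")
}

.em_admixture <- function(g, K, seed, max_iter, tol) {
  set.seed(seed)
  n <- nrow(g); m <- ncol(g)
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0L
  g2 <- 2L - g; g2[!obs] <- 0L
  mi2 <- 2 * rowSums(obs)
  eps <- 1e-6

  Q <- matrix(rexp(n * K), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(runif(K * m, 0.05, 0.95), K, m)

  ll <- function(F) sum(g0 * log(F) + g2 * log1p(-F))
  F <- pmin(pmax(Q %*% P, eps), 1 - eps)
  trace <- numeric(max_iter + 1L)
  trace[1] <- ll(F)
  it <- 0L
  for (it in seq_len(max_iter)) {
    A <- g0 / F            # zero where missing because g0 is zero there
    B <- g2 / (1 - F)
    QN <- (A %*% t(P) + B %*% t(1 - P)) * Q
    AtQ <- crossprod(A, Q)           # m x K
    BtQ <- crossprod(B, Q)
    pn <- t(P) * AtQ                 # m x K numerators
    pd <- t(1 - P) * BtQ
    P <- pmin(pmax(t(pn / (pn + pd)), eps), 1 - eps)
    Q <- QN / mi2
    Q <- Q / rowSums(Q)              # guard against rounding drift
    F <- pmin(pmax(Q %*% P, eps), 1 - eps)
    trace[it + 1L] <- ll(F)
    if (abs(trace[it + 1L] - trace[it]) <
        tol * (abs(trace[it]) + .Machine$double.eps)) break
  }
  list(K = K, Q = Q, P = P, loglik = trace[it + 1L],
       loglik_trace = trace[seq_len(it + 1L)], iterations = it,
       seed = seed)
}

#' @method print ancestry_fit
#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("ancestry_fit: K = %d, loglik = %.2f after %d iterations (seed %d)\n",
              x$K, x$loglik, x$iterations, x$seed))
  invisible(x)
}

#' Cross-validation error for choosing K
#'
#' Non-missing genotype entries are partitioned at random into `folds`
#' disjoint sets (in a canonical sample/marker-id order, so the masking is
#' invariant to row or column permutations of the dataset). For each fold
#' the model is refitted with those entries masked and the prediction error
#' `mean((g - 2 QP)^2)` is evaluated on the held-out entries; the
#' across-fold mean is returned. The most probable K minimises this error.
#'
#' @inheritParams fit_ancestry
#' @param folds number of cross-validation folds (>= 2).
#' @return non-negative scalar CV error.
#' @export
cv_error <- function(ds, K, folds = 5L, seed = 1L, max_iter = 200L,
                     tol = 1e-5, n_restarts = 1L) {
  folds <- as.integer(folds)
  if (folds < 2) stop("folds must be >= 2")
  so <- order(ds$samples); mo <- order(ds$markers$id)
  g <- ds$geno[so, mo, drop = FALSE]
  obs <- which(!is.na(g))
  if (length(obs) == 0) stop("no observed genotype entries to hold out")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs)))
  errs <- numeric(folds)
  for (f in seq_len(folds)) {
    held <- obs[fold_of == f]
    if (length(held) == 0) stop("a fold holds out no entries")
    gtrain <- g
    gtrain[held] <- NA_integer_
    ds_f <- ds
    ds_f$geno <- gtrain
    ds_f$samples <- ds$samples[so]
    ds_f$markers <- ds$markers[mo, ]
    fit <- fit_ancestry(ds_f, K, seed = seed, max_iter = max_iter,
                        tol = tol, n_restarts = n_restarts)
    pred <- 2 * (fit$Q %*% fit$P)
    errs[f] <- mean((g[held] - pred[held])^2)
  }
  mean(errs)
}

#' Per-population mean ancestry fractions
#'
#' @param fit an `ancestry_fit`.
#' @param map a [population_map()] covering the fitted samples.
#' @return populations x K matrix of mean Q.
#' @export
mean_ancestry <- function(fit, map) {
  if (!inherits(map, "population_map")) map <- population_map(map)
  pop <- unclass(map)[rownames(fit$Q)]
  t(sapply(split(seq_len(nrow(fit$Q)), pop), function(i)
    colMeans(fit$Q[i, , drop = FALSE])))
}
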