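#' Marker and sample quality filters
#'
#' `filter_markers()` removes markers whose minor-allele frequency, computed
#' over the non-missing dosages of the samples in scope, falls below
#' `min_maf`. `filter_samples()` removes samples whose genotype call rate
#' falls below `min_call_rate`.
#'
#' @param ds a [genotype_dataset()].
#' @param min_maf minimum minor-allele frequency in `[0, 1]`.
#' @param min_call_rate minimum fraction of non-missing genotypes.
#' @return the filtered `genotype_dataset`.
#' @export
filter_markers <- function(ds, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf <= 1)
  f <- marker_freq(ds)
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= min_maf
  if (!any(keep)) stop("MAF filter removed all markers")
  subset_dataset(ds, markers = which(keep))
}

#' @rdname filter_markers
#' @export
filter_samples <- function(ds, min_call_rate = 0.95) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1)
  cr <- sample_call_rate(ds)
  keep <- cr >= min_call_rate
  if (!any(keep)) stop("call-rate filter removed all samples")
  subset_dataset(ds, samples = which(keep))
}

#' LD-pruning window specification
#'
#' Mirrors PLINK's `--indep-pairwise <window> <step> <r2>`.
#'
#' @param window_snps window width in markers (>= 2).
#' @param step_snps window shift in markers.
#' @param r2_max maximum allowed squared dosage correlation.
#' @return a `prune_spec` list.
#' @export
prune_spec <- function(window_snps = 50L, step_snps = 5L, r2_max = 0.5) {
  window_snps <- as.integer(window_snps); step_snps <- as.integer(step_snps)
  stopifnot(window_snps >= 2, step_snps >= 1, step_snps <= window_snps,
            r2_max > 0, r2_max <= 1)
  structure(list(window_snps = window_snps, step_snps = step_snps,
                 r2_max = r2_max), class = "prune_spec")
}

#' Windowed LD pruning of markers
#'
#' Within each sliding window of `spec$window_snps` markers (advanced by
#' `spec$step_snps`, per chromosome), while any retained pair has squared
#' genotype-dosage correlation above `spec$r2_max`, the member of the
#' worst-offending pair with lower MAF is removed (ties: the later marker).
#' Correlations use pairwise-complete observations.
#'
#' @param ds a [genotype_dataset()] with markers sorted by (chrom, pos).
#' @param spec a [prune_spec()].
#' @return character vector of retained marker ids, in input order.
#' @export
ld_prune <- function(ds, spec = prune_spec()) {
  mk <- ds$markers
  o <- order(mk$chrom, mk$pos)
  if (!identical(o, seq_len(nrow(mk))))
    stop("markers must be sorted by (chromosome, position) before pruning")
  f <- marker_freq(ds)
  maf <- pmin(f, 1 - f)
  keep <- rep(TRUE, nrow(mk))
  for (chr in unique(mk$chrom)) {
    idx <- which(mk$chrom == chr)
    if (length(idx) < 2) next
    starts <- seq(1L, length(idx), by = spec$step_snps)
    for (s in starts) {
      win <- idx[s:min(s + spec$window_snps - 1L, length(idx))]
      win <- win[keep[win]]
      keep[win] <- .prune_window(ds$geno[, win, drop = FALSE],
                                 maf[win], spec$r2_max)
      if (s + spec$window_snps - 1L >= length(idx)) break
    }
  }
  mk$id[keep]
}

# greedy within-window rule shared by ld_prune; returns logical keep vector
.prune_window <- function(g, maf, r2_max) {
  k <- ncol(g)
  keep <- rep(TRUE, k)
  if (k < 2) return(keep)
  r2 <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))^2
  r2[!is.finite(r2)] <- 0
  diag(r2) <- 0
  repeat {
    live <- which(keep)
    if (length(live) < 2) break
    sub <- r2[live, live, drop = FALSE]
    w <- which(sub > r2_max)
    if (length(w) == 0) break
    top <- w[which.max(sub[w])]
    i <- live[(top - 1L) %% length(live) + 1L]
    j <- live[(top - 1L) %/% length(live) + 1L]
    a <- min(i, j); b <- max(i, j)
    drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else b
    keep[drop] <- FALSE
  }
  keep
}

#' Method-of-moments IBD estimation (pi-hat)
#'
#' Estimates P(IBD = 0, 1, 2) per sample pair from identity-by-state counts
#' and their expectations under the supplied allele frequencies, then
#' `pi_hat = P(IBD=2) + P(IBD=1)/2`. Raw probabilities are bounded into
#' `[0, 1]` and renormalised. Markers should be LD-pruned beforehand.
#'
#' @param ds a [genotype_dataset()].
#' @param pairs two-column matrix/data.frame of sample ids; default all
#'   pairs.
#' @param freqs optional per-marker alternate-allele frequencies; default
#'   estimated from `ds`.
#' @param min_overlap pairs with fewer overlapping non-missing markers are
#'   flagged `low_conf`.
#' @return data.frame with columns id1, id2, k0, k1, k2, pihat, n_snps,
#'   low_conf.
#' @export
estimate_ibd <- function(ds, pairs = NULL, freqs = NULL, min_overlap = 50L) {
  if (is.null(pairs)) {
    if (length(ds$samples) < 2) stop("need at least two samples")
    pairs <- t(combn(ds$samples, 2))
  }
  pairs <- as.matrix(pairs)
  if (is.null(freqs)) {
    # expected per-marker IBS probabilities given IBD state, from unbiased
    # allele-count moments (distinct draws without replacement), which
    # removes the finite-sample bias of plugging in estimated frequencies
    na <- colSums(ds$geno, na.rm = TRUE)            # alt allele count
    tt <- 2 * colSums(!is.na(ds$geno))              # total allele copies
    nb <- tt - na
    ok4 <- tt >= 4
    d2 <- tt * (tt - 1)
    d3 <- d2 * (tt - 2)
    d4 <- d3 * (tt - 3)
    p2q2 <- na * (na - 1) * nb * (nb - 1) / d4
    p3q <- na * (na - 1) * (na - 2) * nb / d4
    pq3 <- na * nb * (nb - 1) * (nb - 2) / d4
    p4 <- na * (na - 1) * (na - 2) * (na - 3) / d4
    q4 <- nb * (nb - 1) * (nb - 2) * (nb - 3) / d4
    p2q <- na * (na - 1) * nb / d3
    pq2 <- na * nb * (nb - 1) / d3
    p3 <- na * (na - 1) * (na - 2) / d3
    q3 <- nb * (nb - 1) * (nb - 2) / d3
    e00 <- 2 * p2q2                         # P(IBS0 | IBD0)
    e10 <- 4 * p3q + 4 * pq3                # P(IBS1 | IBD0)
    e20 <- p4 + q4 + 4 * p2q2               # P(IBS2 | IBD0)
    e11 <- 2 * p2q + 2 * pq2                # P(IBS1 | IBD1)
    e21 <- p3 + q3 + p2q + pq2              # P(IBS2 | IBD1)
    e00[!ok4] <- NA_real_
    p <- na / tt
  } else {
    # frequencies supplied externally (treated as exact): plug-in moments
    p <- as.numeric(freqs); q <- 1 - p
    e00 <- 2 * p^2 * q^2
    e10 <- 4 * p^3 * q + 4 * p * q^3
    e20 <- p^4 + q^4 + 4 * p^2 * q^2
    e11 <- 2 * p * q
    e21 <- p^2 + q^2
  }

  g <- ds$geno
  res <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2], k0 = NA_real_,
                    k1 = NA_real_, k2 = NA_real_, pihat = NA_real_,
                    n_snps = NA_integer_, low_conf = NA,
                    stringsAsFactors = FALSE)
  i1 <- match(pairs[, 1], ds$samples); i2 <- match(pairs[, 2], ds$samples)
  if (anyNA(i1) || anyNA(i2)) stop("unknown sample id in pairs")
  for (r in seq_len(nrow(pairs))) {
    d1 <- g[i1[r], ]; d2 <- g[i2[r], ]
    ok <- !is.na(d1) & !is.na(d2) & !is.na(p) & p > 0 & p < 1 & !is.na(e00)
    ibs <- 2L - abs(d1[ok] - d2[ok])
    n0 <- sum(ibs == 0L); n1 <- sum(ibs == 1L); n2 <- sum(ibs == 2L)
    nm <- length(ibs)
    E00 <- sum(e00[ok]); E10 <- sum(e10[ok]); E20 <- sum(e20[ok])
    E11 <- sum(e11[ok]); E21 <- sum(e21[ok])
    k0 <- if (E00 > 0) n0 / E00 else 0
    k1 <- if (E11 > 0) (n1 - k0 * E10) / E11 else 0
    k2 <- if (nm > 0) (n2 - k0 * E20 - k1 * E21) / nm else 0
    k <- pmin(pmax(c(k0, k1, k2), 0), 1)
    if (sum(k) > 0) k <- k / sum(k) else k <- c(1, 0, 0)
    res$k0[r] <- k[1]; res$k1[r] <- k[2]; res$k2[r] <- k[3]
    res$pihat[r] <- k[3] + k[2] / 2
    res$n_snps[r] <- nm
    res$low_conf[r] <- nm < min_overlap
  }
  res
}

# iterative greedy removal on a relatedness graph: drop the sample in the
# most above-threshold pairs; ties broken by lower call rate, then by
# lexicographically later id. Returns removed sample ids.
.greedy_related_removals <- function(ibd, threshold, call_rates) {
  edges <- ibd[ibd$pihat > threshold, c("id1", "id2"), drop = FALSE]
  removed <- character(0)
  while (nrow(edges) > 0) {
    deg <- table(c(edges$id1, edges$id2))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      cr <- call_rates[cand]
      cand <- cand[cr == min(cr)]
    }
    victim <- sort(cand, decreasing = TRUE)[1]
    removed <- c(removed, victim)
    edges <- edges[edges$id1 != victim & edges$id2 != victim, , drop = FALSE]
  }
  removed
}

#' Remove closely related samples within groups
#'
#' Within each population group, IBD is estimated from the group's own
#' allele frequencies and samples are removed greedily: while any pair has
#' `pihat > threshold`, the sample participating in the most such pairs is
#' dropped (ties: lower call rate, then lexicographically later id).
#'
#' @param ds a [genotype_dataset()].
#' @param threshold pi-hat above which a pair counts as closely related.
#' @param grouping a [population_map()]; defaults to the dataset's own
#'   population labels; pass `NULL` explicitly to treat all samples as one
#'   group.
#' @return list with elements `dataset` (samples removed), `removed`
#'   (character vector) and `ibd` (the per-group IBD tables, row-bound).
#' @export
drop_related <- function(ds, threshold = 0.3,
                         grouping = if (is.null(ds$populations)) NULL
                                    else dataset_population_map(ds)) {
  groups <- if (is.null(grouping)) setNames(rep("all", length(ds$samples)),
                                            ds$samples)
            else setNames(unname(unclass(grouping)), names(grouping))
  removed <- character(0)
  tabs <- list()
  for (gp in unique(groups[ds$samples])) {
    ids <- ds$samples[groups[ds$samples] == gp]
    ids <- ids[!is.na(ids)]
    if (length(ids) < 2) next
    sub <- subset_dataset(ds, samples = ids)
    ibd <- estimate_ibd(sub)
    tabs[[gp]] <- cbind(group = gp, ibd)
    removed <- c(removed,
                 .greedy_related_removals(ibd, threshold,
                                          sample_call_rate(sub)))
  }
  keep <- setdiff(ds$samples, removed)
  list(dataset = subset_dataset(ds, samples = keep),
       removed = removed,
       ibd = if (length(tabs)) do.call(rbind, tabs) else NULL)
}
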