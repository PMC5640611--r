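#' f-statistics with block-jackknife standard errors
#'
#' Moment statistics of allele-frequency differences between populations.
#' Writing `a, b, c, d, x` for per-SNP alternate-allele frequencies and
#' `n_x` for the number of non-missing allele copies in population X:
#'
#' * `f2(A, B)`: mean of `(a - b)^2 - a(1-a)/(n_a - 1) - b(1-b)/(n_b - 1)`;
#' * `f3(X; A, B)`: mean of `(x - a)(x - b) - x(1-x)/(n_x - 1)`; a
#'   significantly negative value (conventionally Z < -2) is evidence that
#'   X descends from a mixture of sources related to A and B;
#' * `f4(A, B; C, D)`: mean of `(a - b)(c - d)`, no correction needed.
#'
#' The subtracted terms are the unbiased corrections for sampling noise in
#' the populations that appear twice in the product. Aggregation is the
#' unweighted mean over complete-case SNPs (SNPs masked in any involved
#' population, or with fewer than 2 allele copies where a correction is
#' needed, are excluded). Standard errors come from a weighted
#' delete-one-block jackknife over contiguous blocks of `block_size` SNPs
#' (final short block kept), and `z = estimate / se`.
#'
#' @param freqs a [freq_table()].
#' @param x,a,b,c,d population labels.
#' @param block_size jackknife block size in SNPs (default 200, the value
#'   appropriate for chip-density real data; use larger blocks, e.g. 5000,
#'   for dense simulated data).
#' @return an `fstat_result`: list with `statistic`, `pops`, `estimate`,
#'   `se`, `z`, `n_snps`, `n_blocks`.
#' @export
f3 <- function(freqs, x, a, b, block_size = 200L) {
  .check_pops(freqs, c(x, a, b))
  fx <- freqs$freq[x, ]; fa <- freqs$freq[a, ]; fb <- freqs$freq[b, ]
  nx <- freqs$count[x, ]
  use <- !is.na(fx) & !is.na(fa) & !is.na(fb) &
         nx >= 2 & freqs$count[a, ] >= 1 & freqs$count[b, ] >= 1
  if (!any(use)) stop("no usable SNPs for f3")
  corr <- ifelse(is.finite(nx[use]), fx[use] * (1 - fx[use]) / (nx[use] - 1), 0)
  terms <- (fx[use] - fa[use]) * (fx[use] - fb[use]) - corr
  .fstat_result("f3", c(X = x, A = a, B = b), terms, block_size)
}

#' @rdname f3
#' @export
f4 <- function(freqs, a, b, c, d, block_size = 200L) {
  .check_pops(freqs, c(a, b, c, d))
  fa <- freqs$freq[a, ]; fb <- freqs$freq[b, ]
  fc <- freqs$freq[c, ]; fd <- freqs$freq[d, ]
  use <- !is.na(fa) & !is.na(fb) & !is.na(fc) & !is.na(fd) &
         freqs$count[a, ] >= 1 & freqs$count[b, ] >= 1 &
         freqs$count[c, ] >= 1 & freqs$count[d, ] >= 1
  if (!any(use)) stop("no usable SNPs for f4")
  terms <- (fa[use] - fb[use]) * (fc[use] - fd[use])
  .fstat_result("f4", c(A = a, B = b, C = c, D = d), terms, block_size)
}

#' @rdname f3
#' @export
f2 <- function(freqs, a, b, block_size = 200L) {
  .check_pops(freqs, c(a, b))
  fa <- freqs$freq[a, ]; fb <- freqs$freq[b, ]
  na <- freqs$count[a, ]; nb <- freqs$count[b, ]
  use <- !is.na(fa) & !is.na(fb) & na >= 2 & nb >= 2
  if (!any(use)) stop("no usable SNPs for f2")
  ca <- ifelse(is.finite(na[use]), fa[use] * (1 - fa[use]) / (na[use] - 1), 0)
  cb <- ifelse(is.finite(nb[use]), fb[use] * (1 - fb[use]) / (nb[use] - 1), 0)
  terms <- (fa[use] - fb[use])^2 - ca - cb
  .fstat_result("f2", c(A = a, B = b), terms, block_size)
}

.fstat_result <- function(statistic, pops, terms, block_size) {
  jk <- .jackknife_mean(terms, .block_index(length(terms), block_size))
  structure(list(statistic = statistic, pops = pops,
                 estimate = jk$estimate, se = jk$se,
                 z = if (jk$se > 0) jk$estimate / jk$se else NA_real_,
                 n_snps = length(terms), n_blocks = jk$n_blocks),
            class = "fstat_result")
}

#' @method print fstat_result
#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s): %.6g (se %.3g, Z %.2f, %d SNPs in %d blocks)\n",
              x$statistic, paste(x$pops, collapse = ", "),
              x$estimate, x$se, x$z, x$n_snps, x$n_blocks))
  if (!is.null(x$chinese_fraction))
    cat(sprintf("  alpha = %.4f, complement (e.g. Chinese ancestry) = %.4f%s\n",
                x$estimate, x$chinese_fraction,
                if (isTRUE(x$unstable)) " [unstable denominator]" else ""))
  invisible(x)
}

#' @export
as.data.frame.fstat_result <- function(x, ...) {
  data.frame(statistic = x$statistic,
             pops = paste(x$pops, collapse = ";"),
             estimate = x$estimate, se = x$se, z = x$z,
             n_snps = x$n_snps, n_blocks = x$n_blocks,
             stringsAsFactors = FALSE)
}

#' F4-ratio estimate of an admixture proportion
#'
#' Estimates the mixture proportion `alpha` of the `ib`-related ancestry in
#' the admixed population `eud` as the ratio of two f4 statistics sharing
#' the (`euw`, `outgroup`) comparison:
#' `alpha = f4(euw, outgroup; eud, bmx) / f4(euw, outgroup; ib, bmx)`.
#' In the pig application `euw` is a European wild boar group, `outgroup`
#' the Sumatran wild boars, `ib` an unadmixed European breed (Iberico) and
#' `bmx` the representative donor of Chinese ancestry (Bamaxiang), so
#' `1 - alpha` is the fraction of Chinese ancestry in `eud`. The standard
#' error jackknifes the ratio itself (numerator and denominator recomputed
#' on every delete-one-block replicate), which is correct for their
#' correlation.
#'
#' @inheritParams f3
#' @param euw,outgroup,eud,bmx,ib population labels (see Details).
#' @return an `fstat_result` with `estimate = alpha`, plus elements
#'   `chinese_fraction` (`1 - alpha`) and `unstable` (TRUE when
#'   `|denominator| < 10 x its SE`).
#' @export
f4_ratio <- function(freqs, euw, outgroup, eud, bmx, ib, block_size = 200L) {
  .check_pops(freqs, c(euw, outgroup, eud, bmx, ib))
  fw <- freqs$freq[euw, ]; fo <- freqs$freq[outgroup, ]
  fe <- freqs$freq[eud, ]; fm <- freqs$freq[bmx, ]; fi <- freqs$freq[ib, ]
  cnt_ok <- freqs$count[euw, ] >= 1 & freqs$count[outgroup, ] >= 1 &
            freqs$count[eud, ] >= 1 & freqs$count[bmx, ] >= 1 &
            freqs$count[ib, ] >= 1
  use <- !is.na(fw) & !is.na(fo) & !is.na(fe) & !is.na(fm) & !is.na(fi) &
         cnt_ok
  if (!any(use)) stop("no usable SNPs for the F4-ratio")
  base <- (fw[use] - fo[use])
  num <- base * (fe[use] - fm[use])
  den <- base * (fi[use] - fm[use])
  block <- .block_index(sum(use), block_size)
  jk <- .jackknife_ratio(num, den, block)
  djk <- .jackknife_mean(den, block)
  out <- structure(list(statistic = "f4-ratio",
                        pops = c(EUW = euw, Outgroup = outgroup, EUD = eud,
                                 BMX = bmx, IB = ib),
                        estimate = jk$estimate, se = jk$se,
                        z = if (jk$se > 0) jk$estimate / jk$se else NA_real_,
                        n_snps = sum(use), n_blocks = jk$n_blocks),
                   class = "fstat_result")
  out$chinese_fraction <- 1 - jk$estimate
  out$unstable <- abs(djk$estimate) < 10 * djk$se
  if (out$unstable)
    message("f4_ratio: denominator within 10 SE of zero; estimate flagged unstable")
  out
}

#' Three-population admixture scan
#'
#' Runs `f3(target; A, B)` for every supplied source pair and returns the
#' results sorted by Z score; rows with Z < -2 are flagged as significant
#' evidence that the target is admixed between sources related to that
#' pair.
#'
#' @inheritParams f3
#' @param target the putatively admixed population.
#' @param source_pairs two-column matrix/data.frame of source population
#'   labels (may be empty).
#' @return data.frame with one row per pair, columns A, B, estimate, se, z,
#'   n_snps, n_blocks, significant; sorted by z. The attribute `"top"`
#'   names the most significantly negative pair.
#' @export
three_pop_scan <- function(freqs, target, source_pairs, block_size = 200L) {
  source_pairs <- as.matrix(source_pairs)
  if (nrow(source_pairs) == 0)
    return(data.frame(A = character(0), B = character(0),
                      estimate = numeric(0), se = numeric(0), z = numeric(0),
                      n_snps = integer(0), n_blocks = integer(0),
                      significant = logical(0)))
  rows <- lapply(seq_len(nrow(source_pairs)), function(i) {
    r <- f3(freqs, target, source_pairs[i, 1], source_pairs[i, 2], block_size)
    data.frame(A = source_pairs[i, 1], B = source_pairs[i, 2],
               estimate = r$estimate, se = r$se, z = r$z,
               n_snps = r$n_snps, n_blocks = r$n_blocks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$z < -2
  out <- out[order(out$z), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "top") <- unlist(out[1, c("A", "B")])
  out
}
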