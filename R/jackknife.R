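# Weighted delete-one-block jackknife over contiguous SNP blocks.
#
# Blocks are consecutive runs of `block_size` SNPs in the order the used
# SNPs appear (markers are kept in (chromosome, position) order upstream);
# the final short block is kept and the unequal block sizes are handled by
# the weighted jackknife of Busing et al. (1999), the scheme commonly used
# with f-statistics.

.block_index <- function(n, block_size) {
  if (block_size < 2) stop("block size must be >= 2")
  ((seq_len(n) - 1L) %/% as.integer(block_size)) + 1L
}

# core weighted jackknife for a ratio-of-sums statistic, from per-block
# sums bn (numerator), bd (denominator) and block sizes m. Means are the
# special case bd = m.
.jackknife_blocks <- function(bn, bd, m) {
  g <- length(m)
  if (g < 2) stop("fewer than 2 usable jackknife blocks")
  n <- sum(m)
  sn <- sum(bn); sd <- sum(bd)
  est <- sn / sd
  loo <- (sn - bn) / (sd - bd)
  if (any(!is.finite(loo)))
    stop("jackknife replicate undefined (zero denominator in a block)")
  h <- n / m
  theta_j <- g * est - sum((1 - m / n) * loo)
  tau <- h * est - (h - 1) * loo
  se <- sqrt(sum((tau - theta_j)^2 / (h - 1)) / g)
  list(estimate = est, se = se, n_blocks = g)
}

# statistic = ratio of sums num/den per delete-one-block replicate
.jackknife_ratio <- function(num, den, block) {
  bn <- rowsum(num, block, reorder = TRUE)[, 1]
  bd <- rowsum(den, block, reorder = TRUE)[, 1]
  .jackknife_blocks(bn, bd, tabulate(block))
}

.jackknife_mean <- function(terms, block) {
  m <- tabulate(block)
  bn <- rowsum(terms, block, reorder = TRUE)[, 1]
  .jackknife_blocks(bn, m, m)
}
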