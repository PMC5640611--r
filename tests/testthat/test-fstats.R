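# per-SNP frequencies given column-wise: (pop1, pop2, ...) per SNP
pop_freqs <- function(vals, pops) {
  freq_table(matrix(vals, nrow = length(pops),
                    dimnames = list(pops, NULL)))
}

test_that("allele frequencies count alt copies over non-missing genotypes", {
  g <- rbind(c(1L, NA, 2L),
             c(NA, NA, 0L),
             c(2L, NA, 1L))
  ds <- genotype_dataset(g, data.frame(id = c("a", "b", "c"), chrom = "1",
                                       pos = 1:3, ref = "A", alt = "G"),
                         samples = c("x1", "x2", "y1"),
                         populations = c("X", "X", "Y"))
  fr <- allele_freqs(ds)
  expect_equal(fr$freq["X", ], c(a = 0.5, b = NA, c = 0.5))
  expect_equal(fr$count["X", ], c(a = 2, b = 0, c = 4))
  expect_equal(fr$freq["Y", "a"], 1)
  # a single heterozygote: frequency 0.5 from 2 copies
  expect_equal(fr$freq["Y", "c"], 0.5)
  expect_equal(fr$count["Y", "c"], 2)
})

test_that("f3 reproduces hand-computed products of frequency differences", {
  # x = 0.5, a = 0.1, b = 0.9 at population level: (0.4)(-0.4) = -0.16
  fq <- pop_freqs(rep(c(0.5, 0.1, 0.9), 4), c("X", "A", "B"))
  r <- f3(fq, "X", "A", "B", block_size = 2)
  expect_equal(r$estimate, -0.16)
  expect_equal(r$se, 0)           # identical blocks: jackknife SE exactly 0
  # X identical to A at every SNP: estimate 0
  set.seed(4)
  xa <- runif(6)
  fq2 <- freq_table(rbind(X = xa, A = xa, B = runif(6)))
  expect_equal(f3(fq2, "X", "A", "B", block_size = 2)$estimate, 0)
})

test_that("f4 handles fixed differences, duplicate populations and antisymmetry", {
  fq <- pop_freqs(rep(c(1, 0, 1, 0), 4), c("A", "B", "C", "D"))
  expect_equal(f4(fq, "A", "B", "C", "D", block_size = 2)$estimate, 1)
  set.seed(8)
  fr <- freq_table(matrix(runif(4 * 12), 4, 12,
                          dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(f4(fr, "A", "A", "C", "D", block_size = 3)$estimate, 0)
  expect_equal(f4(fr, "B", "A", "C", "D", block_size = 3)$estimate,
               -f4(fr, "A", "B", "C", "D", block_size = 3)$estimate)
})

test_that("analytic identities hold exactly on population-level frequencies", {
  set.seed(16)
  fr <- freq_table(matrix(runif(4 * 30, 0.05, 0.95), 4, 30,
                          dimnames = list(c("W", "X", "Y", "Z"), NULL)))
  b <- 5
  # f4(A,B;A,B) = f2(A,B)
  expect_equal(f4(fr, "W", "X", "W", "X", b)$estimate,
               f2(fr, "W", "X", b)$estimate, tolerance = 1e-14)
  # f3(X;A,B) = (f2(X,A) + f2(X,B) - f2(A,B)) / 2
  expect_equal(f3(fr, "X", "W", "Y", b)$estimate,
               (f2(fr, "X", "W", b)$estimate + f2(fr, "X", "Y", b)$estimate -
                f2(fr, "W", "Y", b)$estimate) / 2,
               tolerance = 1e-14)
  # f2 trivia
  expect_equal(f2(fr, "W", "W", b)$estimate, 0)
  fq01 <- pop_freqs(rep(c(1, 0), 4), c("P", "Q"))
  expect_equal(f2(fq01, "P", "Q", 2)$estimate, 1)
})

test_that("the small-sample f3 correction is unbiased (binomial Monte Carlo)", {
  # known population frequencies; resample n = 10 diploids for X and check
  # that the corrected per-SNP term recovers the population-level value
  set.seed(24)
  px <- 0.5; pa <- 0.1; pb <- 0.9
  target <- (px - pa) * (px - pb)
  reps <- 100000
  n <- 10
  xhat <- rbinom(reps, 2 * n, px) / (2 * n)
  terms <- (xhat - pa) * (xhat - pb) - xhat * (1 - xhat) / (2 * n - 1)
  mc_se <- sd(terms) / sqrt(reps)
  expect_lt(abs(mean(terms) - target), 3 * mc_se)
})

test_that("block jackknife tracks the sampling distribution and weights short blocks", {
  # block-constant statistic has SE exactly zero even with a short tail block
  fq <- pop_freqs(rep(c(0.3, 0.6), 7), c("A", "B"))
  expect_equal(f2(fq, "A", "B", block_size = 3)$se, 0)
  expect_equal(f2(fq, "A", "B", block_size = 3)$n_blocks, 3)

  # fewer than 2 blocks is an error
  expect_error(f2(pop_freqs(rep(c(0.3, 0.6), 2), c("A", "B")), "A", "B",
                  block_size = 5), "blocks")

  # SE approximates the empirical SD over replicates of independent SNPs
  set.seed(40)
  nsnp <- 600; nrep <- 120
  est <- se <- numeric(nrep)
  for (r in seq_len(nrep)) {
    p0 <- runif(nsnp, 0.1, 0.9)
    fa <- rbinom(nsnp, 40, p0) / 40
    fb <- rbinom(nsnp, 40, p0) / 40
    fr <- freq_table(rbind(A = fa, B = fb),
                     count = matrix(40, 2, nsnp))
    r4 <- f2(fr, "A", "B", block_size = 50)
    est[r] <- r4$estimate; se[r] <- r4$se
  }
  expect_lt(abs(mean(se) / sd(est) - 1), 0.2)
})

test_that("F4-ratio endpoints are exact and the denominator guard fires", {
  # w and i share ancestral drift so the denominator f4 is bounded away
  # from zero; o and m are outgroup/donor-like and independent
  set.seed(48)
  anc <- runif(20)
  w <- 0.7 * anc + 0.15 + runif(20, -0.1, 0.1)
  i <- 0.7 * anc + 0.15 + runif(20, -0.1, 0.1)
  o <- runif(20); m <- runif(20)
  # EUD identical to IB -> alpha = 1; identical to BMX -> alpha = 0
  fr1 <- freq_table(rbind(W = w, O = o, E = i, M = m, I = i))
  r1 <- suppressMessages(f4_ratio(fr1, "W", "O", "E", "M", "I",
                                  block_size = 4))
  expect_equal(r1$estimate, 1)
  expect_equal(r1$chinese_fraction, 0)
  fr0 <- freq_table(rbind(W = w, O = o, E = m, M = m, I = i))
  expect_equal(suppressMessages(
    f4_ratio(fr0, "W", "O", "E", "M", "I", 4))$estimate, 0)
  # a denominator within 10 SE of zero is flagged unstable: make IB nearly
  # identical to the donor BMX
  i_bad <- pmin(pmax(m + runif(20, -0.005, 0.005), 0), 1)
  frbad <- freq_table(rbind(W = w, O = o, E = i, M = m, I = i_bad))
  expect_message(rbad <- f4_ratio(frbad, "W", "O", "E", "M", "I", 4),
                 "unstable")
  expect_true(rbad$unstable)
})

test_that("three_pop_scan orders, flags, and handles an empty pair list", {
  set.seed(56)
  k <- 200
  xa <- runif(k, 0.2, 0.8)
  fr <- freq_table(rbind(X = 0.5 * xa + 0.5 * (1 - xa),  # blend -> admixed-ish
                         A = xa, B = 1 - xa, C = runif(k, 0.2, 0.8)))
  sc <- three_pop_scan(fr, "X", rbind(c("A", "B"), c("A", "C")),
                       block_size = 20)
  expect_equal(nrow(sc), 2)
  expect_true(!is.unsorted(sc$z))
  expect_named(attr(sc, "top"), c("A", "B"))
  empty <- three_pop_scan(fr, "X", matrix(character(0), 0, 2), 20)
  expect_equal(nrow(empty), 0)
})

test_that("f-statistics exclude SNPs masked in any involved population", {
  fr <- freq_table(rbind(X = c(0.5, 0.5, NA, 0.5, 0.5, 0.5, NA, 0.5),
                         A = c(0.1, NA, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
                         B = rep(0.9, 8)))
  r <- f3(fr, "X", "A", "B", block_size = 2)
  expect_equal(r$n_snps, 5)
  expect_equal(r$n_blocks, 3)
  expect_equal(r$estimate, -0.16)
})
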