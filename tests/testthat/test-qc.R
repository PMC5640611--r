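test_that("MAF and call-rate filters apply their thresholds exactly", {
  g <- rbind(c(0L, 0L, 1L, 2L),
             c(0L, 0L, 1L, 2L),
             c(0L, 0L, 1L, 2L),
             c(1L, 0L, 1L, 2L))
  mk <- data.frame(id = paste0("m", 1:4), chrom = "1", pos = 1:4 * 10L,
                   ref = "A", alt = "G")
  ds <- genotype_dataset(g, mk, samples = paste0("s", 1:4))
  # m1: one alt copy over 8 -> MAF 0.125; m2 monomorphic; m3 MAF 0.5;
  # m4 all-hom-alt -> MAF 0
  f <- filter_markers(ds, 0.05)
  expect_setequal(f$markers$id, c("m1", "m3"))
  # every retained marker has MAF >= threshold (exact recount)
  maf <- pmin(marker_freq(f), 1 - marker_freq(f))
  expect_true(all(maf >= 0.05))

  # sample with 94% call rate is removed at a 95% threshold
  set.seed(9)
  g2 <- matrix(sample(0:2, 10 * 100, TRUE), 10, 100)
  g2[1, 1:6] <- NA_integer_       # 94% call rate
  ds2 <- genotype_dataset(g2, data.frame(id = paste0("v", 1:100), chrom = "1",
                                         pos = 1:100, ref = "A", alt = "C"),
                          samples = paste0("s", 1:10))
  kept <- filter_samples(ds2, 0.95)
  expect_false("s1" %in% kept$samples)
  expect_equal(length(kept$samples), 9)
  expect_error(filter_markers(subset_dataset(ds, markers = "m2"), 0.05),
               "removed all")
})

test_that("LD pruning keeps uncorrelated markers and resolves perfect LD", {
  set.seed(21)
  # orthogonal-ish random markers: nothing above the threshold
  g <- matrix(sample(0:2, 50 * 10, TRUE), 50, 10)
  ds <- genotype_dataset(g, data.frame(id = paste0("m", 1:10), chrom = "1",
                                       pos = 1:10 * 50L, ref = "A", alt = "G"))
  r2 <- suppressWarnings(cor(g))^2
  expect_lte(max(r2[upper.tri(r2)]), 0.5)  # fixture is below the threshold
  expect_equal(ld_prune(ds, prune_spec(10, 5, 0.5)), ds$markers$id)

  # a duplicated marker: exactly one of the pair retained
  g2 <- g
  g2[, 4] <- g2[, 3]
  ds2 <- genotype_dataset(g2, ds$markers)
  kept <- ld_prune(ds2, prune_spec(10, 5, 0.5))
  expect_equal(sum(c("m3", "m4") %in% kept), 1)
})

test_that("windowed pruning matches the brute-force greedy oracle", {
  # 20 samples x 5 markers engineered to straddle r2 = 0.5
  set.seed(33)
  base <- sample(0:2, 20, TRUE)
  g <- cbind(base,
             ifelse(runif(20) < 0.85, base, sample(0:2, 20, TRUE)),
             sample(0:2, 20, TRUE),
             ifelse(runif(20) < 0.6, base, sample(0:2, 20, TRUE)),
             2L - base)
  storage.mode(g) <- "integer"
  ds <- genotype_dataset(g, data.frame(id = paste0("m", 1:5), chrom = "1",
                                       pos = 1:5 * 10L, ref = "A", alt = "G"))
  f <- marker_freq(ds)
  maf <- pmin(f, 1 - f)
  keep_oracle <- oracle_prune_window(ds$geno, maf, 0.5)
  kept <- ld_prune(ds, prune_spec(window_snps = 5, step_snps = 5,
                                  r2_max = 0.5))
  expect_identical(kept, ds$markers$id[keep_oracle])

  # invariant: no retained pair within a window exceeds the threshold
  r2 <- suppressWarnings(cor(ds$geno[, kept]))^2
  expect_true(all(r2[upper.tri(r2)] <= 0.5 + 1e-12))
})

test_that("pruning respects chromosome boundaries and window stepping", {
  set.seed(55)
  base <- sample(0:2, 40, TRUE)
  # same signal on two chromosomes: both copies kept (never co-windowed)
  g <- cbind(base, sample(0:2, 40, TRUE), base, sample(0:2, 40, TRUE))
  storage.mode(g) <- "integer"
  ds <- genotype_dataset(g, data.frame(id = paste0("m", 1:4),
                                       chrom = c("1", "1", "2", "2"),
                                       pos = c(10L, 20L, 10L, 20L),
                                       ref = "A", alt = "G"))
  kept <- ld_prune(ds, prune_spec(50, 5, 0.2))
  expect_true(all(c("m1", "m3") %in% kept))
  # unsorted markers are rejected
  ds_bad <- ds
  ds_bad$markers$pos <- c(20L, 10L, 10L, 20L)
  expect_error(ld_prune(ds_bad, prune_spec()), "sorted")
})

test_that("pi-hat is 1 for duplicates, ~0.5 for parent-offspring, ~0 for unrelated", {
  set.seed(77)
  m <- 5000
  p <- runif(m, 0.1, 0.9)
  # unrelated diploids drawn from Hardy-Weinberg at known frequencies
  n <- 20
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  # parent-offspring: child gets one transmitted allele from each parent
  transmit <- function(geno) ifelse(geno == 1L, rbinom(m, 1, 0.5), geno / 2L)
  child <- transmit(g[1, ]) + transmit(g[2, ])
  g <- rbind(g, g[1, ], child)  # row n+1 duplicates row 1
  storage.mode(g) <- "integer"
  ds <- genotype_dataset(g, data.frame(id = paste0("v", 1:m), chrom = "1",
                                       pos = 1:m, ref = "A", alt = "G"),
                         samples = c(paste0("u", 1:n), "dup1", "kid"))
  ib <- estimate_ibd(ds, pairs = rbind(c("u1", "dup1"),
                                       c("u1", "kid"),
                                       c("u3", "u4"),
                                       c("u5", "u17")),
                     freqs = p)
  expect_gt(ib$pihat[1], 0.98)
  expect_equal(ib$pihat[2], 0.5, tolerance = 0.05)
  expect_lt(abs(ib$pihat[3]), 0.05)
  expect_lt(abs(ib$pihat[4]), 0.05)
  # symmetry of the pair
  ib2 <- estimate_ibd(ds, pairs = rbind(c("dup1", "u1")), freqs = p)
  expect_equal(ib2$pihat, ib$pihat[1])
  # IBD probabilities remain a bounded simplex
  expect_true(all(ib[, c("k0", "k1", "k2")] >= 0 &
                  ib[, c("k0", "k1", "k2")] <= 1))
  expect_equal(ib$k0 + ib$k1 + ib$k2, rep(1, 4), tolerance = 1e-12)
})

test_that("unrelated pairs from a simulated population stay near pi-hat 0", {
  # many short loci give ~8k near-independent markers; the estimator is
  # bounded at zero, so unrelated pi-hat is half-normal: the mean sits near
  # zero and most observations fall inside the 0.05 band
  model <- demographic_model(
    populations = data.frame(name = "P", ne = 10000),
    splits = data.frame(time = numeric(), derived = character(),
                        ancestral = character()))
  vals <- c()
  for (rep in 1:10) {
    ds <- simulate_genotypes(model, n_loci = 6000, locus_length = 1000,
                             chroms_per_pop = c(P = 40), seed = 700 + rep)
    ds <- filter_markers(ds, 0.05)
    ib <- estimate_ibd(ds, pairs = rbind(c("P_1", "P_7"), c("P_3", "P_11")))
    vals <- c(vals, ib$pihat)
  }
  expect_lt(mean(abs(vals)), 0.035)
  expect_gte(mean(abs(vals) < 0.05), 0.7)
})

test_that("relatedness removal is greedy, deterministic and leaves no hot pairs", {
  # star graph: hub s1 related to everyone -> only the hub is removed
  ib_star <- data.frame(id1 = "s1", id2 = paste0("s", 2:5),
                        pihat = 0.6, stringsAsFactors = FALSE)
  cr <- setNames(rep(1, 5), paste0("s", 1:5))
  expect_identical(admixkit:::.greedy_related_removals(ib_star, 0.3, cr), "s1")

  # ties break by call rate then by later id
  ib_pair <- data.frame(id1 = "a", id2 = "b", pihat = 0.9)
  expect_identical(admixkit:::.greedy_related_removals(
    ib_pair, 0.3, c(a = 1, b = 1)), "b")
  expect_identical(admixkit:::.greedy_related_removals(
    ib_pair, 0.3, c(a = 0.9, b = 1)), "a")

  # random graphs match the independently coded oracle
  set.seed(13)
  ids <- paste0("s", 1:5)
  for (i in 1:30) {
    pairs <- t(combn(ids, 2))
    ph <- runif(10)
    ib <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2], pihat = ph)
    cr <- setNames(runif(5), ids)
    edges <- ib[ib$pihat > 0.3, c("id1", "id2")]
    expect_identical(admixkit:::.greedy_related_removals(ib, 0.3, cr),
                     oracle_greedy_removals(edges, cr))
  }
})

test_that("drop_related removes exactly one of a duplicated sample within its group", {
  set.seed(99)
  g <- matrix(rbinom(12 * 800, 2, 0.4), 12, 800)
  g[12, ] <- g[1, ]
  storage.mode(g) <- "integer"
  ds <- genotype_dataset(g, data.frame(id = paste0("v", 1:800), chrom = "1",
                                       pos = 1:800, ref = "A", alt = "G"),
                         samples = paste0("s", 1:12),
                         populations = rep(c("G1", "G2"), each = 6))
  # duplicate s12 sits in G2 with s1 in G1: per-group testing finds nothing
  out_grouped <- drop_related(ds, threshold = 0.3)
  expect_length(out_grouped$removed, 0)
  # as a single group the duplicate pair is broken by removing one member
  out_all <- drop_related(ds, threshold = 0.3, grouping = NULL)
  expect_length(out_all$removed, 1)
  expect_true(out_all$removed %in% c("s1", "s12"))
  # greedy invariant: no surviving pair exceeds the threshold under the
  # estimates the removal was based on
  expect_true(all(out_all$ibd$pihat[
    !(out_all$ibd$id1 %in% out_all$removed) &
    !(out_all$ibd$id2 %in% out_all$removed)] <= 0.3))
})
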