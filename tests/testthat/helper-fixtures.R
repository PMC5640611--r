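# Shared fixture builders and independent oracles used across the suite.
# All randomness is seeded by the caller.

rand_dataset <- function(n = 6, m = 20, seed = 1, miss = 0,
                         chroms = 2, pops = NULL) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) g[runif(n * m) < miss] <- NA_integer_
  chrom <- sort(rep_len(as.character(seq_len(chroms)), m))
  mk <- data.frame(id = sprintf("m%03d", seq_len(m)),
                   chrom = chrom,
                   pos = as.integer(stats::ave(seq_len(m), chrom,
                                               FUN = seq_along) * 100L),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_dataset(g, mk, samples = sprintf("s%02d", seq_len(n)),
                   populations = pops)
}

# two populations diverged 4N generations, equal Ne
two_pop_model <- function(ne = 10000, t_split = 40000) {
  demographic_model(
    populations = data.frame(name = c("ANC", "A", "B"), ne = ne),
    splits = data.frame(time = t_split, derived = c("A", "B"),
                        ancestral = "ANC"))
}

# X founded from A five generations ago as an (1 - alpha_a) pulse from B:
# an immediate two-source mixture with fraction alpha_a of A ancestry
mixture_model <- function(alpha_a = 0.5, ne = 10000, t_split = 40000) {
  demographic_model(
    populations = data.frame(name = c("ANC", "A", "B", "X"), ne = ne),
    splits = data.frame(time = c(t_split, t_split, 5),
                        derived = c("A", "B", "X"),
                        ancestral = c("ANC", "ANC", "A")),
    pulses = data.frame(source = "B", dest = "X", start_gen_bp = 5,
                        duration_gens = 1, rate_per_gen = 1 - alpha_a))
}

# five-population layout for F4-ratio recovery: outgroup OUT deepest, donor
# BM on its own branch, (W, I) sister pair, X = alpha*I + (1-alpha)*BM
f4ratio_model <- function(alpha, ne = 10000) {
  demographic_model(
    populations = data.frame(name = c("ANC", "OUT", "BM", "W", "I", "X"),
                             ne = ne),
    splits = data.frame(time = c(60000, 30000, 5000, 5000, 50),
                        derived = c("OUT", "BM", "W", "I", "X"),
                        ancestral = c("ANC", "ANC", "ANC", "ANC", "I")),
    pulses = data.frame(source = "BM", dest = "X", start_gen_bp = 50,
                        duration_gens = 1, rate_per_gen = 1 - alpha))
}

# unadmixed target T (sister of P1) plus five diverged source populations
null_scan_model <- function(ne = 10000) {
  demographic_model(
    populations = data.frame(name = c("ANC", paste0("P", 1:5), "T"),
                             ne = ne),
    splits = data.frame(time = c(60000, 50000, 40000, 35000, 30000, 15000),
                        derived = c("P1", "P2", "P3", "P4", "P5", "T"),
                        ancestral = c("ANC", "ANC", "ANC", "ANC", "ANC",
                                      "P1")))
}

# brute-force LD pruning oracle: same greedy rule as ld_prune but written
# independently as plain nested loops over a single window
oracle_prune_window <- function(g, maf, r2_max) {
  keep <- rep(TRUE, ncol(g))
  repeat {
    worst <- 0; wi <- wj <- 0
    for (i in seq_len(ncol(g) - 1)) for (j in (i + 1):ncol(g)) {
      if (!keep[i] || !keep[j]) next
      r2 <- suppressWarnings(cor(g[, i], g[, j],
                                 use = "pairwise.complete.obs"))^2
      if (is.finite(r2) && r2 > r2_max && r2 > worst) {
        worst <- r2; wi <- i; wj <- j
      }
    }
    if (wi == 0) break
    drop <- if (maf[wi] < maf[wj]) wi else if (maf[wj] < maf[wi]) wj else wj
    keep[drop] <- FALSE
  }
  keep
}

# greedy vertex-removal oracle on a relatedness graph given as an edge list
oracle_greedy_removals <- function(edges, call_rates) {
  removed <- character(0)
  while (nrow(edges) > 0) {
    deg <- table(c(edges[[1]], edges[[2]]))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) cand <- cand[call_rates[cand] == min(call_rates[cand])]
    victim <- sort(cand, decreasing = TRUE)[1]
    removed <- c(removed, victim)
    edges <- edges[edges[[1]] != victim & edges[[2]] != victim, , drop = FALSE]
  }
  removed
}

# all unrooted 4-taxon topologies as rooted-on-outgroup phylo objects
four_taxon_topologies <- function(taxa, outgroup) {
  others <- setdiff(taxa, outgroup)
  lapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p) {
    pair <- others[p]
    rest <- setdiff(others, pair)
    ape::read.tree(text = sprintf("((%s,%s),%s,%s);", pair[1], pair[2],
                                  rest, outgroup))
  })
}
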