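#' Pairwise f2 drift-distance matrix
#'
#' Computes `f2` (with the sampling-noise corrections for both populations)
#' for every pair, with block-jackknife SEs. Negative point estimates —
#' possible from sampling noise — are clamped to 0 with a message.
#'
#' @param freqs a [freq_table()] with at least 3 populations.
#' @param block_size jackknife block size in SNPs.
#' @return a `drift_matrix`: list with `populations`, `d` (symmetric f2
#'   matrix, zero diagonal) and `se`.
#' @export
f2_matrix <- function(freqs, block_size = 200L) {
  pops <- freqs$populations
  if (length(pops) < 3) stop("need at least 3 populations")
  k <- length(pops)
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  se <- matrix(0, k, k, dimnames = list(pops, pops))
  n_clamped <- 0L

  ok <- colSums(is.na(freqs$freq)) == 0 & colSums(freqs$count < 2) == 0
  if (all(ok)) {
    # fast path: every SNP complete in every population, so all pairs share
    # the same SNP set and the per-block pair sums come from one
    # cross-product per block
    F <- freqs$freq
    H <- F * (1 - F) / (freqs$count - 1)
    H[!is.finite(H)] <- 0             # infinite counts: exact frequencies
    block <- .block_index(ncol(F), block_size)
    g <- max(block)
    m <- tabulate(block)
    C <- array(0, c(k, k, g))
    q <- matrix(0, k, g); h <- matrix(0, k, g)
    for (b in seq_len(g)) {
      idx <- which(block == b)
      Fb <- F[, idx, drop = FALSE]
      C[, , b] <- tcrossprod(Fb)
      q[, b] <- rowSums(Fb^2)
      h[, b] <- rowSums(H[, idx, drop = FALSE])
    }
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      bn <- q[i, ] + q[j, ] - 2 * C[i, j, ] - h[i, ] - h[j, ]
      jk <- .jackknife_blocks(bn, m, m)
      est <- jk$estimate
      if (est < 0) { est <- 0; n_clamped <- n_clamped + 1L }
      d[i, j] <- d[j, i] <- est
      se[i, j] <- se[j, i] <- jk$se
    }
  } else {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      r <- f2(freqs, pops[i], pops[j], block_size)
      est <- r$estimate
      if (est < 0) { est <- 0; n_clamped <- n_clamped + 1L }
      d[i, j] <- d[j, i] <- est
      se[i, j] <- se[j, i] <- r$se
    }
  }
  if (n_clamped > 0)
    message(sprintf("f2_matrix: clamped %d negative estimate(s) to 0",
                    n_clamped))
  structure(list(populations = pops, d = d, se = se),
            class = "drift_matrix")
}

#' Neighbour-joining population tree rooted on an outgroup
#'
#' Builds the tree by neighbour joining on the f2 drift distances (labels
#' are sorted internally so the topology does not depend on input order),
#' floors negative NJ branch lengths at 0, and roots the tree by splitting
#' the outgroup's pendant edge at its midpoint.
#'
#' @param dm a `drift_matrix` from [f2_matrix()] (or any symmetric distance
#'   matrix with population dimnames wrapped in `list(populations=, d=)`).
#' @param outgroup population label to root on.
#' @return a rooted `phylo` tree (ape) with attribute `"outgroup"`.
#' @export
build_tree <- function(dm, outgroup) {
  pops <- sort(dm$populations)
  if (length(pops) < 3) stop("need at least 3 populations to build a tree")
  if (!outgroup %in% pops) stop("outgroup not among the populations")
  d <- dm$d[pops, pops]
  phy <- ape::nj(as.dist(d))
  phy$edge.length[phy$edge.length < 0] <- 0
  phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  # split the outgroup edge at its midpoint
  root_node <- ape::Ntip(phy) + 1L
  kids <- which(phy$edge[, 1] == root_node)
  og_tip <- match(outgroup, phy$tip.label)
  og_edge <- kids[phy$edge[kids, 2] == og_tip]
  if (length(og_edge) == 1 && length(kids) == 2) {
    other <- setdiff(kids, og_edge)
    half <- phy$edge.length[og_edge] / 2
    phy$edge.length[og_edge] <- half
    phy$edge.length[other] <- phy$edge.length[other] + half
  }
  attr(phy, "outgroup") <- outgroup
  phy
}

# leaf-pair x edge incidence matrix of a phylo tree: entry 1 when the edge
# lies on the path between the two leaves
.path_incidence <- function(phy) {
  nt <- ape::Ntip(phy)
  desc <- vector("list", max(phy$edge))
  for (i in seq_len(nt)) desc[[i]] <- i
  # accumulate tip descendants child-edges-first (postorder traversal)
  for (e in ape::postorder(phy)) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  pairs <- t(combn(nt, 2))
  inc <- matrix(0, nrow(pairs), nrow(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    s <- desc[[phy$edge[e, 2]]]
    in_s <- matrix(pairs %in% s, nrow(pairs), 2)
    inc[, e] <- as.numeric(xor(in_s[, 1], in_s[, 2]))
  }
  list(pairs = pairs, incidence = inc)
}

#' Fraction of drift variance explained by a tree topology
#'
#' Refits the branch lengths of `tree` to the pairwise drift distances by
#' non-negative least squares on the path-incidence system and returns
#' `1 - SS_residual / SS_total`, with `SS_total` taken about the mean
#' pairwise distance. The residual matrix (observed minus fitted) is
#' attached as attribute `"residuals"`; the refitted tree as `"fitted_tree"`.
#'
#' @param tree a rooted `phylo` whose tips match `dm$populations`.
#' @param dm a `drift_matrix`.
#' @return scalar in `[0, 1]` (can be slightly negative for a grotesquely
#'   wrong topology).
#' @export
variance_explained <- function(tree, dm) {
  tips <- tree$tip.label
  if (!setequal(tips, dm$populations))
    stop("tree tips and drift-matrix populations differ")
  pi <- .path_incidence(tree)
  dobs <- dm$d[tips, tips]
  y <- dobs[pi$pairs]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("degenerate distance matrix: no variance to explain")
  fit <- pracma::lsqnonneg(pi$incidence, y)
  yhat <- as.numeric(pi$incidence %*% fit$x)
  ve <- 1 - sum((y - yhat)^2) / sst
  res <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  res[pi$pairs] <- y - yhat
  res[pi$pairs[, 2:1, drop = FALSE]] <- y - yhat
  ftree <- tree
  ftree$edge.length <- fit$x
  attr(ve, "residuals") <- res
  attr(ve, "fitted_tree") <- ftree
  ve
}

#' Classify the placement of one population group relative to another
#'
#' Decides whether a group of populations (e.g. the European wild boar
#' groups) sits beside the other group (e.g. the European domestic breeds)
#' as a separate clade, or is buried inside its radiation. Walking rootward
#' from the most recent common ancestor of `group_a`, each successive
#' sister subtree consisting of a single `group_b` tip is one "interleaved"
#' population — a population individually closer to the `group_a` clade
#' than the rest of its own group, the signature expected when it received
#' ancestry from `group_a`. The walk stops at the first sister that is not
#' a lone `group_b` tip. Placement is classified as `"nested"` when
#' `group_a` is not monophyletic or when at least `min_interleaved` members
#' of `group_b` interleave; otherwise `"separate"`.
#'
#' @param tree a rooted `phylo`.
#' @param group_a,group_b character vectors of tip labels.
#' @param min_interleaved interleaving count at which the placement is
#'   called nested (default 2: a single adjacent population can reflect
#'   estimation noise, two or more independent interleavings cannot).
#' @return list with `placement` ("separate" or "nested"),
#'   `monophyletic_a`, `interleaved` (count) and `sister` (tip labels of
#'   the first sister subtree).
#' @export
classify_group_placement <- function(tree, group_a, group_b,
                                     min_interleaved = 2L) {
  stopifnot(all(c(group_a, group_b) %in% tree$tip.label))
  nt <- ape::Ntip(tree)
  mono <- ape::is.monophyletic(tree, group_a)
  tips_below <- function(node) {
    if (node <= nt) tree$tip.label[node]
    else ape::extract.clade(tree, node)$tip.label
  }
  node <- ape::getMRCA(tree, group_a)
  first_sister <- NULL
  inter <- 0L
  if (mono) {
    root <- nt + 1L
    while (node != root) {
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      if (length(parent) != 1) break
      sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], node)
      sib_tips <- unlist(lapply(sibs, tips_below))
      if (is.null(first_sister)) first_sister <- sib_tips
      if (length(sib_tips) == 1 && sib_tips %in% group_b) {
        inter <- inter + 1L
        node <- parent
      } else break
    }
  }
  placement <- if (!mono || inter >= min_interleaved) "nested" else "separate"
  list(placement = placement, monophyletic_a = mono,
       interleaved = inter, sister = first_sister)
}

#' Write a population tree as Newick
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
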