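#' Simulate SNP genotypes under a demographic model
#'
#' Simulates `n_loci` independent non-recombining regions under the
#' structured coalescent defined by `model` (population splits, constant
#' per-population diploid Ne, and discrete per-generation migration
#' pulses), drops infinite-sites mutations at rate
#' `model$mutation_rate * locus_length` per branch-generation, pairs
#' consecutive chromosomes within each population into diploids and
#' concatenates the loci into one [genotype_dataset()] (each locus becomes
#' one "chromosome", so jackknife blocks spanning several loci are
#' independent). Monomorphic sites are excluded. Intra-locus recombination
#' is not modelled; `subloci > 1` splits each region into that many
#' independently simulated sub-loci as an approximation.
#'
#' @param model a [demographic_model()].
#' @param n_loci number of independent regions.
#' @param locus_length region length in bp.
#' @param chroms_per_pop haploid sample size per population: a single even
#'   number applied to every leaf population (see [leaf_populations()]), or
#'   a named vector over any subset of the model's populations.
#' @param seed integer seed (all randomness is derived from it).
#' @param subloci independent sub-loci per region (1 = none).
#' @param keep_haplotypes attach the haploid 0/1 matrix as attribute
#'   `"haplotypes"`.
#' @return a `genotype_dataset` with populations attached and attributes:
#'   `"origin"` (data.frame per chromosome: population, and the pulse
#'   source population its lineage most recently arrived from, NA if none),
#'   `"locus"` (marker-to-locus index), and optionally `"haplotypes"`.
#' @export
simulate_genotypes <- function(model, n_loci = 100L, locus_length = 50000L,
                               chroms_per_pop = 40L, seed = 1L,
                               subloci = 1L, keep_haplotypes = FALSE) {
  stopifnot(inherits(model, "demographic_model"))
  leaves <- leaf_populations(model)
  if (is.null(names(chroms_per_pop))) {
    nchr <- setNames(rep(chroms_per_pop[1], length(leaves)), leaves)
  } else {
    if (!all(names(chroms_per_pop) %in% model$populations$name))
      stop("chroms_per_pop names must be model populations")
    nchr <- chroms_per_pop[chroms_per_pop > 0]
  }
  if (any(nchr %% 2 != 0)) stop("chromosomes per population must be even")

  pop_names <- model$populations$name
  pop_ne <- model$populations$ne
  sample_pop <- rep(match(names(nchr), pop_names), nchr) - 1L

  events <- .event_matrix(model, pop_names)
  theta <- model$mutation_rate * locus_length / max(1L, subloci)
  n_chr <- sum(nchr)
  n_rep <- n_loci * subloci

  set.seed(seed)
  odd <- seq(1, n_chr, by = 2)
  per_locus <- vector("list", n_rep)   # dosage pieces, one per locus
  pos_list <- vector("list", n_rep)
  origin_votes <- matrix(0L, n_chr, length(pop_names))
  origin_n <- 0L
  haps <- if (keep_haplotypes) vector("list", n_rep) else NULL
  for (l in seq_len(n_rep)) {
    r <- .sim_locus(sample_pop, pop_ne, events, theta)
    h <- r$hap
    s <- ncol(h)
    if (s > 0) {
      cs <- colSums(h)
      poly <- cs > 0L & cs < n_chr
      h <- h[, poly, drop = FALSE]
      s <- ncol(h)
    }
    per_locus[[l]] <- h[odd, , drop = FALSE] + h[odd + 1, , drop = FALSE]
    pos_list[[l]] <- if (s == 0) integer(0)
                     else sort(sample.int(max(locus_length, s), s))
    if (keep_haplotypes) haps[[l]] <- h
    og <- r$origin
    hit <- og >= 0
    if (any(hit))
      origin_votes[cbind(which(hit), og[hit] + 1L)] <-
        origin_votes[cbind(which(hit), og[hit] + 1L)] + 1L
    origin_n <- origin_n + 1L
  }

  geno <- do.call(cbind, per_locus)
  locus_of <- rep(seq_len(n_rep), vapply(per_locus, ncol, integer(1)))
  pos <- unlist(pos_list)
  per_locus <- NULL
  chrom <- sprintf("L%04d", locus_of)
  markers <- data.frame(id = sprintf("%s_%d", chrom, pos),
                        chrom = chrom, pos = pos, ref = "A", alt = "G",
                        stringsAsFactors = FALSE)
  dup <- duplicated(markers$id)
  if (any(dup)) {
    geno <- geno[, !dup, drop = FALSE]
    markers <- markers[!dup, , drop = FALSE]
    locus_of <- locus_of[!dup]
  }

  pop_per_chr <- rep(names(nchr), nchr)
  pop_per_ind <- pop_per_chr[odd]
  within_idx <- stats::ave(seq_along(pop_per_ind), pop_per_ind,
                           FUN = seq_along)
  ids <- paste0(pop_per_ind, "_", within_idx)

  ds <- genotype_dataset(geno, markers, samples = ids,
                         populations = pop_per_ind)
  # per-chromosome migrant-origin summary: fraction of loci on which the
  # lineage arrived through a pulse, by source population
  of <- origin_votes / origin_n
  colnames(of) <- pop_names
  attr(ds, "origin") <- data.frame(chromosome = seq_len(n_chr),
                                   population = pop_per_chr,
                                   of, check.names = FALSE)
  attr(ds, "locus") <- locus_of
  if (keep_haplotypes) {
    h <- do.call(cbind, haps)
    if (any(dup)) h <- h[, !dup, drop = FALSE]
    attr(ds, "haplotypes") <- h
  }
  ds
}

# encode splits and per-generation pulse events for the C++ core:
# matrix columns (time, type, a, b, rate); type 0 = pulse (a dest, b source),
# type 1 = split (a derived, b ancestral); 0-based population indices;
# sorted by time with pulses before splits at ties
.event_matrix <- function(model, pop_names) {
  sp <- model$splits
  ev <- matrix(numeric(0), 0, 5,
               dimnames = list(NULL, c("time", "type", "a", "b", "rate")))
  if (nrow(sp) > 0)
    ev <- cbind(time = sp$time, type = 1,
                a = match(sp$derived, pop_names) - 1L,
                b = match(sp$ancestral, pop_names) - 1L,
                rate = 0)
  if (!is.null(model$pulses)) {
    pl <- model$pulses
    gens <- lapply(seq_len(nrow(pl)), function(i) {
      g <- seq(pl$start_gen_bp[i] - pl$duration_gens[i] + 1L,
               pl$start_gen_bp[i])
      cbind(time = g, type = 0,
            a = match(pl$dest[i], pop_names) - 1L,
            b = match(pl$source[i], pop_names) - 1L,
            rate = pl$rate_per_gen[i])
    })
    ev <- rbind(ev, do.call(rbind, gens))
  }
  ev[order(ev[, "time"], ev[, "type"]), , drop = FALSE]
}

#' Write a simulated dataset plus its population map
#'
#' @param ds a [genotype_dataset()] with populations attached.
#' @param path output prefix; writes the genotype files and
#'   `<path>.populations.tsv`.
#' @param format `"plink"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
export_fixture <- function(ds, path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (is.null(ds$populations)) stop("dataset has no population labels")
  if (format == "plink") write_plink(ds, path)
  else write_vcf(ds, paste0(path, ".vcf"))
  write_population_map(dataset_population_map(ds),
                       paste0(path, ".populations.tsv"))
  invisible(path)
}

#' Construct F1 hybrid individuals from simulated haplotypes
#'
#' Pairs one haploid chromosome from each of two populations into new
#' diploid samples (Mendelian F1s), appending them to the dataset. Requires
#' a dataset simulated with `keep_haplotypes = TRUE`.
#'
#' @param ds dataset from [simulate_genotypes()] with haplotypes attached.
#' @param pop_a,pop_b parental populations.
#' @param n number of hybrids (uses the first `2n` chromosomes of each
#'   parental population, one per hybrid).
#' @param label population label for the hybrids.
#' @return the extended `genotype_dataset`.
#' @export
make_f1_hybrids <- function(ds, pop_a, pop_b, n, label = "F1") {
  h <- attr(ds, "haplotypes")
  if (is.null(h)) stop("dataset lacks haplotypes; simulate with keep_haplotypes = TRUE")
  org <- attr(ds, "origin")
  ia <- which(org$population == pop_a)[seq_len(n)]
  ib <- which(org$population == pop_b)[seq_len(n)]
  if (anyNA(ia) || anyNA(ib)) stop("not enough chromosomes in a parental population")
  gh <- h[ia, , drop = FALSE] + h[ib, , drop = FALSE]
  geno <- rbind(ds$geno, gh)
  genotype_dataset(geno, ds$markers,
                   samples = c(ds$samples, paste0(label, "_", seq_len(n))),
                   populations = c(ds$populations, rep(label, n)))
}
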