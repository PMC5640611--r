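#' Merge genotype datasets on their common markers
#'
#' Markers are intersected by id across all datasets and harmonised to the
#' first dataset's (ref, alt) orientation: where a later dataset stores the
#' same pair of alleles swapped, its dosages are flipped (`d -> 2 - d`);
#' markers whose allele pairs neither match nor swap are dropped (counted
#' in a message). Sample ids are namespaced `"<tag>:<id>"` so sources with
#' overlapping ids remain distinct. Markers observed fixed (all non-missing
#' dosages 0, or all 2) across the merged dataset are removed. The result
#' is sorted by (chromosome, position).
#'
#' Strand-ambiguous (A/T, C/G) markers whose alleles match either
#' orientation are kept in the first dataset's orientation; no strand
#' flipping is attempted.
#'
#' @param ds_list list of at least two [genotype_dataset()] objects.
#' @param source_tags character vector of source labels used to namespace
#'   sample ids; defaults to `names(ds_list)` or `"d1", "d2", ...`.
#' @return the merged [genotype_dataset()].
#' @export
merge_datasets <- function(ds_list, source_tags = names(ds_list)) {
  if (length(ds_list) < 2) stop("need at least two datasets to merge")
  if (is.null(source_tags))
    source_tags <- paste0("d", seq_along(ds_list))
  stopifnot(length(source_tags) == length(ds_list))

  ids <- Reduce(intersect, lapply(ds_list, function(d) d$markers$id))
  if (length(ids) == 0L) stop("merge error: no markers common to all datasets")

  ref_mk <- ds_list[[1]]$markers
  ref_mk <- ref_mk[match(ids, ref_mk$id), ]

  parts <- vector("list", length(ds_list))
  ok_all <- rep(TRUE, length(ids))
  for (i in seq_along(ds_list)) {
    d <- ds_list[[i]]
    j <- match(ids, d$markers$id)
    g <- d$geno[, j, drop = FALSE]
    same <- d$markers$ref[j] == ref_mk$ref & d$markers$alt[j] == ref_mk$alt
    swap <- d$markers$ref[j] == ref_mk$alt & d$markers$alt[j] == ref_mk$ref
    if (any(swap)) g[, swap] <- 2L - g[, swap, drop = FALSE]
    ok_all <- ok_all & (same | swap)
    parts[[i]] <- g
  }
  n_conflict <- sum(!ok_all)
  if (n_conflict > 0)
    message(sprintf("merge_datasets: dropped %d marker(s) with irreconcilable alleles",
                    n_conflict))
  if (!any(ok_all)) stop("merge error: no markers left after allele harmonisation")

  geno <- do.call(rbind, lapply(parts, function(g) g[, ok_all, drop = FALSE]))
  samples <- unlist(mapply(function(d, tag) paste0(tag, ":", d$samples),
                           ds_list, source_tags, SIMPLIFY = FALSE))
  pops <- unlist(lapply(ds_list, function(d)
    if (is.null(d$populations)) rep(NA_character_, length(d$samples))
    else d$populations))
  if (all(is.na(pops))) pops <- NULL

  mk <- ref_mk[ok_all, , drop = FALSE]
  out <- genotype_dataset(geno, mk, samples = samples, populations = pops)

  f <- marker_freq(out)
  fixed <- !is.na(f) & (f == 0 | f == 1)
  if (any(fixed)) {
    message(sprintf("merge_datasets: removed %d marker(s) fixed in the merged dataset",
                    sum(fixed)))
    if (all(fixed)) stop("merge error: all common markers are fixed")
    out <- subset_dataset(out, markers = which(!fixed))
  }
  sort_markers(out)
}
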