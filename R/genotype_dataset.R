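#' Diploid SNP genotype dataset
#'
#' The central container of the package: a samples x markers matrix of
#' alternate-allele dosages in \{0, 1, 2, NA\} plus marker metadata and,
#' optionally, a population label per sample.
#'
#' @param geno integer matrix, samples in rows and markers in columns;
#'   entries must be 0, 1, 2 or NA (missing genotype).
#' @param markers data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per marker, in column order of `geno`.
#' @param samples character vector of sample ids; defaults to
#'   `rownames(geno)`.
#' @param populations optional character vector of population labels,
#'   parallel to `samples`.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `geno`, `markers`, `samples` and `populations`.
#' @export
genotype_dataset <- function(geno, markers, samples = rownames(geno),
                             populations = NULL) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(geno)))
  samples <- as.character(samples)
  stopifnot(length(samples) == nrow(geno))
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(markers)))
    stop("markers must have columns id, chrom, pos, ref, alt")
  markers <- markers[, req]
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  markers$ref <- as.character(markers$ref)
  markers$alt <- as.character(markers$alt)
  if (nrow(markers) != ncol(geno))
    stop("marker table and genotype matrix disagree on marker count")
  if (anyDuplicated(markers$id))
    stop("marker ids must be unique")
  if (any(markers$pos < 1L, na.rm = TRUE))
    stop("marker positions must be >= 1")
  if (any(markers$ref == markers$alt))
    stop("ref and alt allele must differ")
  rng <- if (anyNA(geno)) suppressWarnings(range(geno, na.rm = TRUE))
         else range(geno)
  if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (!is.null(populations)) {
    populations <- as.character(populations)
    stopifnot(length(populations) == length(samples))
  }
  dimnames(geno) <- list(samples, markers$id)
  structure(list(geno = geno, markers = markers, samples = samples,
                 populations = populations),
            class = "genotype_dataset")
}

#' @method print genotype_dataset
#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d markers\n",
              length(x$samples), nrow(x$markers)))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  chromosomes: %d; missingness: %.2f%%\n",
              length(unique(x$markers$chrom)), 100 * miss))
  if (!is.null(x$populations))
    cat(sprintf("  populations: %s\n",
                paste(unique(x$populations), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)

#' Subset a genotype dataset
#'
#' @param ds a [genotype_dataset()].
#' @param samples sample ids or logical/integer index to keep.
#' @param markers marker ids or logical/integer index to keep.
#' @return the restricted `genotype_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, markers = NULL) {
  si <- seq_along(ds$samples)
  mi <- seq_len(nrow(ds$markers))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, ds$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id in subset")
  }
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, ds$markers$id) else mi[markers]
    if (anyNA(mi)) stop("unknown marker id in subset")
  }
  if (length(si) == 0L) stop("subset removes all samples")
  if (length(mi) == 0L) stop("subset removes all markers")
  genotype_dataset(ds$geno[si, mi, drop = FALSE],
                   ds$markers[mi, , drop = FALSE],
                   samples = ds$samples[si],
                   populations = if (is.null(ds$populations)) NULL
                                 else ds$populations[si])
}

#' Sort markers by chromosome and position
#'
#' @param ds a [genotype_dataset()].
#' @return the dataset with markers ordered by (chrom, pos).
#' @export
sort_markers <- function(ds) {
  o <- order(ds$markers$chrom, ds$markers$pos, ds$markers$id)
  if (identical(o, seq_len(nrow(ds$markers)))) return(ds)
  subset_dataset(ds, markers = o)
}

#' Per-sample genotype call rate
#' @param ds a [genotype_dataset()].
#' @return named numeric vector, fraction of non-missing genotypes.
#' @export
sample_call_rate <- function(ds) {
  setNames(rowMeans(!is.na(ds$geno)), ds$samples)
}

#' Per-marker alternate-allele frequency over the whole dataset
#' @param ds a [genotype_dataset()].
#' @return named numeric vector (NA for fully missing markers).
#' @export
marker_freq <- function(ds) {
  n <- 2 * colSums(!is.na(ds$geno))
  f <- colSums(ds$geno, na.rm = TRUE) / n
  f[n == 0] <- NA_real_
  setNames(f, ds$markers$id)
}
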