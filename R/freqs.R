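#' Per-population allele frequency table
#'
#' For every population and marker, the alternate-allele sample frequency
#' and the number of non-missing allele copies (2 x genotyped diploids) it
#' is based on. A count of 0 means the marker is masked (frequency
#' undefined) for that population.
#'
#' @param ds a [genotype_dataset()].
#' @param map a [population_map()]; defaults to the dataset's attached
#'   population labels.
#' @return a `freq_table`: list with `populations`, `freq` (pop x marker),
#'   `count` (pop x marker) and `markers` (the marker metadata).
#' @export
allele_freqs <- function(ds, map = NULL) {
  if (!is.null(map)) ds <- apply_population_map(ds, map)
  if (is.null(ds$populations)) stop("no population assignment available")
  pops <- unique(ds$populations)
  grp <- factor(ds$populations, levels = pops)
  g <- ds$geno
  if (anyNA(g)) {
    obs <- !is.na(g)
    g0 <- g; g0[!obs] <- 0L
    alt <- rowsum(g0, grp, reorder = FALSE)
    ct <- 2 * rowsum(obs + 0L, grp, reorder = FALSE)
  } else {
    alt <- rowsum(g, grp, reorder = FALSE)
    ct <- matrix(2 * tabulate(grp), length(pops), ncol(g))
  }
  fr <- alt / ct
  fr[ct == 0] <- NA_real_
  dimnames(fr) <- list(pops, ds$markers$id)
  dimnames(ct) <- dimnames(fr)
  freq_table(fr, ct, ds$markers)
}

#' @rdname allele_freqs
#' @param freq populations x markers matrix of alternate-allele frequencies
#'   (rownames = population labels).
#' @param count matching matrix of allele-copy counts; use `Inf` for exact
#'   population-level frequencies (no sampling-noise correction applied).
#' @param markers optional marker metadata; a minimal table (single
#'   chromosome, consecutive positions) is fabricated when absent.
#' @export
freq_table <- function(freq, count = NULL, markers = NULL) {
  freq <- as.matrix(freq)
  if (is.null(rownames(freq))) stop("freq needs population labels as rownames")
  if (is.null(count)) count <- matrix(Inf, nrow(freq), ncol(freq))
  count <- as.matrix(count)
  stopifnot(identical(dim(freq), dim(count)))
  dimnames(count) <- dimnames(freq)
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  if (is.null(markers)) {
    markers <- data.frame(id = if (is.null(colnames(freq)))
                                 paste0("snp", seq_len(ncol(freq)))
                               else colnames(freq),
                          chrom = "1", pos = seq_len(ncol(freq)),
                          ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  structure(list(populations = rownames(freq), freq = freq, count = count,
                 markers = markers),
            class = "freq_table")
}

#' @method print freq_table
#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d populations x %d markers\n",
              length(x$populations), ncol(x$freq)))
  invisible(x)
}

.check_pops <- function(freqs, pops) {
  miss <- setdiff(pops, freqs$populations)
  if (length(miss))
    stop("population(s) not in frequency table: ", paste(miss, collapse = ", "))
}
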