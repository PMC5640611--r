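# PLINK-1 binary triplet (bed/bim/fam) codec.
#
# .bed is SNP-major: after the magic bytes 0x6c 0x1b 0x01, each marker
# occupies ceiling(n/4) bytes, two bits per sample, the first sample in
# the lowest-order bits. Codes: 00 = homozygous A1, 01 = missing,
# 10 = heterozygous, 11 = homozygous A2. We store the alternate allele
# as A1, so dosage(alt) maps 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: dosages encoded by each byte value
.bed_decode_table <- local({
  code2dose <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11
  tab <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      tab[b + 1L, k] <- code2dose[(v %% 4L) + 1L]
      v <- v %/% 4L
    }
  }
  tab
})

#' Read a genotype dataset
#'
#' @param path for PLINK, the triplet prefix (or any of the three file
#'   names); for VCF, the file path.
#' @param format `"plink"` or `"vcf"`.
#' @return a [genotype_dataset()]; for PLINK input the `fam` family id is
#'   attached as `populations` when it is informative (not all "0").
#' @export
read_dataset <- function(path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") read_plink(path) else read_vcf(path)
}

#' Write a genotype dataset
#'
#' @param ds a [genotype_dataset()].
#' @param path PLINK prefix or VCF file path.
#' @param format `"plink"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") write_plink(ds, path) else write_vcf(ds, path)
}

#' @rdname read_dataset
#' @export
read_plink <- function(path) {
  prefix <- sub("\\.(bed|bim|fam)$", "", path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)

  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(fam_df) < 6) stop("malformed fam file (expected 6 columns): ", fam)
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bim_df) != 6) stop("malformed bim file (expected 6 columns): ", bim)
  n <- nrow(fam_df); m <- nrow(bim_df)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], .bed_magic))
    stop("malformed bed file (bad magic bytes): ", bed)
  bpm <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpm * m)
    stop("bed/bim/fam size mismatch in ", bed,
         sprintf(" (expected %d bytes, found %d)", bpm * m, length(body)))

  dose <- .bed_decode_table[as.integer(body) + 1L, , drop = FALSE]
  dose <- matrix(t(dose), nrow = 4L * bpm)   # (4*bpm) x m, samples down rows
  geno <- t(dose[seq_len(n), , drop = FALSE])  # m x n -> transpose below

  markers <- data.frame(id = as.character(bim_df[[2]]),
                        chrom = as.character(bim_df[[1]]),
                        pos = as.integer(bim_df[[4]]),
                        ref = as.character(bim_df[[6]]),
                        alt = as.character(bim_df[[5]]),
                        stringsAsFactors = FALSE)
  fid <- as.character(fam_df[[1]])
  pops <- if (all(fid == "0") || all(fid == fam_df[[2]])) NULL else fid
  genotype_dataset(t(geno), markers, samples = as.character(fam_df[[2]]),
                   populations = pops)
}

#' @rdname write_dataset
#' @export
write_plink <- function(ds, path) {
  if (nrow(ds$markers) == 0L || length(ds$samples) == 0L)
    stop("refusing to write an empty dataset")
  prefix <- sub("\\.(bed|bim|fam)$", "", path)
  n <- length(ds$samples)

  fid <- if (is.null(ds$populations)) rep("0", n) else ds$populations
  write.table(data.frame(fid, ds$samples, 0L, 0L, 0L, -9L),
              paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(ds$markers$chrom, ds$markers$id, 0L,
                         ds$markers$pos, ds$markers$alt, ds$markers$ref),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code: 2 -> 0, NA -> 1, 1 -> 2, 0 -> 3
  code <- matrix(3L, nrow = 4L * ceiling(n / 4), ncol = nrow(ds$markers))
  g <- t(ds$geno)                       # markers x samples -> by sample rows
  cd <- 3L - g                          # 0->3, 1->2, 2->0? (2 -> 1) fix below
  cd[g == 2L] <- 0L
  cd[is.na(g)] <- 1L
  code[seq_len(n), ] <- t(cd)
  pow <- c(1L, 4L, 16L, 64L)
  dim(code) <- c(4L, length(code) / 4L)
  bytes <- as.raw(colSums(code * pow))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(bytes, con)
  invisible(prefix)
}
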