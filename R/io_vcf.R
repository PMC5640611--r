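#' @rdname read_dataset
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("missing VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  nt <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nt & fix$ALT %in% nt
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("read_vcf: dropped %d multi-allelic/non-SNP record(s)",
                    n_drop))
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dose <- (a1 == "1") + (a2 == "1")
  dose[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  storage.mode(dose) <- "integer"

  id <- fix$ID
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  markers <- data.frame(id = id, chrom = fix$CHROM,
                        pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  genotype_dataset(t(dose), markers, samples = colnames(gt))
}

#' @rdname write_dataset
#' @export
write_vcf <- function(ds, path) {
  if (nrow(ds$markers) == 0L || length(ds$samples) == 0L)
    stop("refusing to write an empty dataset")
  gt_char <- c("0/0", "0/1", "1/1")
  g <- ds$geno
  gt <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  gt[ok] <- gt_char[g[ok] + 1L]
  body <- apply(gt, 2, paste, collapse = "\t")   # one string per marker
  m <- ds$markers
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=admixkit",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", ds$samples), collapse = "\t"),
    paste(m$chrom, m$pos, m$id, m$ref, m$alt, ".", "PASS", ".", "GT",
          body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
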