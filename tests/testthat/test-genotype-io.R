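test_that("PLINK and VCF round trips are the identity, including missingness", {
  ds <- rand_dataset(n = 5, m = 24, seed = 11, miss = 0.1,
                     pops = rep(c("P1", "P2"), c(2, 3)))
  td <- withr::local_tempdir()

  write_dataset(ds, file.path(td, "rt"), "plink")
  r <- read_dataset(file.path(td, "rt"), "plink")
  expect_identical(unname(r$geno), unname(ds$geno))
  expect_identical(r$markers, ds$markers)
  expect_identical(r$samples, ds$samples)
  expect_identical(r$populations, ds$populations)

  write_dataset(ds, file.path(td, "rt.vcf"), "vcf")
  v <- read_dataset(file.path(td, "rt.vcf"), "vcf")
  expect_identical(unname(v$geno), unname(ds$geno))
  expect_identical(v$markers, ds$markers)
  expect_identical(v$samples, ds$samples)

  # round trip also for a sample count not divisible by 4 (bed padding)
  ds8 <- rand_dataset(n = 8, m = 7, seed = 3, miss = 0.2)
  write_plink(ds8, file.path(td, "p8"))
  expect_identical(unname(read_plink(file.path(td, "p8"))$geno),
                   unname(ds8$geno))
})

test_that("VCF reader applies the missing and biallelic-SNP conventions", {
  td <- withr::local_tempdir()
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
             "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.",
             "1\t200\tv2\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/1",   # tri-allelic
             "1\t300\tv3\tAT\tG\t.\tPASS\t.\tGT\t0/0\t1/1",    # indel
             "1\t400\tv4\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0")     # phased
  writeLines(lines, file.path(td, "mixed.vcf"))
  expect_message(ds <- read_vcf(file.path(td, "mixed.vcf")), "dropped 2")
  expect_equal(ds$markers$id, c("v1", "v4"))
  expect_identical(ds$geno["s1", ], c(v1 = 1L, v4 = 2L))
  expect_true(is.na(ds$geno["s2", "v1"]))
})

test_that("writers refuse empty datasets and bad paths error", {
  ds <- rand_dataset(4, 6, seed = 2)
  empty <- ds
  empty$markers <- ds$markers[0, ]
  empty$geno <- ds$geno[, 0, drop = FALSE]
  expect_error(write_plink(empty, tempfile()), "empty")
  expect_error(write_vcf(empty, tempfile()), "empty")
  expect_error(read_plink("/no/such/prefix"), "missing")
})

test_that("merge intersects marker ids and harmonises swapped alleles", {
  # marker stored as (A,G) in one source, (G,A) in the other:
  # the second source's dosages flip to 2 - d
  mk1 <- data.frame(id = c("m1", "m2"), chrom = "1", pos = c(10L, 20L),
                    ref = "A", alt = "G")
  mk2 <- data.frame(id = c("m1", "m2"), chrom = "1", pos = c(10L, 20L),
                    ref = c("G", "A"), alt = c("A", "G"))
  d1 <- genotype_dataset(matrix(c(0L, 1L, 1L, 2L), 2, 2), mk1,
                         samples = c("a", "b"))
  d2 <- genotype_dataset(matrix(c(2L, 0L, 1L, 1L), 2, 2), mk2,
                         samples = c("c", "d"))
  m <- merge_datasets(list(one = d1, two = d2))
  expect_equal(m$samples, c("one:a", "one:b", "two:c", "two:d"))
  # m1 flipped for source two; m2 unchanged; allele counts conserved
  expect_equal(unname(m$geno[, "m1"]), c(0L, 1L, 0L, 2L))
  expect_equal(unname(m$geno[, "m2"]), c(1L, 2L, 1L, 1L))
  expect_equal(m$markers$ref, c("A", "A"))
  alt_before <- sum(2L - d2$geno[, "m1"])   # alt copies in first orientation
  expect_equal(sum(m$geno[3:4, "m1"]), alt_before)

  # self-merge returns the original markers and dosages
  sm <- merge_datasets(list(x = d1, y = d1))
  expect_equal(sm$markers$id, d1$markers$id)
  expect_equal(unname(sm$geno[1:2, ]), unname(d1$geno))
})

test_that("merge drops irreconcilable markers, fixed markers, and errors on empty overlap", {
  mk1 <- data.frame(id = c("m1", "m2", "m3"), chrom = "1",
                    pos = c(10L, 20L, 30L), ref = "A", alt = "G")
  mk2 <- data.frame(id = c("m1", "m2", "m3"), chrom = "1",
                    pos = c(10L, 20L, 30L),
                    ref = c("A", "C", "A"), alt = c("G", "T", "G"))
  d1 <- genotype_dataset(matrix(c(0L, 1L,  1L, 2L,  2L, 2L), 2, 3), mk1,
                         samples = c("a", "b"))
  d2 <- genotype_dataset(matrix(c(1L, 1L,  0L, 2L,  2L, 2L), 2, 3), mk2,
                         samples = c("c", "d"))
  # m2 has conflicting alleles (A/G vs C/T) -> dropped; m3 fixed -> removed
  expect_message(expect_message(m <- merge_datasets(list(p = d1, q = d2)),
                                "irreconcilable"), "fixed")
  expect_equal(m$markers$id, "m1")

  d3 <- genotype_dataset(matrix(0:1, 2, 1),
                         data.frame(id = "zz", chrom = "1", pos = 1L,
                                    ref = "A", alt = "G"),
                         samples = c("e", "f"))
  expect_error(merge_datasets(list(d1, d3)), "no markers common")
})

test_that("merged marker sets behave like id-set intersection (associativity)", {
  mk <- function(ids) data.frame(id = ids, chrom = "1",
                                 pos = seq_along(ids) * 10L,
                                 ref = "A", alt = "G")
  gen <- function(ids, seed, n = 3) {
    set.seed(seed)
    genotype_dataset(matrix(sample(0:2, n * length(ids), TRUE), n), mk(ids),
                     samples = paste0("s", seed, "_", 1:n))
  }
  A <- gen(c("a", "b", "c", "d"), 1)
  B <- gen(c("b", "c", "d", "e"), 2)
  C <- gen(c("c", "d", "f"), 3)
  m <- suppressMessages(merge_datasets(list(A = A, B = B, C = C)))
  expected <- Reduce(intersect, list(A$markers$id, B$markers$id, C$markers$id))
  expect_true(all(m$markers$id %in% expected))
  m2 <- suppressMessages(merge_datasets(
    list(AB = suppressMessages(merge_datasets(list(A = A, B = B))), C = C)))
  expect_setequal(m$markers$id, m2$markers$id)
})

test_that("population map application restricts and annotates", {
  ds <- rand_dataset(10, 8, seed = 5)
  full <- population_map(setNames(rep(c("X", "Y"), 5), ds$samples))
  a <- apply_population_map(ds, full)
  expect_equal(length(a$samples), 10)
  expect_equal(a$populations, rep(c("X", "Y"), 5))

  half <- population_map(setNames(rep("Z", 5), ds$samples[1:5]))
  b <- apply_population_map(ds, half)
  expect_equal(b$samples, ds$samples[1:5])

  none <- population_map(c(nobody = "Q"))
  expect_error(apply_population_map(ds, none), "covers no sample")
})

test_that("population map TSV round-trips", {
  m <- population_map(c(s1 = "P1", s2 = "P1", s3 = "P2"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_population_map(m, p)
  r <- read_population_map(p)
  expect_identical(unclass(r), unclass(m))
})
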