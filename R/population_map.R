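#' Sample-to-population assignment
#'
#' @param x either a named character vector (names = sample ids, values =
#'   population labels), or a data.frame whose first two columns are
#'   sample id and population label.
#' @return a `population_map`: named character vector with a `populations`
#'   attribute giving the ordered unique labels.
#' @export
population_map <- function(x) {
  if (is.data.frame(x)) {
    v <- as.character(x[[2]])
    names(v) <- as.character(x[[1]])
    x <- v
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("population map needs sample ids as names")
  if (anyDuplicated(names(x))) stop("duplicated sample id in population map")
  x <- setNames(as.character(x), names(x))
  structure(x, populations = unique(unname(x)), class = "population_map")
}

#' @method print population_map
#' @export
print.population_map <- function(x, ...) {
  tab <- table(factor(unname(unclass(x)), levels = attr(x, "populations")))
  cat(sprintf("population_map: %d samples in %d populations\n",
              length(x), length(tab)))
  print(tab)
  invisible(x)
}

#' Restrict a dataset to mapped samples and attach population labels
#'
#' Samples absent from the map are dropped; the map's labels are attached
#' to the dataset for downstream grouping.
#'
#' @param ds a [genotype_dataset()].
#' @param map a [population_map()] (or something coercible to one).
#' @return the annotated, possibly restricted `genotype_dataset`.
#' @export
apply_population_map <- function(ds, map) {
  if (!inherits(map, "population_map")) map <- population_map(map)
  keep <- ds$samples %in% names(map)
  if (!any(keep)) stop("population map covers no sample of the dataset")
  out <- subset_dataset(ds, samples = which(keep))
  out$populations <- unname(unclass(map)[out$samples])
  out
}

#' Population map of an annotated dataset
#' @param ds a [genotype_dataset()] with populations attached.
#' @return a [population_map()].
#' @export
dataset_population_map <- function(ds) {
  if (is.null(ds$populations)) stop("dataset has no population labels")
  population_map(setNames(ds$populations, ds$samples))
}

#' Read/write a two-column sample-population TSV
#' @param path file path.
#' @return a [population_map()].
#' @export
read_population_map <- function(path) {
  population_map(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
}

#' @rdname read_population_map
#' @param map a [population_map()].
#' @export
write_population_map <- function(map, path) {
  write.table(data.frame(sample = names(map),
                         population = unname(unclass(map))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
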