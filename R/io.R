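## Readers and writers for the pipeline's text formats.

#' Read aligned allele protein sequences from FASTA
#'
#' Sequence names are allele identifiers of the form
#' `"<locus>*<field1>:<field2>[...]"`; symbols are validated against the 20
#' amino acids plus `-` and `X`.
#'
#' @param path FASTA file.
#' @return A \pkg{Biostrings} `AAStringSet`.
#' @export
readAlleleFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path)
  invisible(lapply(as.character(x), .encodeResidues))  # symbol validation
  x
}

#' @rdname readAlleleFasta
#' @param sequences an `AAStringSet` or named character vector.
#' @export
writeAlleleFasta <- function(sequences, path) {
  if (!is(sequences, "XStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Write / read a distance matrix as TSV
#'
#' Square layout with a header row and a leading column of allele ids;
#' values carry 6 decimal places.  Writing then reading restores the values
#' at that precision.
#'
#' @param m an [AlleleDistanceMatrix-class].
#' @param path TSV file.
#' @return `writeDistanceMatrix` the path, invisibly;
#'   `readDistanceMatrix` an [AlleleDistanceMatrix-class].
#' @export
writeDistanceMatrix <- function(m, path) {
  stopifnot(is(m, "AlleleDistanceMatrix"))
  v <- m@values
  tab <- data.frame(allele = rownames(v),
                    format(v, nsmall = 6, digits = 1, scientific = FALSE,
                           trim = TRUE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @param locus locus label for the result; defaults to the file name stem.
#' @export
readDistanceMatrix <- function(path, locus = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- tab[[1]]
  v <- as.matrix(tab[, -1, drop = FALSE])
  if (!identical(colnames(v), ids))
    stop("matrix header does not match its allele column in ", path)
  rownames(v) <- ids
  storage.mode(v) <- "double"
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  alleleDistanceMatrix(v, locus)
}

.readCountCol <- function(tab, col, file) {
  x <- tab[[col]]
  if (is.character(x)) x[!nzchar(trimws(x))] <- NA
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & (is.na(v) | v != floor(v)))
  if (length(bad))
    stop("non-integer value in column '", col, "' (", file, " line ",
         bad[1] + 1L, ")")
  as.integer(v)
}

#' Read a mating-record CSV
#'
#' Columns: `mating_id`, `sow_id`, `boar_id`, `litter_size`, `n_live`,
#' `n_stillborn`, `n_weaned`, `n_preweaning_dead`; blank weaning fields
#' encode missing follow-up.  Structural violations are reported with the
#' offending line number.
#'
#' @param path CSV file (header required, UTF-8).
#' @return Validated data.frame.
#' @export
readMatings <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (cl in c("litter_size", "n_live", "n_stillborn", "n_weaned",
               "n_preweaning_dead")) {
    if (!cl %in% names(tab))
      stop("matings file ", path, " missing column: ", cl)
    tab[[cl]] <- .readCountCol(tab, cl, basename(path))
  }
  validateMatings(tab, file = basename(path))
  tab
}

#' @rdname readMatings
#' @export
writeMatings <- function(matings, path) {
  utils::write.csv(matings, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write an animals CSV
#'
#' Columns: `animal_id`, `sex` (`sow`/`boar`), `hap1`, `hap2`.
#'
#' @param path CSV file.
#' @param registry registry used to check haplotype ids.
#' @return data.frame.
#' @export
readAnimals <- function(path, registry = slaRegistry()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  .checkAnimals(tab, registry)
  tab
}

#' @rdname readAnimals
#' @export
writeAnimals <- function(animals, path) {
  utils::write.csv(animals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report to a directory
#'
#' Emits `groups.tsv` (range-group layout with trait summaries),
#' `correlations.tsv` (the per locus/trait Spearman grid) and
#' `series.json` (group-center vs summary series for trend figures, plus
#' the configuration echo).
#'
#' @param analysis a [SlaAnalysis-class].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeAnalysis <- function(analysis, dir) {
  stopifnot(is(analysis, "SlaAnalysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(analysis@groups, file.path(dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(analysis@correlations,
                     file.path(dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(params = analysis@params,
                            series = analysis@series),
                       file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Packaged range-group mating counts
#'
#' The published Table-5-style layout: for each stage (birth / weaning) and
#' locus key, the number of matings per incremental range group (including
#' the merged sparse DRB1 group).
#'
#' @return data.frame: `stage`, `locus_key`, `range_label`, `center`, `n`.
#' @export
groupedMatingCounts <- function() {
  utils::read.delim(system.file("extdata", "grouped_mating_counts.tsv",
                                package = "SLAdissim", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
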