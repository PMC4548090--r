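#' Read an aligned FASTA file
#'
#' @param path FASTA file (IUPAC alphabet, gaps as "-").
#' @param locusLabel Locus label.
#' @param ploidyFactor 1 or 2.
#' @return A \linkS4class{HaplotypeAlignment}.
#' @export
readFastaAlignment <- function(path, locusLabel = "locus", ploidyFactor = 1L) {
  ss <- Biostrings::readDNAStringSet(path)
  HaplotypeAlignment(ss, locusLabel = locusLabel,
                     ploidyFactor = ploidyFactor)
}

#' @rdname readFastaAlignment
#' @param aln A HaplotypeAlignment.
#' @param file Output path.
#' @export
writeFastaAlignment <- function(aln, file) {
  Biostrings::writeXStringSet(aln@seqs, file)
  invisible(file)
}

#' Read a sample-to-population map
#'
#' Tab-delimited, 2 to 4 columns: sample, population and optionally lat, lon
#' (decimal degrees). A header line is detected automatically.
#'
#' @param path File path.
#' @return A \linkS4class{PopulationMap}.
#' @export
readPopulationMap <- function(path) {
  first <- readLines(path, n = 1)
  hasHeader <- grepl("sample", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c("sample", "pop")
  if (ncol(df) >= 4) names(df)[3:4] <- c("lat", "lon")
  PopulationMap(df)
}

#' Read a suitability stack from layer tables plus a manifest
#'
#' The manifest is a CSV with columns \code{file}, \code{enm}, \code{aogcm},
#' \code{period}, \code{tss}; each layer file is a CSV with columns
#' \code{cell_id}, \code{x}, \code{y}, \code{suitability}, all sharing one
#' cell set.
#'
#' @param manifest Manifest CSV path; layer paths are resolved relative to it.
#' @param occurrences Optional path to a one-column file of occurrence cell
#'   ids.
#' @return A \linkS4class{SuitabilityStack}.
#' @export
readSuitabilityStack <- function(manifest, occurrences = NULL) {
  mf <- read.table(manifest, sep = ",", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("file", "enm", "aogcm", "period", "tss")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  dir <- dirname(manifest)
  cells <- NULL; vals <- NULL
  for (i in seq_len(nrow(mf))) {
    ly <- read.table(file.path(dir, mf$file[i]), sep = ",", header = TRUE,
                     stringsAsFactors = FALSE)
    ly$cell_id <- as.character(ly$cell_id)
    if (is.null(cells)) {
      cells <- ly[, c("cell_id", "x", "y")]
      vals <- matrix(NA_real_, nrow(cells), nrow(mf))
    } else if (!identical(ly$cell_id, cells$cell_id)) {
      stop("layer '", mf$file[i], "' has a different cell set")
    }
    vals[, i] <- ly$suitability
  }
  occ <- if (!is.null(occurrences)) readLines(occurrences) else character()
  SuitabilityStack(cells, vals, mf[, c("enm", "aogcm", "period", "tss")],
                   occ)
}

#' @rdname readSuitabilityStack
#' @param stack A SuitabilityStack.
#' @param dir Output directory (created if needed).
#' @export
writeSuitabilityStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ly <- stack@layers
  files <- sprintf("layer_%s_%s_%s.csv", ly$enm, ly$aogcm, ly$period)
  for (i in seq_len(nrow(ly))) {
    df <- cbind(stack@cells, suitability = stack@values[, i])
    write.table(df, file.path(dir, files[i]), sep = ",", row.names = FALSE,
                quote = FALSE)
  }
  mf <- cbind(file = files, ly)
  write.table(mf, file.path(dir, "manifest.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  if (length(stack@occurrences) > 0)
    writeLines(stack@occurrences, file.path(dir, "occurrences.txt"))
  invisible(file.path(dir, "manifest.csv"))
}

# TSV with NA rendered as "-" (comparison-table convention) plus a JSON twin
.writeResult <- function(df, path, meta = list()) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- ifelse(is.na(out[[j]]), "-",
                                                 format(out[[j]], digits = 6))
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(meta = meta, table = df), js, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

.runMeta <- function(seed = NULL, extra = list()) {
  c(list(package = "CoalScenarios",
         version = as.character(utils::packageVersion("CoalScenarios")),
         seed = seed), extra)
}
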