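# Readers and writers for the plain-text formats the pipeline touches:
# count matrix TSV, HTSeq-count two-column files, sample annotation TSV,
# GMT gene sets, edge-list TSV, protein-list CSV, PSM TSV, Elispot CSV,
# truth JSON.

#' Read a gene x sample count matrix from TSV
#'
#' First column = gene symbols, header row = sample ids.
#'
#' @param path file path.
#' @return integer matrix.
#' @export
readCountMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a count matrix to TSV
#' @param counts matrix; @param path file path.
#' @export
writeCountMatrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read per-sample HTSeq-count files (two columns: gene, count)
#'
#' Special counter rows beginning with `__` are dropped. Sample names are
#' taken from the file names.
#'
#' @param paths character vector of file paths, or a directory.
#' @return integer matrix, genes x samples.
#' @export
readHtseqCounts <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, full.names = TRUE)
  tabs <- lapply(paths, function(p) {
    df <- read.delim(p, header = FALSE, stringsAsFactors = FALSE)
    df <- df[!startsWith(df[[1]], "__"), , drop = FALSE]
    setNames(df[[2]], df[[1]])
  })
  genes <- sort(unique(unlist(lapply(tabs, names))))
  m <- vapply(tabs, function(v) unname(v[genes]), numeric(length(genes)))
  m[is.na(m)] <- 0
  dimnames(m) <- list(genes, sub("\\.[^.]*$", "", basename(paths)))
  m
}

#' Read a sample annotation table from TSV
#'
#' Requires a `sample` column (used as row names) plus design columns.
#'
#' @param path file path.
#' @return data.frame keyed by sample.
#' @export
readSampleAnnotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stop("annotation needs a 'sample' column")
  rownames(df) <- df$sample
  df
}

#' Write sample annotation to TSV
#' @param annotation data.frame; @param path file path.
#' @export
writeSampleAnnotation <- function(annotation, path) {
  df <- data.frame(sample = rownames(annotation), annotation,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name <tab> description <tab> member1 <tab> member2 ...`
#'
#' @param path file path.
#' @return named list of member character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of member vectors.
#' @param path file path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Write a PPINetwork as an edge-list TSV
#' @param network a [PPINetwork-class]; @param path file path.
#' @export
writeEdgeList <- function(network, path) {
  write.table(ppiEdges(network), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Read a protein list CSV (one identifier per line, optional second column)
#' @param path file path.
#' @return character vector of identifiers (first column).
#' @export
readProteinList <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as.character(df[[1]])
}

#' Write a protein set to a one-column CSV
#' @param proteins character vector; @param path file path.
#' @export
writeProteinList <- function(proteins, path) {
  write.csv(data.frame(protein = proteins), path, row.names = FALSE,
            quote = FALSE)
}

#' Read a PSM table from TSV
#' @param path file path with columns `peptide`, `protein`, `length`,
#'   `score`, `is_decoy`.
#' @return data.frame.
#' @export
readPsmTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$is_decoy <- as.logical(df$is_decoy)
  df
}

#' Write a PSM table to TSV
#' @param psms data.frame; @param path file path.
#' @export
writePsmTable <- function(psms, path) {
  write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read Elispot count tables from CSV
#'
#' Columns `condition`, `day`, `well`, `spots`; returns one data.frame per
#' condition.
#'
#' @param path file path.
#' @return named list of data.frames.
#' @export
readElispot <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  split(df, df$condition)
}

#' Write Elispot series to one CSV
#' @param seriesList named list of data.frames; @param path file path.
#' @export
writeElispot <- function(seriesList, path) {
  write.csv(do.call(rbind, unname(seriesList)), path, row.names = FALSE,
            quote = FALSE)
}

#' Serialize a SyntheticTruth to JSON
#' @param truth a [SyntheticTruth-class]; @param path file path.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(list(
    planted_factors = plantedFactors(truth),
    planted_deg = plantedDeg(truth),
    enriched_sets = enrichedSets(truth),
    batch_assignment = as.list(truth@batchAssignment),
    params = truth@params), path, auto_unbox = TRUE, digits = NA)
}
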