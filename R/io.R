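# Readers and writers for the plain-text formats used across the
# pipeline: dense expression TSV (genes as rows), sample/cell annotation
# TSV, GMT gene sets, MTX sparse triplets, ligand-receptor CSV, survival
# TSV, and risk-model JSON. All writers produce byte-stable output so
# reruns under a fixed seed are reproducible.

#' @rdname expressionTSV
#' @param E expression container or genes-by-samples matrix.
#' @param path output file.
#' @export
writeExpressionTSV <- function(E, path) {
  M <- exprsOf(E)
  # %.17g round-trips doubles exactly through text
  ch <- matrix(sprintf("%.17g", M), nrow = nrow(M),
               dimnames = dimnames(M))
  df <- data.frame(gene = rownames(M), ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dense expression TSV (genes as rows)
#'
#' `writeExpressionTSV()` writes a genes-by-samples matrix with a leading
#' `gene` column; `readExpressionTSV()` reads it back to a numeric
#' matrix, preserving values to full precision.
#'
#' @name expressionTSV
#' @return a numeric matrix with gene row names.
#' @export
readExpressionTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  M
}

#' @rdname annotationTSV
#' @param ann data.frame keyed by its row names (sample or cell ids).
#' @param path output file.
#' @export
writeAnnotationTSV <- function(ann, path) {
  df <- data.frame(id = rownames(ann), as.data.frame(ann),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample / cell annotation sidecar TSV
#'
#' Annotations are keyed by an `id` column holding the sample or cell
#' identifier.
#'
#' @name annotationTSV
#' @return data.frame with ids as row names.
#' @export
readAnnotationTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- df$id
  df$id <- NULL
  df
}

#' @rdname gmt
#' @param sets named list of character gene sets.
#' @param path output file.
#' @param description optional per-set description column (defaults to
#'   the set name).
#' @export
writeGMT <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' GMT gene-set files
#'
#' One record per line: set name, description, then member genes, all
#' tab-separated.
#'
#' @name gmt
#' @return named list of character gene sets.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' @rdname mtx
#' @param E matrix (dense or sparse) with gene row names and cell column
#'   names.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @export
writeMTX <- function(E, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(methods::as(Matrix::Matrix(E, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(E), file.path(dir, "features.tsv"))
  writeLines(colnames(E), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' MTX triplet directories
#'
#' The conventional single-cell trio: `matrix.mtx` (MatrixMarket sparse
#' triplets), `features.tsv` (gene ids) and `barcodes.tsv` (cell ids).
#'
#' @name mtx
#' @param dir directory holding the three files.
#' @return a dense genes-by-cells matrix.
#' @export
readMTX <- function(dir) {
  M <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(M) <- readLines(file.path(dir, "features.tsv"))
  colnames(M) <- readLines(file.path(dir, "barcodes.tsv"))
  M
}

#' @rdname lrTable
#' @param lr data.frame with columns `ligand`, `receptor`.
#' @param path output CSV.
#' @export
writeLRTable <- function(lr, path) {
  write.table(lr[, c("ligand", "receptor")], path, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ligand-receptor pair CSV
#'
#' Two columns, `ligand,receptor`, one pair per row.
#'
#' @name lrTable
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
readLRTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% colnames(df)))
    stop("LR table needs 'ligand' and 'receptor' columns",
         call. = FALSE)
  df
}

#' @rdname survivalTSV
#' @param survival data.frame with columns `sample`, `time`, `event`.
#' @param path output file.
#' @export
writeSurvivalTSV <- function(survival, path) {
  validateSurvival(survival)
  write.table(survival[, c("sample", "time", "event")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Survival table TSV
#'
#' Columns `sample`, `time` (> 0) and `event` (0 = censored, 1 = event);
#' malformed rows raise a validation error.
#'
#' @name survivalTSV
#' @return validated data.frame.
#' @export
readSurvivalTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validateSurvival(df)
  df
}

#' @rdname modelJSON
#' @param model a [RiskModel-class].
#' @param path output file.
#' @export
writeModelJSON <- function(model, path) {
  stopifnot(is(model, "RiskModel"))
  obj <- list(genes = model@genes,
              coefficients = as.list(model@coefficients),
              cutpoint = if (is.na(model@cutpoint)) NULL else
                model@cutpoint,
              provenance = model@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Risk-model JSON
#'
#' Genes, coefficients, optional cut-point and provenance tag.
#'
#' @name modelJSON
#' @return a [RiskModel-class].
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(obj$coefficients)
  new("RiskModel", genes = obj$genes, coefficients = coefs[obj$genes],
      cutpoint = if (is.null(obj$cutpoint)) NA_real_ else obj$cutpoint,
      provenance = obj$provenance)
}
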