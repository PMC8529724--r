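## Input schemas. Measurement tables are comma-delimited; expression
## matrices and GMT are tab-delimited. Delimiters are fixed, not sniffed.

.SCHEMAS <- list(
  growth = list(
    columns = c("model", "drug", "arm", "animal", "day", "width_mm",
                "length_mm"),
    numeric = c("day", "width_mm", "length_mm"),
    check = function(df) {
      ok <- df$day >= 0 & df$width_mm > 0 & df$length_mm > 0 &
        df$arm %in% c("treated", "control")
      ok
    }
  ),
  viability = list(
    columns = c("model", "drug", "concentration_uM", "replicate",
                "viability"),
    numeric = c("concentration_uM", "viability"),
    check = function(df) df$concentration_uM >= 0 & df$viability >= 0
  ),
  combination = list(
    columns = c("model", "drugA", "doseA_uM", "drugB", "doseB_uM",
                "replicate", "fluorescence", "confluence"),
    numeric = c("doseA_uM", "doseB_uM", "fluorescence", "confluence"),
    check = function(df) df$doseA_uM >= 0 & df$doseB_uM >= 0 &
      df$fluorescence >= 0 & df$confluence >= 0
  ),
  response = list(
    columns = c("model", "drug", "platform", "response_value"),
    numeric = "response_value",
    check = function(df) df$response_value >= 0 &
      df$platform %in% c("PDX", "PD3D")
  ),
  pairing = list(
    columns = c("sample_a", "sample_b", "relation", "layer"),
    numeric = character(),
    check = function(df) rep(TRUE, nrow(df))
  )
)

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name TAB description TAB gene1 TAB gene2 ...}. Duplicate gene
#' symbols within a set are removed; duplicate set names are an error.
#' Trailing whitespace and a missing final newline are tolerated.
#'
#' @param path path to a GMT file.
#' @return a [GeneSetCollection].
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdesc\tTP53\tBRCA2\tTP53", gmt)
#' readGmt(gmt)
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(new("GeneSetCollection", setNames = character(),
               descriptions = character(), genes = list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 bad[1]))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  new("GeneSetCollection",
      setNames = nm,
      descriptions = vapply(fields, `[[`, character(1), 2L),
      genes = lapply(fields, function(f) unique(f[-(1:2)])))
}

#' Write a gene-set collection to a GMT file
#'
#' @param gsc a [GeneSetCollection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(gsc, path) {
  stopifnot(is(gsc, "GeneSetCollection"))
  lines <- vapply(seq_along(gsc@setNames), function(i)
    paste(c(gsc@setNames[i], gsc@descriptions[i], gsc@genes[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a measurement table
#'
#' Reads a comma-delimited table with header and validates it against one
#' of the five input schemas (`growth`, `viability`, `combination`,
#' `response`, `pairing`). Rows violating the schema invariants (negative
#' days, non-positive dimensions, non-finite numerics, unknown arm or
#' platform labels) are dropped with a message reporting the count;
#' missing numeric cells are rejected, never imputed.
#'
#' @param path path to a CSV file.
#' @param schema one of \code{names(measurementSchemas())}.
#' @return a `data.frame` with attribute `schema`.
#' @export
readMeasurementTable <- function(path, schema) {
  schema <- match.arg(schema, names(.SCHEMAS))
  sc <- .SCHEMAS[[schema]]
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing <- setdiff(sc$columns, names(df))
  if (length(missing))
    stop(sprintf("schema '%s': missing required column(s): %s",
                 schema, paste(missing, collapse = ", ")))
  df <- df[, sc$columns, drop = FALSE]
  validateMeasurementTable(df, schema)
}

#' @rdname readMeasurementTable
#' @param df a data.frame already holding the schema's columns.
#' @export
validateMeasurementTable <- function(df, schema) {
  schema <- match.arg(schema, names(.SCHEMAS))
  sc <- .SCHEMAS[[schema]]
  missing <- setdiff(sc$columns, names(df))
  if (length(missing))
    stop(sprintf("schema '%s': missing required column(s): %s",
                 schema, paste(missing, collapse = ", ")))
  n0 <- nrow(df)
  for (cn in sc$numeric) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  finite <- if (length(sc$numeric))
    Reduce(`&`, lapply(sc$numeric, function(cn) is.finite(df[[cn]])))
  else rep(TRUE, n0)
  ok <- finite
  ok[ok] <- sc$check(df[ok, , drop = FALSE])
  if (any(!ok))
    message(sprintf("schema '%s': rejected %d of %d row(s) violating invariants",
                    schema, sum(!ok), n0))
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop(sprintf("schema '%s': zero valid rows", schema))
  rownames(df) <- NULL
  attr(df, "schema") <- schema
  df
}

#' @rdname readMeasurementTable
#' @export
measurementSchemas <- function() .SCHEMAS

#' Write result records to CSV
#'
#' Writes a data.frame (or a list of records sharing one schema) with a
#' deterministic column order so that output round-trips through
#' [readMeasurementTable()] / `read.csv`. An empty record set yields a
#' header-only file; records with differing fields are an error.
#'
#' @param records a data.frame, or a list of single-row data.frames /
#'   named lists sharing identical field names.
#' @param path output path.
#' @param columns optional explicit column order; defaults to the order
#'   of the first record.
#' @return `path`, invisibly.
#' @export
writeResults <- function(records, path, columns = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0L) {
      if (is.null(columns))
        stop("empty record list needs explicit 'columns' for the header")
      df <- as.data.frame(stats::setNames(
        replicate(length(columns), logical(0), simplify = FALSE), columns))
    } else {
      fields <- lapply(records, function(r) sort(names(r)))
      if (!all(vapply(fields, identical, logical(1), fields[[1]])))
        stop("records with mixed schemas: field names differ")
      df <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    }
  } else stop("records must be a data.frame or list")
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(df))
    if (length(missing))
      stop("records lack column(s): ", paste(missing, collapse = ", "))
    df <- df[, columns, drop = FALSE]
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column gene symbols, remaining columns sample IDs, values
#' non-negative abundances. Duplicate gene symbols and missing values
#' are errors; the matrix is assumed library-size-normalized upstream.
#'
#' @param path path to a tab-delimited file.
#' @return numeric matrix, genes in rows.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(m < 0)) stop("expression values must be non-negative")
  rownames(m) <- genes
  m
}

#' @rdname readExpressionMatrix
#' @param m numeric matrix, genes in rows.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path path to a YAML file with per-stage blocks (paths,
#'   thresholds, seeds, permutation counts).
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

## Coerce expression input: plain matrix, data.frame, or a
## SummarizedExperiment (assay 1). Keeps the Bioconductor container
## usable without hard-depending on it.
.asExprMatrix <- function(x) {
  if (is.matrix(x)) m <- x
  else if (methods::is(x, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("SummarizedExperiment input needs the SummarizedExperiment package")
    m <- SummarizedExperiment::assay(x, 1L)
    m <- as.matrix(m)
  } else if (is.data.frame(x)) m <- as.matrix(x)
  else stop("expression input must be a matrix, data.frame or SummarizedExperiment")
  if (is.null(rownames(m))) stop("expression matrix must have gene rownames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene symbols in matrix")
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}
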