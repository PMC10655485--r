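#' Read a count matrix from delimited text or Matrix Market files
#'
#' Loads raw integer RNA-seq counts and normalizes the orientation to
#' samples x genes. Delimited files are tab-separated with the first column
#' holding row identifiers and a header of column identifiers; leading `#`
#' comment lines are skipped. Matrix Market (`.mtx`) files need companion
#' one-ID-per-line row and column files. All entries are validated as
#' non-negative integers; offending coordinates are named in the error.
#'
#' @param path File to read.
#' @param orientation `"samples_by_genes"` (rows are samples) or
#'   `"genes_by_samples"` (the transpose, common in expression dumps).
#' @param format `"auto"` (by extension), `"delimited"` or
#'   `"matrix_market"`.
#' @param row_ids,col_ids Companion ID files for Matrix Market input
#'   (row/column identifiers of the matrix on disk).
#' @param metadata Optional data frame (or TSV path) of per-sample
#'   metadata; matched to sample IDs by its first column.
#' @param tissue_col Name of the metadata column holding tissue labels.
#' @return An object of class `"dgd_counts"`: list with `counts`
#'   (samples x genes integer matrix), `tissues` (or `NULL`) and
#'   `metadata`.
#' @export
read_counts <- function(path, orientation = c("samples_by_genes", "genes_by_samples"),
                        format = c("auto", "delimited", "matrix_market"),
                        row_ids = NULL, col_ids = NULL,
                        metadata = NULL, tissue_col = "tissue") {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "matrix_market" else "delimited"

  if (format == "delimited") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                             row.names = 1L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop_dgd("non-numeric entries in ", path)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    if (!is.null(row_ids)) rownames(m) <- read_gene_list(row_ids)
    if (!is.null(col_ids)) colnames(m) <- read_gene_list(col_ids)
  }

  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad))
    stop_dgd("non-integer or negative count at row ", bad[1, 1], ", column ",
             bad[1, 2], " (", nrow(bad), " offending entries)")
  storage.mode(m) <- "integer"
  if (orientation == "genes_by_samples") m <- t(m)
  if (anyDuplicated(rownames(m))) stop_dgd("duplicate sample IDs")
  if (anyDuplicated(colnames(m))) stop_dgd("duplicate gene IDs")

  tissues <- NULL
  if (!is.null(metadata)) {
    if (is.character(metadata)) metadata <- utils::read.table(
      metadata, header = TRUE, sep = "\t", comment.char = "#",
      stringsAsFactors = FALSE, check.names = FALSE)
    ids <- metadata[[1L]]
    if (!all(ids %in% rownames(m)))
      stop_dgd("metadata rows must be a subset of sample IDs")
    if (tissue_col %in% names(metadata))
      tissues <- metadata[[tissue_col]][match(rownames(m), ids)]
  }
  structure(list(counts = m, tissues = tissues, metadata = metadata),
            class = "dgd_counts")
}

#' @export
print.dgd_counts <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "samples x", ncol(x$counts), "genes\n")
  if (!is.null(x$tissues))
    cat("tissues:", paste(names(table(x$tissues)), table(x$tissues),
                          sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Write a count matrix as tab-separated text
#'
#' Emits a `#`-prefixed provenance header (tool version) followed by a
#' header row of gene IDs; first column holds sample IDs. Round-trips
#' bit-exactly through [read_counts()].
#'
#' @param x `"dgd_counts"` object or samples x genes matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  m <- if (inherits(x, "dgd_counts")) x$counts else as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# dgdr ", as.character(utils::packageVersion("dgdr"))), con)
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = TRUE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path File to read.
#' @return Character vector of IDs.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Align a count matrix to a model's gene order
#'
#' Reorders columns to the model's gene list. Genes missing from the input
#' are an error by default; with `fill_missing = TRUE` they are zero-filled
#' with a warning giving the count. Extra genes are dropped (count
#' reported via message).
#'
#' @param x `"dgd_counts"` object or samples x genes matrix with gene IDs
#'   as column names.
#' @param model_genes Character vector of gene IDs in model order (or a
#'   [dgd] object).
#' @param fill_missing Zero-fill genes absent from the input instead of
#'   erroring.
#' @return Object of the same kind as `x`, columns in model order.
#' @export
align_genes <- function(x, model_genes, fill_missing = FALSE) {
  if (inherits(model_genes, "dgd")) model_genes <- model_genes$genes
  if (anyDuplicated(model_genes)) stop_dgd("'model_genes' must be unique")
  m <- if (inherits(x, "dgd_counts")) x$counts else as.matrix(x)
  if (is.null(colnames(m))) stop_dgd("input must carry gene IDs as column names")
  missing <- setdiff(model_genes, colnames(m))
  extra <- setdiff(colnames(m), model_genes)
  if (length(missing) && !fill_missing)
    stop_dgd(length(missing), " model gene(s) missing from input, e.g. ",
             paste(utils::head(missing, 3), collapse = ", "),
             "; use fill_missing = TRUE to zero-fill")
  if (length(missing)) {
    warning(length(missing), " missing gene(s) zero-filled")
    fill <- matrix(0L, nrow(m), length(missing),
                   dimnames = list(rownames(m), missing))
    m <- cbind(m, fill)
  }
  if (length(extra)) message(length(extra), " gene(s) not in the model dropped")
  m <- m[, model_genes, drop = FALSE]
  if (inherits(x, "dgd_counts")) { x$counts <- m; x } else m
}

#' Save a fitted model to a single archive file
#'
#' Serializes the complete model — decoder weights, mixture parameters,
#' dispersions, gene IDs, prior hyperparameters and fit artifacts — with a
#' schema version field. [dgd_load()] round-trips all parameters
#' bit-exactly.
#'
#' @param object A [dgd] model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
dgd_save <- function(object, path) {
  if (!inherits(object, "dgd")) stop_dgd("'object' must be a dgd model")
  saveRDS(list(schema = "dgdr-model/1", model = object), path)
  invisible(path)
}

#' @rdname dgd_save
#' @export
dgd_load <- function(path) {
  arc <- readRDS(path)
  if (!identical(arc$schema, "dgdr-model/1"))
    stop_dgd("unrecognized model archive schema: ", arc$schema %||% "<none>")
  arc$model
}
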