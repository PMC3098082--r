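#' Construct a two-class expression dataset
#'
#' The central container of the package: a genes x samples real-valued
#' matrix together with unique gene and sample identifiers and a binary
#' class label per sample. One of the two classes is designated the
#' "positive" class; up/down direction calls for genes are made relative
#' to it.
#'
#' @param matrix numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers (length
#'   `nrow(matrix)`).
#' @param sample_ids character vector of unique sample identifiers (length
#'   `ncol(matrix)`).
#' @param labels character or factor vector of per-sample class labels;
#'   exactly two distinct values, each with at least two samples.
#' @param positive_class label treated as "class 1" for direction calls;
#'   defaults to the lexicographically smaller label.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `gene_ids`, `sample_ids`, `labels`, `positive_class`.
#' @export
expression_dataset <- function(matrix, gene_ids, sample_ids, labels,
                               positive_class = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)

  if (nrow(matrix) != length(gene_ids))
    stop("matrix has ", nrow(matrix), " rows but ", length(gene_ids),
         " gene ids", call. = FALSE)
  if (ncol(matrix) != length(sample_ids))
    stop("matrix has ", ncol(matrix), " columns but ", length(sample_ids),
         " sample ids", call. = FALSE)
  if (length(labels) != length(sample_ids))
    stop("need one class label per sample", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(matrix)))
    stop("expression matrix contains non-finite values", call. = FALSE)

  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("exactly two classes required, found ", length(classes), ": ",
         paste(classes, collapse = ", "), call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("each class needs >= 2 samples (",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")",
         call. = FALSE)

  positive_class <- positive_class %||% classes[1L]
  if (!positive_class %in% classes)
    stop("positive_class '", positive_class, "' is not one of the labels (",
         paste(classes, collapse = ", "), ")", call. = FALSE)

  dimnames(matrix) <- list(gene_ids, sample_ids)
  structure(
    list(matrix = matrix, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels, positive_class = positive_class),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  counts <- table(x$labels)
  cat("ExpressionDataset: ", length(x$gene_ids), " genes x ",
      length(x$sample_ids), " samples\n", sep = "")
  cat("classes: ", paste(names(counts), counts, sep = "=", collapse = ", "),
      " (positive: ", x$positive_class, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

#' Read a two-class expression dataset from tab-delimited text
#'
#' The default single-file dialect is self-describing: row 1 holds the
#' sample identifiers (an optional leading cell naming the gene-id column is
#' tolerated), row 2 is the token `class` followed by one label per sample,
#' and every following row is a gene id followed by its numeric expression
#' values. Alternatively labels may live in a separate two-column
#' (sample_id, label) file passed as `labels`.
#'
#' @param path path to the tab-delimited expression matrix.
#' @param labels optional path to a two-column tab-delimited label file;
#'   when given, the matrix file must not contain a `class` row.
#' @param positive_class optional class name to treat as positive; defaults
#'   to the lexicographically smaller label.
#' @param impute `"none"` (default; missing values are an error) or
#'   `"row-mean"` (replace missing cells by the gene's mean over observed
#'   samples).
#'
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(path, labels = NULL, positive_class = NULL,
                         impute = c("none", "row-mean")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)               # tolerate CRLF
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("file too short: ", path, call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]

  if (!is.null(labels) && length(fields) >= 2L &&
      identical(fields[[2L]][1L], "class"))
    stop("matrix file has an inline 'class' row; do not pass a label file too",
         call. = FALSE)

  lab_row <- if (is.null(labels)) {
    if (!identical(fields[[2L]][1L], "class"))
      stop("row 2 must start with the token 'class' ",
           "(or pass labels= a separate label file)", call. = FALSE)
    fields[[2L]]
  } else NULL

  data_rows <- fields[seq.int(if (is.null(labels)) 3L else 2L, length(fields))]
  if (length(data_rows) < 1L) stop("no gene rows found", call. = FALSE)

  n_cols <- length(data_rows[[1L]])
  n_samples <- n_cols - 1L
  sample_ids <- if (length(header) == n_cols) header[-1L]
  else if (length(header) == n_samples) header
  else stop("header has ", length(header), " fields but gene rows have ",
            n_cols, call. = FALSE)

  gene_ids <- vapply(data_rows, `[[`, character(1L), 1L)
  mat <- matrix(NA_real_, nrow = length(data_rows), ncol = n_samples)
  for (i in seq_along(data_rows)) {
    row <- data_rows[[i]]
    if (length(row) != n_cols)
      stop("gene row ", i, " ('", row[1L], "') has ", length(row),
           " fields, expected ", n_cols, call. = FALSE)
    vals <- row[-1L]
    missing <- !nzchar(vals) | vals %in% c("NA", "na", "NaN")
    num <- suppressWarnings(as.numeric(vals))
    bad <- !missing & is.na(num)
    if (any(bad)) {
      j <- which(bad)[1L]
      stop("non-numeric value '", vals[j], "' at gene '", row[1L],
           "' (row ", i, "), sample '", sample_ids[j], "' (column ", j, ")",
           call. = FALSE)
    }
    if (any(missing)) {
      if (impute != "row-mean") {
        j <- which(missing)[1L]
        stop("missing value at gene '", row[1L], "' (row ", i,
             "), sample '", sample_ids[j], "' (column ", j,
             "); re-run with impute = \"row-mean\" to impute", call. = FALSE)
      }
      if (all(missing))
        stop("gene '", row[1L], "' has no observed values to impute from",
             call. = FALSE)
      num[missing] <- mean(num[!missing])
    }
    mat[i, ] <- num
  }

  lab <- if (is.null(labels)) {
    if (length(lab_row) != n_cols)
      stop("class row has ", length(lab_row), " fields, expected ", n_cols,
           call. = FALSE)
    lab_row[-1L]
  } else {
    read_label_file(labels, sample_ids)
  }

  expression_dataset(mat, gene_ids, sample_ids, lab,
                     positive_class = positive_class)
}

read_label_file <- function(path, sample_ids) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 2L)
    stop("label file must have two columns (sample_id, label)", call. = FALSE)
  idx <- match(sample_ids, tab[[1L]])
  if (anyNA(idx))
    stop("label file is missing samples: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  tab[[2L]][idx]
}

#' Write a dataset in the tab-delimited dialect read by [read_dataset()]
#'
#' @param ds an [expression_dataset()].
#' @param path output file path.
#' @param digits significant digits for expression values (default keeps
#'   full double precision so write/read round-trips exactly).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, digits = 17L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", ds$sample_ids), collapse = "\t"), con)
  writeLines(paste(c("class", ds$labels), collapse = "\t"), con)
  body <- vapply(seq_along(ds$gene_ids), function(i) {
    paste(c(ds$gene_ids[i],
            formatC(ds$matrix[i, ], digits = digits, format = "g")),
          collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Sample indices of the positive and negative class
#'
#' @param ds an [expression_dataset()].
#' @return list with integer vectors `positive` and `negative` (1-based
#'   column indices, in file order), disjoint and jointly covering all
#'   samples.
#' @export
split_by_class <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  pos <- which(ds$labels == ds$positive_class)
  list(positive = pos, negative = which(ds$labels != ds$positive_class))
}

# Internal lightweight view of a sample subset (bootstrap in-bag multisets
# may repeat samples, so this bypasses the unique-id constructor).
ds_view <- function(ds, idx) {
  list(matrix = ds$matrix[, idx, drop = FALSE],
       labels = ds$labels[idx],
       positive_class = ds$positive_class,
       gene_ids = ds$gene_ids)
}
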