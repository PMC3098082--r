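#' Create a feature block
#'
#' A feature block is the classifier-facing view of a dataset: a features x
#' samples numeric matrix plus feature names, an encoding tag (`"numeric"`
#' or `"interval-index"`), and the provenance/fitted state needed to apply
#' the same construction to new samples.
#'
#' @param matrix features x samples numeric matrix.
#' @param feature_names character vector, one per row.
#' @param encoding `"numeric"` or `"interval-index"`.
#' @param state optional fitted state (cut lists, gene list, direction).
#' @return object of class `FeatureBlock`.
#' @export
feature_block <- function(matrix, feature_names,
                          encoding = c("numeric", "interval-index"),
                          state = list()) {
  encoding <- match.arg(encoding)
  matrix <- base::matrix(as.numeric(matrix), nrow = length(feature_names),
                         dimnames = list(feature_names, NULL),
                         ncol = if (length(feature_names))
                           length(matrix) / length(feature_names) else 0L)
  structure(list(matrix = matrix, feature_names = feature_names,
                 encoding = encoding, state = state),
            class = "FeatureBlock")
}

# Feature block holding the expression of a selected gene list.
gene_block <- function(ds_like, gene_ids) {
  idx <- match(gene_ids, ds_like$gene_ids)
  if (anyNA(idx))
    stop("unknown gene id(s): ",
         paste(gene_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  feature_block(ds_like$matrix[idx, , drop = FALSE], gene_ids,
                encoding = "numeric", state = list(gene_ids = gene_ids))
}

#' Fit per-feature MDL discretizers on training samples
#'
#' Learns MDL cut points (see [mdl_discretize()]) for every feature of a
#' numeric block from the training samples only. The fitted model is
#' applied unchanged to held-out samples by [apply_discretizer()]; values
#' outside the training range fall into the first or last interval.
#'
#' @param block numeric [feature_block()] of the training samples.
#' @param labels training class labels.
#' @return object of class `DiscretizationModel`: named list of sorted cut
#'   vectors (possibly empty), one per feature.
#' @export
fit_discretizer <- function(block, labels) {
  stopifnot(inherits(block, "FeatureBlock"), block$encoding == "numeric")
  cuts <- lapply(seq_len(nrow(block$matrix)), function(i)
    mdl_discretize(block$matrix[i, ], labels))
  names(cuts) <- block$feature_names
  structure(cuts, class = "DiscretizationModel")
}

#' Map numeric features to interval indices
#'
#' Each value is replaced by the 0-based index of its half-open interval
#' \eqn{(-\infty, c_1), [c_1, c_2), \ldots, [c_m, \infty)}; values exactly
#' at a cut fall in the right-hand interval, identically at fit and apply
#' time. A feature with no cuts maps entirely to interval 0.
#'
#' @param model a `DiscretizationModel` from [fit_discretizer()].
#' @param block numeric [feature_block()] over the same features.
#' @return an interval-index [feature_block()].
#' @export
apply_discretizer <- function(model, block) {
  stopifnot(inherits(model, "DiscretizationModel"),
            inherits(block, "FeatureBlock"))
  if (!identical(names(model), block$feature_names))
    stop("discretizer was fitted on different features (",
         paste(names(model), collapse = ","), " vs ",
         paste(block$feature_names, collapse = ","), ")", call. = FALSE)
  out <- block$matrix
  for (i in seq_len(nrow(out))) {
    cuts <- model[[i]]
    out[i, ] <- if (length(cuts)) findInterval(block$matrix[i, ], cuts)
    else 0
  }
  feature_block(out, block$feature_names, encoding = "interval-index",
                state = c(block$state, list(cuts = unclass(model))))
}

#' Feature-vector addition: sum same-direction genes into one composite
#'
#' Collapses a block of k selected genes, all chosen under the up- or
#' down-regulated pattern, into a single composite feature by element-wise
#' summation of their raw expression vectors:
#' \eqn{composite[s] = \sum_g x[g, s]}. Summing genes that shift the same
#' way between classes amplifies their shared pattern and averages out
#' sample-level outliers. No rescaling is applied, and the composite
#' replaces the gene features (the classifier sees exactly one feature).
#'
#' @param block numeric [feature_block()] of the selected genes.
#' @param pattern the selection pattern that produced the genes; must be
#'   `"up"` or `"down"` — composites across mixed-direction (`"total"`)
#'   selections are refused.
#' @return a one-feature numeric [feature_block()] named
#'   `fva(<k> genes, <pattern>)`.
#' @export
feature_vector_addition <- function(block, pattern) {
  stopifnot(inherits(block, "FeatureBlock"), block$encoding == "numeric")
  if (!pattern %in% c("up", "down"))
    stop("feature vector addition requires up- or down-regulated selection",
         call. = FALSE)
  composite <- colSums(block$matrix)
  name <- sprintf("fva(%d genes, %s)", nrow(block$matrix), pattern)
  feature_block(matrix(composite, nrow = 1L), name, encoding = "numeric",
                state = c(block$state, list(fva_pattern = pattern)))
}
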