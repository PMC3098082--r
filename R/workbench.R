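#' Specify one gene-selection procedure
#'
#' A procedure is one point in the workbench grid: a feature-ranking
#' statistic, an expression-pattern restriction, a gene count k, optional
#' feature discretization, optional feature-vector addition, and a
#' classifier. Feature-vector addition requires same-direction genes, so
#' `fva = TRUE` is only legal with pattern `"up"` or `"down"`.
#'
#' @param fs_method `"ttest"`, `"wilcoxon"` or `"infogain"`.
#' @param pattern `"total"`, `"up"` or `"down"`.
#' @param k positive integer number of genes to select.
#' @param discretize discretize classifier features?
#' @param fva apply feature-vector addition?
#' @param classifier `"svm"` or `"rf"`.
#' @return object of class `ProcedureSpec`.
#' @export
procedure_spec <- function(fs_method = c("ttest", "wilcoxon", "infogain"),
                           pattern = c("total", "up", "down"),
                           k = 10L, discretize = FALSE, fva = FALSE,
                           classifier = c("svm", "rf")) {
  fs_method <- match.arg(fs_method)
  pattern <- match.arg(pattern)
  classifier <- match.arg(classifier)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  if (fva && pattern == "total")
    stop("feature vector addition requires up- or down-regulated selection",
         call. = FALSE)
  structure(list(fs_method = fs_method, pattern = pattern, k = as.integer(k),
                 discretize = isTRUE(discretize), fva = isTRUE(fva),
                 classifier = classifier),
            class = "ProcedureSpec")
}

format_spec <- function(spec) {
  sprintf("%s/%s/k=%d/disc=%s/fva=%s/%s", spec$fs_method, spec$pattern,
          spec$k, ifelse(spec$discretize, "on", "off"),
          ifelse(spec$fva, "on", "off"), spec$classifier)
}

#' @export
print.ProcedureSpec <- function(x, ...) {
  cat("ProcedureSpec:", format_spec(x), "\n")
  invisible(x)
}

#' Enumerate the procedure grid
#'
#' The Cartesian product of feature-selection method, expression pattern,
#' discretization, feature-vector addition and classifier, crossed with
#' the k grid, in a fixed canonical order. Feature-vector addition is only
#' combined with the up/down patterns, so with all defaults and a single
#' k the pattern `"total"` contributes 3x2x2 = 12 procedures and the
#' patterns up/down contribute 3x2x2x2x2 = 48, totalling 60.
#'
#' @param methods subset of `c("ttest", "wilcoxon", "infogain")`.
#' @param patterns subset of `c("total", "up", "down")`.
#' @param discretize logical vector of discretization options to cross
#'   (default both off and on).
#' @param fva logical vector of feature-vector-addition options.
#' @param classifiers subset of `c("svm", "rf")`.
#' @param k_grid positive integers; the default spans the gene counts
#'   typically examined for microarray panels (10-200).
#' @return list of [procedure_spec()] objects in canonical order
#'   (k, method, pattern, discretize, fva, classifier — rightmost fastest).
#' @export
enumerate_procedures <- function(methods = c("ttest", "wilcoxon", "infogain"),
                                 patterns = c("total", "up", "down"),
                                 discretize = c(FALSE, TRUE),
                                 fva = c(FALSE, TRUE),
                                 classifiers = c("svm", "rf"),
                                 k_grid = c(10L, 15L, 20L, 25L, 30L, 50L,
                                            70L, 100L, 200L)) {
  if (!length(methods) || !length(patterns) || !length(discretize) ||
      !length(fva) || !length(classifiers) || !length(k_grid))
    stop("every grid dimension needs at least one option", call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  patterns <- match.arg(patterns, several.ok = TRUE)
  classifiers <- match.arg(classifiers, several.ok = TRUE)

  specs <- list()
  for (k in sort(unique(as.integer(k_grid))))
    for (m in methods)
      for (p in patterns)
        for (d in sort(unique(discretize)))
          for (f in sort(unique(fva))) {
            if (f && p == "total") next
            for (cl in classifiers)
              specs[[length(specs) + 1L]] <-
                procedure_spec(m, p, k, d, f, cl)
          }
  specs
}

#' Run a grid of procedures against a dataset
#'
#' Evaluates every procedure with [evaluate_procedure()]. Each procedure
#' uses a seed derived from (master seed, its position in the canonical
#' enumeration), so the report is identical whatever the worker count or
#' scheduling; a failing procedure is recorded with its error message and
#' never aborts the rest of the grid.
#'
#' @param specs list of [procedure_spec()] (e.g. from
#'   [enumerate_procedures()]).
#' @param ds an [expression_dataset()].
#' @param plan a [bootstrap_plan()]; its `master_seed` is the grid master
#'   seed.
#' @param workers number of worker processes (forked; 1 = serial).
#' @return object of class `GridReport`: `results` (list, one
#'   `ProcedureResult` or failure record per spec, in spec order),
#'   `status` character vector (`"ok"`, `"truncated-k"` or
#'   `"failed: <msg>"`), dataset fingerprint, plan, package version.
#' @export
run_grid <- function(specs, ds, plan, workers = 1L) {
  if (!length(specs)) stop("empty procedure list", call. = FALSE)
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(plan, "BootstrapPlan"))
  workers <- max(1L, as.integer(workers))

  eval_one <- function(i) {
    proc_plan <- bootstrap_plan(B = plan$B,
                                master_seed = derive_seed(plan$master_seed, i),
                                max_redraws = plan$max_redraws)
    tryCatch(evaluate_procedure(specs[[i]], ds, proc_plan),
             error = function(e) {
               structure(list(spec = specs[[i]],
                              message = conditionMessage(e)),
                         class = "ProcedureFailure")
             })
  }
  idx <- seq_along(specs)
  results <- if (workers > 1L)
    parallel::mclapply(idx, eval_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  else lapply(idx, eval_one)

  status <- vapply(results, function(r) {
    if (inherits(r, "ProcedureFailure")) paste0("failed: ", r$message)
    else if (isTRUE(r$truncated)) "truncated-k"
    else "ok"
  }, character(1L))
  if (all(startsWith(status, "failed")))
    stop("all ", length(specs), " procedures failed; first error: ",
         results[[1L]]$message, call. = FALSE)

  counts <- table(ds$labels)
  structure(list(results = results, status = status,
                 dataset = list(n_genes = length(ds$gene_ids),
                                n_samples = length(ds$sample_ids),
                                class_counts = as.list(counts),
                                positive_class = ds$positive_class),
                 plan = unclass(plan),
                 version = as.character(utils::packageVersion("gsbench"))),
            class = "GridReport")
}

#' Best procedures of a grid report
#'
#' Applies the workbench's model-selection rule: among procedures that
#' completed, keep those with the smallest .632+ bootstrap error, and
#' among those the smallest k; ALL remaining ties are returned (equally
#' good procedures are equally reportable), in canonical grid order.
#'
#' @param report a [run_grid()] report.
#' @return list of the best `ProcedureResult`s.
#' @export
rank_results <- function(report) {
  stopifnot(inherits(report, "GridReport"))
  ok <- !startsWith(report$status, "failed")
  if (!any(ok)) stop("no procedure completed", call. = FALSE)
  res <- report$results[ok]
  errs <- vapply(res, `[[`, numeric(1L), "err632plus")
  res <- res[errs == min(errs)]
  ks <- vapply(res, function(r) r$spec$k, integer(1L))
  res[ks == min(ks)]
}

result_row <- function(r, status) {
  spec <- r$spec
  if (inherits(r, "ProcedureFailure")) {
    data.frame(fs_method = spec$fs_method, k = spec$k, pattern = spec$pattern,
               discretize = spec$discretize, fva = spec$fva,
               classifier = spec$classifier,
               err632plus = NA_real_, err_bar = NA_real_, err1 = NA_real_,
               gamma = NA_real_, status = status, genes = "",
               stringsAsFactors = FALSE)
  } else {
    data.frame(fs_method = spec$fs_method, k = spec$k, pattern = spec$pattern,
               discretize = spec$discretize, fva = spec$fva,
               classifier = spec$classifier,
               err632plus = r$err632plus, err_bar = r$err_bar, err1 = r$err1,
               gamma = r$gamma, status = status,
               genes = paste(r$gene_ids, collapse = ";"),
               stringsAsFactors = FALSE)
  }
}

#' Turn a grid report into a data frame
#'
#' One row per procedure with the spec columns, the .632+ error
#' decomposition, the run status and the semicolon-joined selected gene
#' list, sorted by (err632plus, k, canonical order).
#'
#' @param report a [run_grid()] report.
#' @return data.frame.
#' @export
grid_table <- function(report) {
  rows <- do.call(rbind, Map(result_row, report$results, report$status))
  ord <- order(rows$err632plus, rows$k, seq_len(nrow(rows)), na.last = TRUE)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Write the report files of a grid run
#'
#' Emits `grid.tsv` (one row per procedure, best first), `best.tsv` (the
#' [rank_results()] subset), `report.json` (the full machine-readable
#' report) and `run.log` (plan, seed, version, timestamp) into `out_dir`.
#'
#' @param report a [run_grid()] report.
#' @param out_dir output directory (created if absent).
#' @return character vector of the written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "GridReport"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- grid_table(report)
  grid_path <- file.path(out_dir, "grid.tsv")
  utils::write.table(grid, grid_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  best <- rank_results(report)
  best_report <- report
  keep <- vapply(report$results, function(r)
    any(vapply(best, identical, logical(1L), r)), logical(1L))
  best_report$results <- report$results[keep]
  best_report$status <- report$status[keep]
  best_path <- file.path(out_dir, "best.tsv")
  utils::write.table(grid_table(best_report), best_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_to_list(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("gsbench version: ", report$version),
    paste0("procedures: ", length(report$results)),
    paste0("bootstrap B: ", report$plan$B),
    paste0("master seed: ", report$plan$master_seed),
    paste0("dataset: ", report$dataset$n_genes, " genes x ",
           report$dataset$n_samples, " samples, positive class ",
           report$dataset$positive_class)
  ), log_path)

  invisible(c(grid_path, best_path, json_path, log_path))
}

report_to_list <- function(report) {
  list(
    dataset = report$dataset,
    plan = report$plan,
    version = report$version,
    procedures = Map(function(r, st) {
      base <- list(spec = unclass(r$spec), status = st)
      if (!inherits(r, "ProcedureFailure")) {
        base$estimate <- list(err_bar = r$err_bar, err1 = r$err1,
                              gamma = r$gamma, R = r$R, w = r$w,
                              err632plus = r$err632plus,
                              n_oob_excluded = r$n_oob_excluded)
        base$genes <- r$gene_ids
      } else {
        base$message <- r$message
      }
      base
    }, report$results, report$status)
  )
}

#' @export
print.GridReport <- function(x, ...) {
  cat("GridReport: ", length(x$results), " procedures on ",
      x$dataset$n_genes, " genes x ", x$dataset$n_samples, " samples\n",
      sep = "")
  n_fail <- sum(startsWith(x$status, "failed"))
  if (n_fail) cat(n_fail, "failed\n")
  best <- tryCatch(rank_results(x), error = function(e) NULL)
  if (!is.null(best)) {
    cat("best (err632plus=", format(best[[1L]]$err632plus, digits = 4),
        ", k=", best[[1L]]$spec$k, "):\n", sep = "")
    for (b in best) cat("  ", format_spec(b$spec), "\n", sep = "")
  }
  invisible(x)
}
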