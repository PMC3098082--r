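#' Plan a .632+ bootstrap run
#'
#' @param B number of bootstrap replicates (default 100).
#' @param master_seed integer seed; replicate r draws with a seed derived
#'   deterministically from (master_seed, r), so results do not depend on
#'   execution order or parallel scheduling.
#' @param max_redraws how many times a replicate whose in-bag sample
#'   contains a single class is redrawn (with the next derived seed)
#'   before the evaluation errors out.
#' @return object of class `BootstrapPlan`.
#' @export
bootstrap_plan <- function(B = 100L, master_seed = 1L, max_redraws = 50L) {
  stopifnot(B >= 1L, max_redraws >= 1L)
  structure(list(B = as.integer(B), master_seed = as.integer(master_seed),
                 max_redraws = as.integer(max_redraws)),
            class = "BootstrapPlan")
}

#' Draw one bootstrap replicate
#'
#' Draws n samples with replacement; the out-of-bag set is every sample
#' drawn zero times. Replicates whose in-bag multiset holds fewer than two
#' samples of either class cannot support the ranking statistics or train
#' a classifier and are redrawn with the next derived seed, up to
#' `plan$max_redraws` times.
#'
#' @param n number of samples (>= 4).
#' @param labels class label per sample.
#' @param plan a [bootstrap_plan()].
#' @param r replicate index (1-based).
#' @return list with `in_bag` (integer multiset of length n) and `oob`
#'   (sorted integer set, possibly empty).
#' @export
bootstrap_resample <- function(n, labels, plan, r) {
  stopifnot(n >= 4L, length(labels) == n)
  seed <- derive_seed(plan$master_seed, r)
  for (attempt in seq_len(plan$max_redraws)) {
    set.seed(seed)
    in_bag <- sample.int(n, n, replace = TRUE)
    counts <- table(factor(labels[in_bag], levels = unique(labels)))
    if (length(counts) == 2L && min(counts) >= 2L) {
      return(list(in_bag = in_bag,
                  oob = setdiff(seq_len(n), unique(in_bag))))
    }
    seed <- derive_seed(seed, attempt)
  }
  stop("replicate ", r, ": in-bag sample class-degenerate after ",
       plan$max_redraws, " redraws (class balance ",
       paste(names(table(labels)), table(labels), sep = "=", collapse = ", "),
       ")", call. = FALSE)
}

# ---- fitting one complete procedure -----------------------------------

# Fit the entire gene-selection procedure (rank -> pattern filter -> top-k
# -> transforms -> classifier) on the samples indexed by train_idx (a
# multiset for bootstrap replicates). Returns a fitted pipeline that can
# predict any sample subset of the same dataset.
fit_procedure <- function(spec, ds, train_idx, seed) {
  view <- ds_view(ds, train_idx)
  scores <- switch(spec$fs_method,
                   ttest = score_ttest(view),
                   wilcoxon = score_wilcoxon(view),
                   infogain = score_infogain(view),
                   stop("unknown fs_method: ", spec$fs_method, call. = FALSE))
  sel <- select_top_k(scores, spec$pattern, spec$k)
  if (!length(sel$gene_ids))
    stop("no genes in pattern group '", spec$pattern, "'", call. = FALSE)

  build_block <- function(sample_idx) {
    block <- gene_block(ds_view(ds, sample_idx), sel$gene_ids)
    if (spec$fva) block <- feature_vector_addition(block, spec$pattern)
    block
  }
  train_block <- build_block(train_idx)
  disc <- NULL
  if (spec$discretize) {
    disc <- fit_discretizer(train_block, view$labels)
    train_block <- apply_discretizer(disc, train_block)
  }
  model <- train_model(classifier_spec(spec$classifier, seed = seed),
                       train_block, view$labels)

  structure(list(spec = spec, gene_ids = sel$gene_ids,
                 truncated = sel$truncated, discretizer = disc,
                 model = model, build_block = build_block),
            class = "FittedProcedure")
}

predict_procedure <- function(fit, ds, sample_idx) {
  block <- fit$build_block(sample_idx)
  if (!is.null(fit$discretizer))
    block <- apply_discretizer(fit$discretizer, block)
  predict_model(fit$model, block)
}

#' Resubstitution error of a procedure
#'
#' Runs the full procedure on all samples and scores its predictions on
#' those same samples — the optimistic training-set error err-bar of the
#' .632+ estimator.
#'
#' @param spec a [procedure_spec()].
#' @param ds an [expression_dataset()].
#' @param seed seed for classifier training.
#' @return list with `err_bar`, the predictions, and the fitted procedure.
#' @export
resubstitution_error <- function(spec, ds, seed = 1L) {
  all_idx <- seq_along(ds$sample_ids)
  fit <- fit_procedure(spec, ds, all_idx, seed = seed)
  pred <- predict_procedure(fit, ds, all_idx)
  list(err_bar = misclassification_error(pred, ds$labels),
       predictions = pred, fit = fit)
}

#' Leave-one-out bootstrap error of a procedure
#'
#' For each replicate the ENTIRE procedure — feature ranking, pattern
#' filtering, top-k selection, transforms and classifier training — is
#' re-run on the in-bag samples only, then applied to that replicate's
#' out-of-bag samples. Each sample's out-of-bag errors are first averaged
#' within the sample and then across samples (samples never out-of-bag are
#' excluded from the mean and counted). Re-running selection inside every
#' resample is what keeps the estimate honest: selecting genes once on the
#' full data and only refitting the classifier would leak the test labels
#' into the gene list.
#'
#' @inheritParams resubstitution_error
#' @param plan a [bootstrap_plan()].
#' @return list with `err1` and `n_oob_excluded`.
#' @export
loo_bootstrap_error <- function(spec, ds, plan) {
  n <- length(ds$sample_ids)
  err_sum <- numeric(n)
  oob_count <- integer(n)
  for (r in seq_len(plan$B)) {
    bs <- bootstrap_resample(n, ds$labels, plan, r)
    if (!length(bs$oob)) next
    fit <- fit_procedure(spec, ds, bs$in_bag,
                         seed = derive_seed(plan$master_seed, plan$B + r))
    pred <- predict_procedure(fit, ds, bs$oob)
    wrong <- pred != ds$labels[bs$oob]
    err_sum[bs$oob] <- err_sum[bs$oob] + wrong
    oob_count[bs$oob] <- oob_count[bs$oob] + 1L
  }
  covered <- oob_count > 0L
  if (!any(covered))
    stop("no sample was ever out-of-bag; increase B (currently ", plan$B,
         ")", call. = FALSE)
  list(err1 = mean(err_sum[covered] / oob_count[covered]),
       n_oob_excluded = sum(!covered))
}

#' No-information error rate
#'
#' The expected error if labels and predictions were independent:
#' \eqn{\gamma = \sum_c p_c (1 - q_c)} with \eqn{p_c} the observed class
#' proportions and \eqn{q_c} the proportions predicted as class c by the
#' full-data resubstitution model.
#'
#' @param labels true labels.
#' @param predictions resubstitution predictions on the same samples.
#' @return gamma, in \[0, 1\].
#' @export
no_information_rate <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions))
  classes <- sort(unique(c(labels, predictions)))
  p <- vapply(classes, function(cl) mean(labels == cl), numeric(1L))
  q <- vapply(classes, function(cl) mean(predictions == cl), numeric(1L))
  sum(p * (1 - q))
}

#' The .632+ bootstrap estimator
#'
#' Blends the optimistic resubstitution error and the pessimistic
#' leave-one-out bootstrap error with a data-driven weight. With
#' err1' = min(err1, gamma), the relative overfitting rate is
#' \eqn{R = (err1' - \bar{err}) / (\gamma - \bar{err})} when
#' err1' > err-bar and gamma > err-bar (else 0), clipped to \[0, 1\]; the
#' weight is \eqn{w = 0.632 / (1 - 0.368 R)} and the estimate
#' \eqn{(1 - w)\,\bar{err} + w\,err1'}. R = 0 recovers the plain .632
#' estimator; R = 1 (maximal overfitting) gives w = 1 and the estimate
#' collapses to err1'.
#'
#' @param err_bar resubstitution error in \[0, 1\].
#' @param err1 leave-one-out bootstrap error in \[0, 1\].
#' @param gamma no-information rate in \[0, 1\].
#' @return list with `err1_used`, `R`, `w` (in \[0.632, 1\]) and
#'   `err632plus`, which always lies between min and max of (err_bar,
#'   err1_used).
#' @export
err632plus <- function(err_bar, err1, gamma) {
  stopifnot(err_bar >= 0, err_bar <= 1, err1 >= 0, err1 <= 1,
            gamma >= 0, gamma <= 1)
  err1p <- min(err1, gamma)
  R <- if (err1p > err_bar && gamma > err_bar)
    (err1p - err_bar) / (gamma - err_bar) else 0
  R <- min(1, max(0, R))
  w <- 0.632 / (1 - 0.368 * R)
  list(err1_used = err1p, R = R, w = w,
       err632plus = (1 - w) * err_bar + w * err1p)
}

#' Evaluate one gene-selection procedure end to end
#'
#' Composes [resubstitution_error()], [loo_bootstrap_error()],
#' [no_information_rate()] and [err632plus()], and records the gene list
#' the procedure selects on the FULL dataset (the reportable gene set).
#'
#' @inheritParams loo_bootstrap_error
#' @return object of class `ProcedureResult`: the spec, the
#'   `BootstrapEstimate` fields (`err_bar`, `err1`, `gamma`, `R`, `w`,
#'   `err632plus`, `n_oob_excluded`), the selected `gene_ids`, and
#'   `truncated`.
#' @export
evaluate_procedure <- function(spec, ds, plan) {
  stopifnot(inherits(spec, "ProcedureSpec"), inherits(ds, "ExpressionDataset"),
            inherits(plan, "BootstrapPlan"))
  resub <- resubstitution_error(spec, ds, seed = derive_seed(plan$master_seed, 0L))
  loo <- loo_bootstrap_error(spec, ds, plan)
  gamma <- no_information_rate(ds$labels, resub$predictions)
  tail <- err632plus(resub$err_bar, loo$err1, gamma)
  structure(list(spec = spec,
                 err_bar = resub$err_bar, err1 = loo$err1, gamma = gamma,
                 R = tail$R, w = tail$w, err632plus = tail$err632plus,
                 n_oob_excluded = loo$n_oob_excluded,
                 gene_ids = resub$fit$gene_ids,
                 truncated = resub$fit$truncated),
            class = "ProcedureResult")
}

#' @export
print.ProcedureResult <- function(x, ...) {
  cat(format_spec(x$spec), "\n")
  cat(sprintf("  err632plus=%.4f (err_bar=%.4f, err1=%.4f, gamma=%.4f, w=%.3f)\n",
              x$err632plus, x$err_bar, x$err1, x$gamma, x$w))
  cat("  genes: ", paste(utils::head(x$gene_ids, 8L), collapse = ", "),
      if (length(x$gene_ids) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
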