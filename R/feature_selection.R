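#' Rank genes by a two-sample Welch t-test
#'
#' Per gene: the Welch (unequal-variance) t statistic between the two
#' classes and its two-sided p-value with Welch-Satterthwaite degrees of
#' freedom. Genes with zero variance in both classes and equal means are
#' assigned t = 0, p = 1; zero pooled variance with unequal means gives
#' |t| = Inf, p = 0. The ranking key is (p ascending, |t| descending,
#' gene file order), broken deterministically.
#'
#' @param ds an [expression_dataset()] (each class needs >= 2 samples), or
#'   an internal sample view.
#' @return data.frame with columns `gene_id`, `statistic`, `p_value`,
#'   `info_gain` (NA here), `direction` (`"up"`/`"down"` relative to the
#'   positive class) and `rank`; rows in gene file order. The attribute
#'   `"method"` records the statistic used.
#' @export
score_ttest <- function(ds) {
  x <- ds$matrix
  pos <- ds$labels == ds$positive_class
  n1 <- sum(pos); n2 <- sum(!pos)
  stopifnot(n1 >= 2L, n2 >= 2L)
  x1 <- x[, pos, drop = FALSE]; x2 <- x[, !pos, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  tt[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign((m1 - m2)[degen]))
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  score_frame(ds, statistic = tt, p_value = p, info_gain = NA_real_,
              center = 0, method = "ttest")
}

#' Rank genes by the Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Per gene: the Mann-Whitney U statistic for the positive class against
#' the other class, with a two-sided p-value from the exact null
#' distribution when `min(n1, n2) <= 12` and the gene has no tied values,
#' and otherwise from the normal approximation with tie correction and
#' continuity correction. Being a rank statistic, any strictly increasing
#' transform of a gene's values leaves its U and p unchanged. Ranking key:
#' (p ascending, |U - n1 n2 / 2| descending, gene file order).
#'
#' @inheritParams score_ttest
#' @inherit score_ttest return
#' @export
score_wilcoxon <- function(ds) {
  x <- ds$matrix
  pos <- ds$labels == ds$positive_class
  n1 <- sum(pos); n2 <- sum(!pos)
  stopifnot(n1 >= 2L, n2 >= 2L)
  n <- n1 + n2
  mu <- n1 * n2 / 2

  rt <- row_ranks(x)
  U <- rowSums(rt$ranks[, pos, drop = FALSE]) - n1 * (n1 + 1) / 2
  tie_term <- rt$tie_term
  has_ties <- tie_term > 0
  exact <- !has_ties & min(n1, n2) <= 12L

  p <- rep(NA_real_, nrow(x))
  if (any(exact)) {
    u <- U[exact]
    pe <- ifelse(u > mu,
                 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE),
                 2 * stats::pwilcox(u, n1, n2))
    p[exact] <- pmin(1, pe)
  }
  if (any(!exact)) {
    u <- U[!exact]
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term[!exact] / (n * (n - 1)))
    d <- u - mu
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)     # continuity correction
    pa <- 2 * stats::pnorm(-abs(z))
    pa[sigma2 == 0] <- 1                        # all values tied
    p[!exact] <- pmin(1, pa)
  }
  score_frame(ds, statistic = U, p_value = p, info_gain = NA_real_,
              center = mu, method = "wilcoxon")
}

#' Rank genes by information gain under MDL discretization
#'
#' Per gene: the reduction in class entropy achieved by the interval
#' partition returned by [mdl_discretize()],
#' \eqn{IG = H(class) - \sum_i (n_i/N) H(class \mid interval_i)} in bits.
#' Genes whose MDL search accepts no cut score 0. For two classes
#' \eqn{0 \le IG \le H(class) \le 1} bit. Ranking key: (IG descending,
#' gene file order).
#'
#' @inheritParams score_ttest
#' @param single_split if `TRUE`, the discretizer stops after one accepted
#'   cut per gene instead of recursing.
#' @inherit score_ttest return
#' @export
score_infogain <- function(ds, single_split = FALSE) {
  x <- ds$matrix
  labels <- ds$labels
  y <- match(labels, unique(labels))
  k_all <- max(y)
  ig <- vapply(seq_len(nrow(x)), function(i) {
    cuts <- mdl_cuts(x[i, ], y, k_all, single_split = single_split)
    info_gain_from_cuts(x[i, ], labels, cuts)
  }, numeric(1L))
  score_frame(ds, statistic = ig, p_value = NA_real_, info_gain = ig,
              center = NA_real_, method = "infogain")
}

#' Up/down direction of every gene
#'
#' A gene is "up-regulated" when its mean expression in the positive class
#' exceeds its mean in the other class, and "down-regulated" otherwise;
#' exactly equal means are called "down" (a documented, deterministic tie
#' rule).
#'
#' @inheritParams score_ttest
#' @return character vector (`"up"`/`"down"`) in gene file order.
#' @export
assign_direction <- function(ds) {
  pos <- ds$labels == ds$positive_class
  m1 <- rowMeans(ds$matrix[, pos, drop = FALSE])
  m2 <- rowMeans(ds$matrix[, !pos, drop = FALSE])
  unname(ifelse(m1 > m2, "up", "down"))
}

# Within-row ranks (ties averaged, as rank()) of every row of a matrix in
# one radix pass, plus the per-row tie-correction term sum(t^3 - t).
# Exact: sorts on (row, value) keys rather than perturbing values.
row_ranks <- function(x) {
  G <- nrow(x); n <- ncol(x); N <- G * n
  xv <- as.vector(x)                       # column-major
  rw <- rep.int(seq_len(G), n)             # row index of each element
  ord <- order(rw, xv, method = "radix")
  rs <- rw[ord]; vs <- xv[ord]
  pos <- rep(seq_len(n), times = G)        # within-row position after sort
  newrun <- c(TRUE, (rs[-1L] != rs[-N]) | (vs[-1L] != vs[-N]))
  runid <- cumsum(newrun)
  lens <- tabulate(runid)
  avg <- (pos[newrun] + (lens - 1) / 2)[runid]   # average rank of tied run
  ranks <- numeric(N)
  ranks[ord] <- avg
  tie_term <- as.vector(rowsum(lens^3 - lens, rs[newrun]))
  list(ranks = matrix(ranks, nrow = G), tie_term = tie_term)
}

# Shared assembly of the per-gene score table; computes the deterministic
# rank used by select_top_k. `center` is the null center of the statistic
# (0 for t, n1*n2/2 for U); NA means "larger statistic is better" (IG).
score_frame <- function(ds, statistic, p_value, info_gain, center, method) {
  idx <- seq_along(ds$gene_ids)
  ord <- if (is.na(center[1L]) && method == "infogain") {
    order(-statistic, idx)
  } else {
    order(p_value, -abs(statistic - center), idx)
  }
  rank <- integer(length(idx))
  rank[ord] <- idx
  out <- data.frame(gene_id = ds$gene_ids,
                    statistic = statistic,
                    p_value = p_value,
                    info_gain = info_gain,
                    direction = assign_direction(ds),
                    rank = rank,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}

#' Select the top k genes within a pattern group
#'
#' Filters a score table to the requested expression pattern (`"total"`
#' keeps all genes, `"up"`/`"down"` keep only genes of that direction),
#' sorts by the precomputed rank and returns the first `k` gene ids. When
#' the group holds fewer than `k` genes all of them are returned and the
#' result is flagged truncated.
#'
#' @param scores a score table from one of the `score_*` functions.
#' @param pattern `"total"`, `"up"` or `"down"`.
#' @param k positive integer number of genes to select.
#' @return list with `gene_ids` (ordered character vector) and `truncated`
#'   (logical).
#' @export
select_top_k <- function(scores, pattern = c("total", "up", "down"), k) {
  pattern <- match.arg(pattern)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  keep <- if (pattern == "total") rep(TRUE, nrow(scores))
  else scores$direction == pattern
  sub <- scores[keep, , drop = FALSE]
  sub <- sub[order(sub$rank), , drop = FALSE]
  n_take <- min(nrow(sub), as.integer(k))
  list(gene_ids = sub$gene_id[seq_len(n_take)], truncated = n_take < k)
}

#' Write a score table as TSV
#'
#' @param scores a score table from one of the `score_*` functions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
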