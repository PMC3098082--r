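#' Entropy-based discretization with the MDL stopping rule
#'
#' Recursively splits a numeric vector at the cut point minimizing the
#' class-entropy of the induced partition (Fayyad-Irani style). A candidate
#' cut is the midpoint between adjacent distinct values; a split is kept
#' only if its information gain exceeds the minimum-description-length
#' acceptance threshold
#' \deqn{gain > \frac{\log_2(n-1)}{n} + \frac{\Delta}{n}, \quad
#'   \Delta = \log_2(3^c - 2) - [c\,H(S) - c_1 H(S_1) - c_2 H(S_2)]}
#' where \eqn{c} counts the classes present in a segment. Accepted halves
#' are split again recursively unless `single_split = TRUE`.
#'
#' @param values numeric vector (length >= 2).
#' @param labels class label per value.
#' @param single_split if `TRUE`, stop after the first accepted cut.
#' @return sorted numeric vector of accepted cut points; `numeric(0)` when
#'   no cut passes the MDL test (constant vectors, pure labels, or no
#'   worthwhile split).
#' @export
mdl_discretize <- function(values, labels, single_split = FALSE) {
  n <- length(values)
  stopifnot(n >= 2L, length(labels) == n)
  y <- match(labels, unique(labels))
  mdl_cuts(values, y, max(y), single_split)
}

# entropy (bits) of each row of a count matrix, given row totals
row_entropy <- function(counts, totals) {
  p <- counts / totals
  h <- p * log2(p)
  h[!is.finite(h)] <- 0
  -rowSums(h)
}

# Core recursive MDL search; y must be integer codes 1..k_all. Iterative
# stack instead of recursion; entropies of all left/right partitions of a
# segment come from one cumulative class-count pass.
mdl_cuts <- function(values, y, k_all, single_split = FALSE) {
  ord <- order(values)
  v <- values[ord]
  y <- y[ord]
  n <- length(v)
  if (k_all == 2L) return(mdl_cuts2(v, y == 1L, single_split))

  cuts <- numeric(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1L]; hi <- seg[2L]
    m <- hi - lo + 1L
    if (m < 2L) next
    vs <- v[lo:hi]; ys <- y[lo:hi]
    cand <- which(vs[-m] < vs[-1L])          # split after position i
    if (!length(cand)) next

    counts <- matrix(0, nrow = m, ncol = k_all)
    counts[cbind(seq_len(m), ys)] <- 1
    counts <- apply(counts, 2L, cumsum)
    if (m == 1L) counts <- matrix(counts, nrow = 1L)
    total <- counts[m, ]

    nl <- cand
    nr <- m - cand
    left <- counts[cand, , drop = FALSE]
    right <- rep(total, each = length(cand)) - left
    h_left <- row_entropy(left, nl)
    h_right <- row_entropy(right, nr)
    e <- (nl * h_left + nr * h_right) / m

    best <- which.min(e)                     # leftmost minimum
    i <- cand[best]
    h_s <- row_entropy(matrix(total, nrow = 1L), m)
    gain <- h_s - e[best]

    c_s <- sum(total > 0)
    c_1 <- sum(left[best, ] > 0)
    c_2 <- sum(right[best, ] > 0)
    delta <- log2(3^c_s - 2) -
      (c_s * h_s - c_1 * h_left[best] - c_2 * h_right[best])
    if (gain <= (log2(m - 1) + delta) / m) next

    cuts <- c(cuts, (vs[i] + vs[i + 1L]) / 2)
    if (!single_split) {
      stack[[length(stack) + 1L]] <- c(lo, lo + i - 1L)
      stack[[length(stack) + 1L]] <- c(lo + i, hi)
    }
  }
  sort(cuts)
}

# binary entropy (bits), vectorized, 0 log 0 := 0
h2 <- function(p) {
  h <- numeric(length(p))
  i <- p > 0 & p < 1
  q <- p[i]
  h[i] <- -(q * log2(q) + (1 - q) * log2(1 - q))
  h
}

# Two-class specialization of the MDL search (the workbench's only case in
# practice); v must already be sorted, is1 a logical class indicator
# aligned with v. Same acceptance rule as the generic path.
mdl_cuts2 <- function(v, is1, single_split = FALSE) {
  n <- length(v)
  cuts <- numeric(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1L]; hi <- seg[2L]
    m <- hi - lo + 1L
    if (m < 2L) next
    vs <- v[lo:hi]
    c1 <- cumsum(is1[lo:hi])
    t1 <- c1[m]
    if (t1 == 0 || t1 == m) next             # pure segment, nothing to gain
    cand <- which(vs[-m] < vs[-1L])
    if (!length(cand)) next

    nl <- cand; nr <- m - cand
    l1 <- c1[cand]; r1 <- t1 - l1
    h_left <- h2(l1 / nl)
    h_right <- h2(r1 / nr)
    e <- (nl * h_left + nr * h_right) / m
    best <- which.min(e)
    i <- cand[best]
    h_s <- h2(t1 / m)
    gain <- h_s - e[best]

    c_1 <- (l1[best] > 0) + (nl[best] > l1[best])
    c_2 <- (r1[best] > 0) + (nr[best] > r1[best])
    delta <- log2(7) -
      (2 * h_s - c_1 * h_left[best] - c_2 * h_right[best])
    if (gain <= (log2(m - 1) + delta) / m) next

    cuts <- c(cuts, (vs[i] + vs[i + 1L]) / 2)
    if (!single_split) {
      stack[[length(stack) + 1L]] <- c(lo, lo + i - 1L)
      stack[[length(stack) + 1L]] <- c(lo + i, hi)
    }
  }
  sort(cuts)
}

# Information gain (bits) of the partition induced by `cuts` on `values`.
info_gain_from_cuts <- function(values, labels, cuts) {
  if (!length(cuts)) return(0)
  y <- match(labels, unique(labels))
  bin <- findInterval(values, cuts)
  n <- length(values)
  cond <- 0
  for (b in unique(bin)) {
    sel <- bin == b
    cond <- cond + sum(sel) / n * entropy_bits(y[sel])
  }
  entropy_bits(y) - cond
}
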