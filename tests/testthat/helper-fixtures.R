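# Fixture builders and independent reference implementations used across
# the suite. References here are deliberately naive (recursion, explicit
# enumeration, entropies recomputed from scratch) and share no code with
# the package internals they check.

tiny_dataset <- function(values, labels, positive_class = NULL,
                         n_genes = NULL) {
  mat <- if (is.matrix(values)) values
  else matrix(values, nrow = n_genes %||% 1L, byrow = TRUE)
  expression_dataset(mat,
                     gene_ids = paste0("g", seq_len(nrow(mat))),
                     sample_ids = paste0("s", seq_len(ncol(mat))),
                     labels = labels, positive_class = positive_class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tiny_file <- function(lines, eol = "\n") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path, sep = eol)
  path
}

# -- naive reference: Shannon entropy and recursive MDL discretization ---

ref_entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

ref_mdl <- function(values, labels) {
  n <- length(values)
  if (n < 2L) return(numeric(0))
  ord <- order(values)
  v <- values[ord]
  y <- labels[ord]
  cands <- which(v[-n] < v[-1L])
  if (!length(cands)) return(numeric(0))
  ents <- sapply(cands, function(i)
    (i * ref_entropy(y[1:i]) + (n - i) * ref_entropy(y[(i + 1):n])) / n)
  i <- cands[which.min(ents)]
  hs <- ref_entropy(y)
  gain <- hs - min(ents)
  ks <- length(unique(y))
  k1 <- length(unique(y[1:i])); k2 <- length(unique(y[(i + 1):n]))
  delta <- log2(3^ks - 2) -
    (ks * hs - k1 * ref_entropy(y[1:i]) - k2 * ref_entropy(y[(i + 1):n]))
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (v[i] + v[i + 1L]) / 2
  sort(c(ref_mdl(v[1:i], y[1:i]), cut, ref_mdl(v[(i + 1):n], y[(i + 1):n])))
}

ref_info_gain <- function(values, labels, cuts) {
  if (!length(cuts)) return(0)
  bin <- findInterval(values, cuts)
  cond <- sum(sapply(unique(bin), function(b) {
    sel <- bin == b
    mean(sel) * ref_entropy(labels[sel])
  }))
  ref_entropy(labels) - cond
}

# entropy-minimizing first cut over ALL placements, ignoring MDL: the
# accepted first cut of the recursive search must coincide with it
ref_best_cut <- function(values, labels) {
  n <- length(values)
  ord <- order(values)
  v <- values[ord]; y <- labels[ord]
  cands <- which(v[-n] < v[-1L])
  if (!length(cands)) return(NA_real_)
  ents <- sapply(cands, function(i)
    (i * ref_entropy(y[1:i]) + (n - i) * ref_entropy(y[(i + 1):n])) / n)
  i <- cands[which.min(ents)]
  (v[i] + v[i + 1L]) / 2
}

# -- naive reference: exact two-sided Mann-Whitney p by full enumeration --

ref_wilcoxon_exact <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  picks <- utils::combn(n1 + n2, n1)
  us <- apply(picks, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}
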