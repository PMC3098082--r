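two_class_labels <- function(n1, n2) c(rep("A", n1), rep("B", n2))

test_that("Welch t scores match the textbook computation and degenerate rules", {
  # strong separation: compare against stats::t.test (independent route;
  # the package computes the statistic vectorized from the formula)
  ds <- tiny_dataset(c(10, 11, 12, 1, 2, 3), two_class_labels(3, 3))
  sc <- score_ttest(ds)
  ref <- t.test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sc$statistic, unname(ref$statistic))
  expect_equal(sc$p_value, ref$p.value)
  expect_equal(sc$direction, "up")

  # identical values in both classes: t = 0, p = 1
  flat <- tiny_dataset(c(1, 2, 3, 1, 2, 3), two_class_labels(3, 3))
  sc2 <- score_ttest(flat)
  expect_equal(sc2$statistic, 0)
  expect_equal(sc2$p_value, 1)

  # both classes constant at the same value
  const <- tiny_dataset(rep(5, 6), two_class_labels(3, 3))
  expect_equal(score_ttest(const)$p_value, 1)

  # both classes constant at different values: maximal evidence
  sep <- tiny_dataset(c(9, 9, 9, 2, 2, 2), two_class_labels(3, 3))
  expect_equal(score_ttest(sep)$p_value, 0)
})

test_that("Welch scores agree with t.test across random genes", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:9, 1); n2 <- sample(2:9, 1)
    v <- rnorm(n1 + n2, sd = sample(c(0.5, 2), 1))
    ds <- tiny_dataset(v, two_class_labels(n1, n2))
    sc <- score_ttest(ds)
    ref <- t.test(v[seq_len(n1)], v[-seq_len(n1)])
    expect_equal(sc$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(sc$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Wilcoxon U and exact p reproduce the frozen enumeration example", {
  # class A = (1,2,3), class B = (4,5,6): U = 0 and the exact two-sided p
  # is 2/20 = 0.1 (2 of the C(6,3) = 20 rank assignments are as extreme)
  ds <- tiny_dataset(c(1, 2, 3, 4, 5, 6), two_class_labels(3, 3))
  sc <- score_wilcoxon(ds)
  expect_equal(sc$statistic, 0)
  expect_equal(sc$p_value, 0.1)

  # identical multisets in both classes -> p = 1
  same <- tiny_dataset(c(7, 8, 9, 9, 8, 7), two_class_labels(3, 3))
  expect_equal(score_wilcoxon(same)$p_value, 1)

  # all values tied across both classes -> p = 1
  allsame <- tiny_dataset(rep(4, 8), two_class_labels(4, 4))
  expect_equal(score_wilcoxon(allsame)$p_value, 1)
})

test_that("exact Wilcoxon p equals full enumeration for n1, n2 <= 6", {
  set.seed(21)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(seq_len(50), n1 + n2)    # distinct -> tie-free, exact branch
    ds <- tiny_dataset(v, two_class_labels(n1, n2))
    sc <- score_wilcoxon(ds)
    ref <- ref_wilcoxon_exact(v[seq_len(n1)], v[-seq_len(n1)])
    expect_equal(sc$statistic, ref$U)
    expect_equal(sc$p_value, ref$p, tolerance = 1e-12)
  }
})

test_that("Wilcoxon approximate branch matches wilcox.test with ties", {
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(13:20, 1); n2 <- sample(13:20, 1)
    v <- round(rnorm(n1 + n2), 1)        # rounding forces ties
    ds <- tiny_dataset(v, two_class_labels(n1, n2))
    sc <- score_wilcoxon(ds)
    ref <- suppressWarnings(
      wilcox.test(v[seq_len(n1)], v[-seq_len(n1)], exact = FALSE,
                  correct = TRUE))
    expect_equal(sc$statistic, unname(ref$statistic))
    expect_equal(sc$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("MDL discretization finds the class-pure cut and stops otherwise", {
  # one clean boundary between (1,2,3 | A) and (10,11,12 | B): single cut
  # at the midpoint 6.5
  expect_equal(mdl_discretize(c(1, 2, 3, 10, 11, 12),
                              c("A", "A", "A", "B", "B", "B")), 6.5)
  # pure labels: zero entropy, nothing to gain
  expect_length(mdl_discretize(c(1, 2, 3, 4), rep("A", 4)), 0)
  # constant vector: no candidate boundary
  expect_length(mdl_discretize(rep(2, 6), c("A", "A", "A", "B", "B", "B")), 0)
  # order of presentation is irrelevant
  expect_equal(mdl_discretize(c(10, 1, 11, 2, 12, 3),
                              c("B", "A", "B", "A", "B", "A")), 6.5)
})

test_that("MDL cuts agree with a naive recursive reference on random cases", {
  set.seed(7)
  n_checked <- 0
  for (i in 1:300) {
    n <- sample(4:20, 1)
    v <- round(rnorm(n), sample(c(0, 1, 5), 1))
    y <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(mdl_discretize(v, y), ref_mdl(v, y))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 250)
})

test_that("information gain uses the MDL partition and respects its bounds", {
  # perfect separation of 4 vs 4: H(class) = 1 bit, conditional entropy 0
  ds <- tiny_dataset(c(1, 2, 3, 4, 10, 11, 12, 13), two_class_labels(4, 4))
  expect_equal(score_infogain(ds)$info_gain, 1.0)

  # constant gene scores zero
  const <- tiny_dataset(rep(3, 8), two_class_labels(4, 4))
  expect_equal(score_infogain(const)$info_gain, 0)

  # 0 <= IG <= H(class) <= 1 bit over random genes (two classes)
  set.seed(13)
  mat <- matrix(rnorm(50 * 14), nrow = 50)
  dsr <- tiny_dataset(mat, two_class_labels(8, 6))
  ig <- score_infogain(dsr)$info_gain
  h_class <- -sum(c(8, 6) / 14 * log2(c(8, 6) / 14))
  expect_true(all(ig >= 0))
  expect_true(all(ig <= h_class + 1e-12))
  expect_lte(h_class, 1)
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(17)
  mat <- matrix(rnorm(40 * 12, mean = 2), nrow = 40)
  ds <- tiny_dataset(mat, two_class_labels(6, 6))
  trans <- tiny_dataset(exp(mat / 2), two_class_labels(6, 6))

  w1 <- score_wilcoxon(ds); w2 <- score_wilcoxon(trans)
  expect_equal(w2$statistic, w1$statistic)
  expect_equal(w2$p_value, w1$p_value)
  expect_equal(w2$rank, w1$rank)

  i1 <- score_infogain(ds); i2 <- score_infogain(trans)
  expect_equal(i2$info_gain, i1$info_gain)
  expect_equal(i2$rank, i1$rank)
})

test_that("direction calls follow positive-class means with a down tie rule", {
  ds <- tiny_dataset(matrix(c(5, 5, 2, 2,     # up: positive mean higher
                              2, 2, 5, 5,     # down
                              3, 3, 3, 3),    # exact tie -> down
                            nrow = 3, byrow = TRUE),
                     labels = c("A", "A", "B", "B"), positive_class = "A")
  expect_equal(assign_direction(ds), c("up", "down", "down"))
  # flipping the positive class flips the strict calls
  flipped <- tiny_dataset(matrix(c(5, 5, 2, 2), nrow = 1),
                          labels = c("A", "A", "B", "B"), positive_class = "B")
  expect_equal(assign_direction(flipped), "down")
})

test_that("select_top_k filters by pattern, respects ranks and flags truncation", {
  set.seed(5)
  mat <- rbind(matrix(rnorm(20, mean = 3), nrow = 5),        # 5 up genes
               matrix(rnorm(20, mean = -3), nrow = 5))       # 5 down genes
  mat[, 3:4] <- -mat[, 3:4]
  ds <- tiny_dataset(mat, labels = c("A", "A", "B", "B"), positive_class = "A")
  sc <- score_ttest(ds)

  top3 <- select_top_k(sc, "total", 3)
  expect_length(top3$gene_ids, 3)
  expect_false(top3$truncated)
  # the selected genes are the 3 best-ranked overall
  expect_equal(top3$gene_ids, sc$gene_id[order(sc$rank)][1:3])

  up <- select_top_k(sc, "up", 8)
  expect_true(up$truncated)
  expect_true(all(sc$direction[match(up$gene_ids, sc$gene_id)] == "up"))

  # union consistency: the top-k overall is contained in the union of the
  # per-direction top-k lists
  k <- 4
  both <- union(select_top_k(sc, "up", k)$gene_ids,
                select_top_k(sc, "down", k)$gene_ids)
  expect_true(all(select_top_k(sc, "total", k)$gene_ids %in% both))
})

test_that("equal p-values break ties by statistic then file order, reproducibly", {
  # two identical genes and one weaker gene: identical rows tie on p and
  # |t|, so file order decides
  mat <- rbind(c(10, 11, 1, 2), c(10, 11, 1, 2), c(5, 6, 4, 5))
  ds <- tiny_dataset(mat, labels = c("A", "A", "B", "B"))
  sc <- score_ttest(ds)
  expect_equal(select_top_k(sc, "total", 2)$gene_ids, c("g1", "g2"))
  expect_identical(select_top_k(sc, "total", 2)$gene_ids,
                   select_top_k(sc, "total", 2)$gene_ids)
})

test_that("score tables export as TSV", {
  ds <- tiny_dataset(c(1, 2, 3, 4, 5, 6), two_class_labels(3, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(score_wilcoxon(ds), path)
  back <- read.delim(path)
  expect_equal(nrow(back), 1)
  expect_equal(back$gene_id, "g1")
  expect_true(all(c("statistic", "p_value", "direction", "rank")
                  %in% names(back)))
})
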