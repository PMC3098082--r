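test_that("the default grid enumerates exactly 60 procedures per k", {
  specs <- enumerate_procedures(k_grid = 10)
  expect_length(specs, 60)
  patterns <- vapply(specs, function(s) s$pattern, character(1))
  expect_equal(sum(patterns == "total"), 12)
  expect_equal(sum(patterns %in% c("up", "down")), 48)
  # fva never combines with the total pattern
  expect_false(any(vapply(specs, function(s)
    s$fva && s$pattern == "total", logical(1))))
  # canonical order is reproducible
  expect_identical(vapply(specs, gsbench:::format_spec, character(1)),
                   vapply(enumerate_procedures(k_grid = 10),
                          gsbench:::format_spec, character(1)))
})

test_that("restricted grids follow the counting rule", {
  expect_length(enumerate_procedures(patterns = "total", k_grid = 10), 12)
  expect_length(enumerate_procedures(k_grid = c(10, 20, 30, 50, 100)), 300)
  expect_length(enumerate_procedures(methods = "wilcoxon",
                                     patterns = c("up", "down"),
                                     classifiers = "svm", k_grid = 5), 8)

  # closed-form count checked against exhaustive generation over subsets
  for (m in 1:3) for (pat in list("total", c("up", "down"),
                                  c("total", "up", "down")))
    for (d in list(FALSE, c(FALSE, TRUE))) for (f in list(TRUE, c(FALSE, TRUE)))
      for (cl in list("svm", c("svm", "rf"))) {
        n_total <- as.integer("total" %in% pat)
        n_ud <- length(setdiff(pat, "total"))
        expected <- m * length(d) * length(cl) *
          (n_total * as.integer(FALSE %in% f) + n_ud * length(f))
        got <- tryCatch(length(enumerate_procedures(
          methods = c("ttest", "wilcoxon", "infogain")[seq_len(m)],
          patterns = pat, discretize = d, fva = f, classifiers = cl,
          k_grid = 10)), error = function(e) 0L)
        expect_equal(got, expected)
      }

  expect_error(enumerate_procedures(methods = character(0), k_grid = 10),
               "at least one option")
  expect_error(procedure_spec("ttest", "total", fva = TRUE),
               "up- or down-regulated")
})

small_grid_fixture <- function(seed = 1) {
  sim <- generate_dataset(simulation_config(
    n_genes = 40, n1 = 8, n2 = 8, n_up = 4, n_down = 4, effect_size = 3,
    seed = seed))
  specs <- enumerate_procedures(methods = c("ttest", "wilcoxon"),
                                patterns = c("total", "up"),
                                discretize = FALSE, fva = c(FALSE, TRUE),
                                classifiers = c("svm", "rf"), k_grid = 3)
  list(ds = sim$dataset, truth = sim$truth, specs = specs)
}

test_that("run_grid evaluates every spec and reports identically across workers", {
  fx <- small_grid_fixture()
  plan <- bootstrap_plan(B = 8, master_seed = 17)
  r1 <- run_grid(fx$specs, fx$ds, plan, workers = 1)
  r2 <- run_grid(fx$specs, fx$ds, plan, workers = 2)
  expect_length(r1$results, length(fx$specs))
  expect_identical(r1$results, r2$results)
  expect_identical(r1$status, r2$status)
  expect_identical(grid_table(r1), grid_table(r2))
  expect_true(all(r1$status %in% c("ok", "truncated-k") |
                    startsWith(r1$status, "failed")))
})

test_that("one failing procedure never aborts the rest of the grid", {
  # a dataset where every gene has exactly equal class means is all-"down",
  # so an up-pattern procedure finds no genes and fails; the others finish
  mat <- matrix(rep(c(1, 2, 3, 4), 6), nrow = 6, byrow = TRUE)
  ds <- expression_dataset(mat, paste0("g", 1:6), paste0("s", 1:4),
                           c("A", "A", "B", "B"))
  specs <- list(procedure_spec("ttest", "up", k = 2, classifier = "svm"),
                procedure_spec("ttest", "down", k = 2, classifier = "svm"))
  plan <- bootstrap_plan(B = 4, master_seed = 5)
  rep <- run_grid(specs, ds, plan)
  expect_match(rep$status[1], "^failed: no genes in pattern group")
  expect_false(startsWith(rep$status[2], "failed"))
  expect_error(run_grid(list(), ds, plan), "empty procedure list")
})

test_that("rank_results keeps all ties at minimal error then minimal k", {
  fake_result <- function(err, k, method = "ttest") {
    structure(list(spec = procedure_spec(method, "total", k = k,
                                         classifier = "svm"),
                   err_bar = 0, err1 = err, gamma = 0.5, R = 0, w = 0.632,
                   err632plus = err, n_oob_excluded = 0L,
                   gene_ids = paste0("g", seq_len(k)), truncated = FALSE),
              class = "ProcedureResult")
  }
  report <- structure(list(
    results = list(fake_result(0.02, 10, "ttest"),
                   fake_result(0.02, 10, "wilcoxon"),
                   fake_result(0.02, 10, "infogain"),
                   fake_result(0.02, 20, "ttest"),
                   fake_result(0.05, 10, "ttest")),
    status = rep("ok", 5),
    dataset = list(), plan = list(), version = "0"),
    class = "GridReport")
  best <- rank_results(report)
  expect_length(best, 3)
  expect_true(all(vapply(best, function(r) r$err632plus, numeric(1)) == 0.02))
  expect_true(all(vapply(best, function(r) r$spec$k, integer(1)) == 10L))

  # single strict minimum -> singleton
  report$results[[2]]$err632plus <- 0.5
  report$results[[3]]$err632plus <- 0.5
  report$results[[4]]$err632plus <- 0.5
  expect_length(rank_results(report), 1)
})

test_that("write_report emits a consistent file set", {
  fx <- small_grid_fixture(seed = 2)
  plan <- bootstrap_plan(B = 6, master_seed = 23)
  report <- run_grid(fx$specs[1:6], fx$ds, plan)
  out <- withr::local_tempdir()
  paths <- write_report(report, out)
  expect_true(all(file.exists(paths)))

  grid <- read.delim(file.path(out, "grid.tsv"))
  best <- read.delim(file.path(out, "best.tsv"))
  expect_equal(nrow(grid), 6)
  expect_true(nrow(best) >= 1)
  # best rows are a subset of grid rows
  key <- function(d) paste(d$fs_method, d$pattern, d$k, d$discretize, d$fva,
                           d$classifier)
  expect_true(all(key(best) %in% key(grid)))
  # grid.tsv is sorted by error then k
  expect_true(!is.unsorted(grid$err632plus, na.rm = TRUE))

  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_length(js$procedures, 6)
  expect_equal(js$dataset$positive_class, "case")

  # re-running with the same seed reproduces everything but the timestamp
  out2 <- withr::local_tempdir()
  write_report(run_grid(fx$specs[1:6], fx$ds, plan), out2)
  expect_identical(readLines(file.path(out, "grid.tsv")),
                   readLines(file.path(out2, "grid.tsv")))
  expect_identical(readLines(file.path(out, "report.json")),
                   readLines(file.path(out2, "report.json")))
})
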