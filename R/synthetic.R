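#' Configure the synthetic two-class expression generator
#'
#' The generator emulates the input the workbench is built for: a
#' preprocessed genes x samples expression matrix with two sample classes
#' and a minority of informative genes whose class-conditional means
#' differ. Values are `base_level` plus Gaussian noise; informative-up
#' genes gain `+effect_size * noise_sd` in the positive class,
#' informative-down genes `-effect_size * noise_sd`. An optional fraction
#' of samples receive additive spikes on a random gene subset to mimic
#' outlier arrays.
#'
#' @param n_genes total gene count (default 2000, a typical filtered
#'   microarray panel).
#' @param n1,n2 samples in the positive / other class (default 30 + 30).
#' @param n_up,n_down number of informative up- / down-regulated genes
#'   (default 20 each; `n_up + n_down <= n_genes`).
#' @param effect_size class-mean shift in units of `noise_sd` (>= 0;
#'   default 2, a clearly-but-not-trivially separable signal; 0 gives a
#'   null dataset).
#' @param noise_sd within-class standard deviation (default 1).
#' @param base_level baseline expression (default 8, a log2-intensity
#'   scale).
#' @param outlier_fraction fraction of samples spiked (default 0).
#' @param outlier_magnitude spike size in units of `noise_sd` (default 5),
#'   applied to a random 10% of genes of each outlier sample.
#' @param seed integer seed; the same config is byte-reproducible.
#' @return object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 2000L, n1 = 30L, n2 = 30L,
                              n_up = 20L, n_down = 20L, effect_size = 2,
                              noise_sd = 1, base_level = 8,
                              outlier_fraction = 0, outlier_magnitude = 5,
                              seed = 1L) {
  stopifnot(n_genes >= 1L, n1 >= 2L, n2 >= 2L, n_up >= 0L, n_down >= 0L,
            n_up + n_down <= n_genes, effect_size >= 0, noise_sd > 0,
            outlier_fraction >= 0, outlier_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes), n1 = as.integer(n1),
                 n2 = as.integer(n2), n_up = as.integer(n_up),
                 n_down = as.integer(n_down), effect_size = effect_size,
                 noise_sd = noise_sd, base_level = base_level,
                 outlier_fraction = outlier_fraction,
                 outlier_magnitude = outlier_magnitude,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Generate a synthetic two-class dataset with known ground truth
#'
#' @param cfg a [simulation_config()].
#' @return list with `dataset` (an [expression_dataset()]; classes `case`
#'   and `control`, positive class `case`) and `truth` (data.frame of the
#'   informative gene ids and their planted directions).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  n <- cfg$n1 + cfg$n2
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  sample_ids <- c(sprintf("case_%02d", seq_len(cfg$n1)),
                  sprintf("ctrl_%02d", seq_len(cfg$n2)))
  labels <- c(rep("case", cfg$n1), rep("control", cfg$n2))

  mat <- matrix(stats::rnorm(cfg$n_genes * n, mean = cfg$base_level,
                             sd = cfg$noise_sd),
                nrow = cfg$n_genes)
  shift <- cfg$effect_size * cfg$noise_sd
  up_idx <- seq_len(cfg$n_up)
  down_idx <- seq.int(cfg$n_up + 1L, length.out = cfg$n_down)
  pos <- seq_len(cfg$n1)
  if (cfg$n_up > 0L) mat[up_idx, pos] <- mat[up_idx, pos] + shift
  if (cfg$n_down > 0L) mat[down_idx, pos] <- mat[down_idx, pos] - shift

  n_outliers <- round(cfg$outlier_fraction * n)
  if (n_outliers > 0L) {
    outlier_samples <- sample.int(n, n_outliers)
    n_spiked <- max(1L, round(0.1 * cfg$n_genes))
    for (s in outlier_samples) {
      spiked <- sample.int(cfg$n_genes, n_spiked)
      mat[spiked, s] <- mat[spiked, s] +
        cfg$outlier_magnitude * cfg$noise_sd * sample(c(-1, 1), 1L)
    }
  }

  truth <- data.frame(
    gene_id = gene_ids[c(up_idx, down_idx)],
    direction = c(rep("up", cfg$n_up), rep("down", cfg$n_down)),
    stringsAsFactors = FALSE)

  list(dataset = expression_dataset(mat, gene_ids, sample_ids, labels,
                                    positive_class = "case"),
       truth = truth)
}

#' Write a simulated dataset plus its ground-truth sidecar
#'
#' Writes the matrix in the tab-delimited dialect of [read_dataset()] as
#' `matrix.tsv` and the planted informative genes as `truth.tsv` next to
#' it, so downstream checks are self-describing.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir output directory (created if absent).
#' @return list with the generated `dataset`, `truth`, and the written
#'   `paths`.
#' @export
write_simulation <- function(cfg, out_dir) {
  sim <- generate_dataset(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  matrix_path <- file.path(out_dir, "matrix.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  write_dataset(sim$dataset, matrix_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(sim, list(paths = c(matrix = matrix_path, truth = truth_path)))
}
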