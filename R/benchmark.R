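#' Packaged benchmark deviation-statistics table
#'
#' Published per-model, per-cluster-size deviation statistics (Err, MSE,
#' MAE, in kcal/mol) of standard and dispersion-corrected DFT water-cluster
#' interaction energies against quantum Monte Carlo references, shipped as
#' plain TSV. Used as input for the statistics-layer worked examples: the
#' size-intensive headline metric is `mae_per_mol = mae / n_monomers`
#' (reported with 2-decimal display rounding).
#'
#' @param file Path to a stats TSV (defaults to the packaged table).
#' @return Data.frame with columns `model`, `variant`, `n_monomers`, `err`,
#'   `mse`, `mae`, plus the computed `mae_per_mol`.
#' @export
read_benchmark_stats <- function(file = benchmark_stats_file()) {
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("model", "variant", "n_monomers", "err", "mse", "mae")
  miss <- setdiff(need, names(df))
  if (length(miss))
    d4_abort(paste0("benchmark stats table missing column(s): ",
                    paste(miss, collapse = ", ")), "d4tune_format_error")
  df$mae_per_mol <- df$mae / df$n_monomers
  df
}

#' @rdname read_benchmark_stats
#' @export
benchmark_stats_file <- function() {
  system.file("extdata", "water_cluster_benchmark_stats.tsv",
              package = "d4tune", mustWork = TRUE)
}
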