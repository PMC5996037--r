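#' Pearson correlation between predicted and true fractions
#'
#' @param pred Numeric vector of predictions.
#' @param truth Numeric vector of ground truth, same length (>= 3).
#' @return The Pearson product-moment correlation, or \code{NA_real_} when
#'   either side has zero variance.
#' @export
pearson <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) < 3) stop("need >= 3 paired observations")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) return(NA_real_)
  stats::cor(pred, truth)
}

rmse <- function(pred, truth) sqrt(mean((pred - truth)^2))

#' Score deconvolution of pure (single-cell-type) samples
#'
#' A sample counts as identified when the unique argmax of its predicted
#' fraction vector matches its annotated cell type; ties count as not
#' identified. The self-proportion is the fraction assigned to the true
#' type.
#'
#' @param fractions A \code{celldecon_fractions} data.frame from
#'   [deconvolve()].
#' @param annotation data.frame (\code{sample_id}, \code{cell_type})
#'   covering every sample.
#' @return List with \code{identification_rate}, \code{median_self_proportion}
#'   and the per-sample table \code{detail}.
#' @export
evaluate_pure_samples <- function(fractions, annotation) {
  fm <- fraction_matrix(fractions)
  ann <- match_annotation(annotation, rownames(fm))
  unknown <- setdiff(ann$cell_type, colnames(fm))
  if (length(unknown) > 0) {
    stop("annotated cell type(s) absent from fractions: ",
         paste(unique(unknown), collapse = ", "))
  }
  hit <- logical(nrow(fm))
  self <- numeric(nrow(fm))
  for (i in seq_len(nrow(fm))) {
    row <- fm[i, ]
    top <- which(row == max(row))
    hit[i] <- length(top) == 1 && colnames(fm)[top] == ann$cell_type[i]
    self[i] <- row[ann$cell_type[i]]
  }
  list(identification_rate = mean(hit),
       median_self_proportion = stats::median(self),
       detail = data.frame(sample_id = rownames(fm),
                           cell_type = ann$cell_type,
                           identified = hit, self_proportion = self,
                           stringsAsFactors = FALSE))
}

#' Benchmark deconvolution solvers on a simulated dataset
#'
#' Builds a signature matrix from the simulated pure-cell counts,
#' deconvolutes every mixture with every requested method, and aggregates
#' accuracy per (method, tumor fraction): the pooled Pearson correlation and
#' RMSE over all (sample, cell type) pairs at that tumor fraction, plus
#' per-cell-type correlations. Per-sample solver failures are recorded and
#' skipped in the aggregation.
#'
#' @param sim Output of [simulate_benchmark()] (or [read_benchmark()]).
#' @param methods Character vector of solver names.
#' @param sig_config A [signature_config()] used for the signature build.
#' @param seed Seed forwarded to the solver specs.
#' @return List of class \code{celldecon_benchmark}: \code{report} (long
#'   data.frame: method, tumor_fraction, pcc, rmse, n_pairs),
#'   \code{per_cell_type} (method, tumor_fraction, cell_type, pcc),
#'   \code{signature} and the per-method fraction tables in
#'   \code{fractions}.
#' @export
benchmark_solvers <- function(sim,
                              methods = c("llsr", "qp", "ridge", "lasso",
                                          "elastic_net", "nu_svr"),
                              sig_config = signature_config(),
                              seed = 1L) {
  bad <- setdiff(methods, SOLVER_METHODS)
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  sig <- build_signature(sim$pure_counts, sim$annotation, sig_config)
  types <- colnames(sig$signature)
  truth_mat <- as.matrix(sim$truth[, types, drop = FALSE])
  rownames(truth_mat) <- sim$truth$sample_id

  report <- list(); per_ct <- list(); fracs <- list()
  for (method in methods) {
    # simulated mixtures are generated directly on the training CPM scale,
    # so no mapping onto the reference distribution is needed
    ft <- deconvolve(sim$mixtures, sig, solver_spec(method, seed = seed),
                     normalize = "none")
    fracs[[method]] <- ft
    fm <- fraction_matrix(ft)
    ok <- stats::complete.cases(fm)
    for (tf in sort(unique(sim$truth$tumor_fraction))) {
      rows <- sim$truth$tumor_fraction == tf & ok
      pred <- as.vector(fm[rows, , drop = FALSE])
      tru <- as.vector(truth_mat[rows, , drop = FALSE])
      report[[length(report) + 1L]] <- data.frame(
        method = method, tumor_fraction = tf,
        pcc = pearson(pred, tru), rmse = rmse(pred, tru),
        n_pairs = length(pred), stringsAsFactors = FALSE)
      for (ct in types) {
        per_ct[[length(per_ct) + 1L]] <- data.frame(
          method = method, tumor_fraction = tf, cell_type = ct,
          pcc = pearson(fm[rows, ct], truth_mat[rows, ct]),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(report = do.call(rbind, report),
                 per_cell_type = do.call(rbind, per_ct),
                 signature = sig, fractions = fracs),
            class = "celldecon_benchmark")
}

#' Plot benchmark accuracy against tumor content
#'
#' One line per method: pooled Pearson correlation between predicted and
#' true fractions as tumor content rises.
#'
#' @param benchmark A \code{celldecon_benchmark} from [benchmark_solvers()],
#'   or its \code{report} data.frame.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(benchmark) {
  report <- if (inherits(benchmark, "celldecon_benchmark")) benchmark$report else benchmark
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$tumor_fraction, y = .data$pcc,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "tumor content (fraction of mixture)",
                  y = "Pearson r (predicted vs true fractions)",
                  colour = "method") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @export
print.celldecon_benchmark <- function(x, ...) {
  cat("celldecon benchmark:", length(unique(x$report$method)), "methods x",
      length(unique(x$report$tumor_fraction)), "tumor fractions\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
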