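#' Configuration for signature matrix construction
#'
#' Thresholds follow the marker-selection rules used throughout: a gene is a
#' candidate marker for a cell type when its one-vs-rest adjusted P value is
#' below \code{adj_p_threshold} and its log2 fold change exceeds
#' \code{lfc_threshold} (both strict); genes whose maximum raw count across
#' all pure-cell samples falls below \code{min_max_count} are dropped; the
#' surviving genes are ranked by decreasing fold change and the \code{top_k}
#' per cell type enter the signature.
#'
#' @param adj_p_threshold Adjusted-P cutoff (strict \code{<}), default 0.05.
#' @param lfc_threshold log2 fold-change cutoff (strict \code{>}), default 2.
#' @param min_max_count Minimum of the per-gene maximum raw count, default 100.
#' @param top_k Markers retained per cell type, default 20.
#' @param tissue_filter_profiles Optional expression matrix of
#'   non-hematopoietic/tumor profiles (genes x profiles); markers highly
#'   expressed there are removed.
#' @param tissue_filter_quantile Per-profile expression quantile above which
#'   a gene counts as highly expressed, default 0.95.
#' @param lowess_span Span of the lowess mean-variance trend in the voom
#'   transform, default 0.5.
#' @return A list of class \code{signature_config}.
#' @export
signature_config <- function(adj_p_threshold = 0.05,
                             lfc_threshold = 2,
                             min_max_count = 100L,
                             top_k = 20L,
                             tissue_filter_profiles = NULL,
                             tissue_filter_quantile = 0.95,
                             lowess_span = 0.5) {
  stopifnot(adj_p_threshold > 0, lfc_threshold > 0,
            min_max_count >= 0, top_k >= 1)
  structure(list(adj_p_threshold = adj_p_threshold,
                 lfc_threshold = lfc_threshold,
                 min_max_count = as.integer(min_max_count),
                 top_k = as.integer(top_k),
                 tissue_filter_profiles = tissue_filter_profiles,
                 tissue_filter_quantile = tissue_filter_quantile,
                 lowess_span = lowess_span),
            class = "signature_config")
}

#' voom transform: log2-CPM with precision weights
#'
#' Converts counts to log2((count + 0.5) / (library size + 1) * 1e6) and
#' derives per-observation precision weights from a lowess trend of
#' sqrt(residual standard deviation) against mean log2 count, as implemented
#' in \pkg{limma}. When an annotation is supplied the trend is fitted under
#' the group-means design, so group differences do not inflate the residual
#' variance.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @param annotation Optional annotation data.frame (\code{sample_id},
#'   \code{cell_type}); when NULL an intercept-only design is used.
#' @param span Lowess span for the trend, default 0.5.
#' @return List with \code{log_expr} (log2-CPM matrix), \code{weights}
#'   (positive matrix, genes x samples) and \code{design} (model matrix).
#' @export
voom_transform <- function(counts, annotation = NULL, span = 0.5) {
  if (ncol(counts) < 2) stop("voom needs >= 2 samples")
  if (any(colSums(counts) <= 0)) stop("all library sizes must be > 0")
  design <- voom_design(counts, annotation)
  if (ncol(counts) - ncol(design) < 1) {
    stop("fewer than 2 samples per fitted group: residual variance undefined")
  }
  v <- limma::voom(counts, design = design, span = span)
  if (any(!is.finite(v$weights)) || any(v$weights <= 0)) {
    stop("voom produced non-finite or non-positive weights")
  }
  list(log_expr = v$E, weights = v$weights, design = design)
}

voom_design <- function(counts, annotation) {
  if (is.null(annotation)) {
    return(matrix(1, ncol(counts), 1, dimnames = list(colnames(counts), "Intercept")))
  }
  ann <- match_annotation(annotation, colnames(counts))
  group <- factor(ann$cell_type)
  if (nlevels(group) < 2) stop("annotation must contain >= 2 distinct cell types")
  design <- stats::model.matrix(~ 0 + group)
  colnames(design) <- levels(group)
  rownames(design) <- colnames(counts)
  design
}

match_annotation <- function(annotation, sample_ids) {
  idx <- match(sample_ids, annotation$sample_id)
  if (any(is.na(idx))) {
    stop("samples without annotation: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  annotation[idx, , drop = FALSE]
}

#' One-vs-rest moderated differential expression for one cell type
#'
#' Fits, per gene, a weighted least-squares regression of log expression on
#' the target-vs-rest indicator, moderates the residual variances by
#' empirical-Bayes shrinkage toward a common prior, and reports two-sided P
#' values from the t distribution with moderated degrees of freedom,
#' BH-adjusted across genes.
#'
#' @param log_expr log2 expression matrix, genes x samples.
#' @param weights Positive precision weights, same shape (or NULL for
#'   unweighted).
#' @param annotation Annotation data.frame covering every sample.
#' @param target Cell-type label to contrast against all the rest.
#' @return data.frame with columns \code{gene_id}, \code{cell_type},
#'   \code{log2_fc}, \code{t_mod}, \code{p_value}, \code{adj_p_value}.
#' @export
moderated_de_test <- function(log_expr, weights, annotation, target) {
  ann <- match_annotation(annotation, colnames(log_expr))
  is_target <- ann$cell_type == target
  if (sum(is_target) < 2) stop("target '", target, "' has fewer than 2 samples")
  if (sum(!is_target) < 2) stop("rest group has fewer than 2 samples")
  design <- cbind(Intercept = 1, target = as.numeric(is_target))
  fit <- limma::lmFit(log_expr, design = design, weights = weights)
  fit <- limma::eBayes(fit)
  tab <- limma::topTable(fit, coef = "target", number = Inf, sort.by = "none")
  data.frame(gene_id = rownames(log_expr),
             cell_type = target,
             log2_fc = tab$logFC,
             t_mod = tab$t,
             p_value = tab$P.Value,
             adj_p_value = tab$adj.P.Val,
             stringsAsFactors = FALSE)
}

#' Keep significantly upregulated marker candidates
#'
#' @param de data.frame from [moderated_de_test()].
#' @param config A [signature_config()].
#' @return The rows of \code{de} with \code{adj_p_value <} the threshold and
#'   \code{log2_fc >} the threshold (upregulated in the target only).
#' @export
filter_significant <- function(de, config = signature_config()) {
  if (nrow(de) == 0) stop("empty DE result")
  keep <- de$adj_p_value < config$adj_p_threshold &
    de$log2_fc > config$lfc_threshold
  de[keep, , drop = FALSE]
}

#' Remove genes highly expressed in non-immune tissue or tumor profiles
#'
#' A gene is removed when its expression in any supplied profile exceeds
#' that profile's expression quantile. With no profiles the gene set passes
#' through unchanged.
#'
#' @param genes Character vector of candidate gene IDs.
#' @param tissue_profiles Expression matrix, genes x profiles, or NULL.
#' @param quantile Per-profile quantile in (0, 1), default 0.95.
#' @return The surviving gene IDs.
#' @export
filter_tissue_expressed <- function(genes, tissue_profiles = NULL, quantile = 0.95) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  if (is.null(tissue_profiles) || ncol(tissue_profiles) == 0) return(genes)
  high <- rep(FALSE, length(genes))
  for (j in seq_len(ncol(tissue_profiles))) {
    prof <- tissue_profiles[, j]
    cutoff <- stats::quantile(prof, probs = quantile, names = FALSE)
    idx <- match(genes, rownames(tissue_profiles))
    high <- high | (!is.na(idx) & prof[idx] > cutoff)
  }
  genes[!high]
}

#' Drop genes never expressed above a raw-count floor
#'
#' Keeps genes whose maximum raw count across all pure-cell samples is at
#' least \code{min_max_count}.
#'
#' @param genes Candidate gene IDs (must exist in \code{counts}).
#' @param counts Raw counts matrix, genes x samples.
#' @param min_max_count Integer floor, default 100.
#' @return The surviving gene IDs.
#' @export
filter_low_count <- function(genes, counts, min_max_count = 100L) {
  stopifnot(all(genes %in% rownames(counts)))
  maxima <- apply(counts[genes, , drop = FALSE], 1, max)
  genes[maxima >= min_max_count]
}

#' Select the top-k markers per cell type by fold change
#'
#' Within each cell type genes are ordered by decreasing log2 fold change,
#' ties broken by smaller adjusted P and then lexicographic gene ID, and the
#' first \code{top_k} taken. The union over cell types forms the signature
#' gene list; a gene selected for several types is kept once and attributed
#' to the type where its fold change is largest.
#'
#' @param de_by_type Named list (one element per cell type) of filtered DE
#'   data.frames.
#' @param top_k Markers per type, default 20.
#' @return data.frame with columns \code{gene_id}, \code{cell_type} (the
#'   attributed source type), \code{log2_fc}, \code{adj_p_value}.
#' @export
select_top_k <- function(de_by_type, top_k = 20L) {
  picks <- lapply(names(de_by_type), function(ct) {
    de <- de_by_type[[ct]]
    if (is.null(de) || nrow(de) == 0) {
      stop("cell type '", ct, "' has no surviving marker genes")
    }
    if (nrow(de) < top_k) {
      warning("cell type '", ct, "' has only ", nrow(de),
              " surviving genes (top_k = ", top_k, ")")
    }
    ord <- order(-de$log2_fc, de$adj_p_value, de$gene_id)
    de[ord[seq_len(min(top_k, nrow(de)))], , drop = FALSE]
  })
  all <- do.call(rbind, picks)
  # resolve overlaps: keep the occurrence with the largest fold change
  ord <- order(all$gene_id, -all$log2_fc, all$adj_p_value)
  all <- all[ord, , drop = FALSE]
  all <- all[!duplicated(all$gene_id), , drop = FALSE]
  rownames(all) <- NULL
  all[, c("gene_id", "cell_type", "log2_fc", "adj_p_value")]
}

#' Build a signature gene matrix from labeled pure-cell counts
#'
#' Runs the full construction pipeline: voom transform, one-vs-rest
#' moderated DE per cell type, the significance / tissue-expression /
#' low-count filters, and top-k fold-change ranking. Signature entries are
#' the mean quantile-normalized linear (CPM-scale) expression of each
#' signature gene across the pure samples of each cell type, and the
#' training reference distribution is stored alongside so new mixtures can
#' be normalized onto the training scale.
#'
#' @param counts Raw counts, genes x pure-cell samples.
#' @param annotation data.frame (\code{sample_id}, \code{cell_type})
#'   covering every sample, >= 2 cell types.
#' @param config A [signature_config()].
#' @return List of class \code{celldecon_signature} with elements
#'   \code{signature} (genes x cell types), \code{reference} (sorted
#'   training quantiles), \code{genes} (marker attribution table),
#'   \code{de} (per-type DE tables) and \code{metadata}.
#' @export
build_signature <- function(counts, annotation, config = signature_config()) {
  ann <- match_annotation(annotation, colnames(counts))
  types <- sort(unique(ann$cell_type))
  if (length(types) < 2) stop("need >= 2 cell types to build a signature")

  v <- voom_transform(counts, annotation, span = config$lowess_span)
  de_all <- lapply(types, function(ct) {
    moderated_de_test(v$log_expr, v$weights, annotation, ct)
  })
  names(de_all) <- types

  de_filtered <- lapply(types, function(ct) {
    de <- filter_significant(de_all[[ct]], config)
    keep <- filter_tissue_expressed(de$gene_id, config$tissue_filter_profiles,
                                    config$tissue_filter_quantile)
    keep <- filter_low_count(keep, counts, config$min_max_count)
    de[de$gene_id %in% keep, , drop = FALSE]
  })
  names(de_filtered) <- types

  markers <- select_top_k(de_filtered, config$top_k)

  expr <- cpm_normalize(counts)
  reference <- rowMeans(apply(expr, 2, sort))
  expr_qn <- quantile_normalize(expr, reference)
  sig <- matrix(0, nrow(markers), length(types),
                dimnames = list(markers$gene_id, types))
  for (ct in types) {
    cols <- ann$sample_id[ann$cell_type == ct]
    sig[, ct] <- rowMeans(expr_qn[markers$gene_id, cols, drop = FALSE])
  }

  structure(list(
    signature = sig,
    reference = reference,
    genes = markers,
    de = de_all,
    metadata = list(
      adj_p_threshold = config$adj_p_threshold,
      lfc_threshold = config$lfc_threshold,
      min_max_count = config$min_max_count,
      top_k = config$top_k,
      tissue_filter_quantile = config$tissue_filter_quantile,
      lowess_span = config$lowess_span,
      n_cell_types = length(types),
      n_signature_genes = nrow(sig))),
    class = "celldecon_signature")
}

#' @export
print.celldecon_signature <- function(x, ...) {
  cat("celldecon signature matrix:", nrow(x$signature), "genes x",
      ncol(x$signature), "cell types\n")
  cat("cell types:", paste(colnames(x$signature), collapse = ", "), "\n")
  invisible(x)
}
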