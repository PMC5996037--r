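#' Read an expression or counts matrix from TSV/CSV
#'
#' Parses a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Genes are rows, samples are
#' columns throughout the package.
#'
#' @param path Path to a TSV (default) or CSV file. Files ending in
#'   \code{.csv} are read comma-separated, anything else tab-separated.
#' @param kind Either \code{"counts"} (values must be nonnegative integers)
#'   or \code{"expression"} (nonnegative reals).
#' @return A numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @export
read_matrix <- function(path, kind = c("expression", "counts")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("input file not found: ", path)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a gene column plus >= 1 sample column: ", path)
  gene_ids <- trimws(df[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0) {
    stop("duplicate gene IDs in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in header of ", path)
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !is.na(col))
    if (length(bad) > 0) {
      stop("malformed numeric value '", col[bad[1]], "' at gene '",
           gene_ids[bad[1]], "', sample '", sample_ids[j], "' in ", path)
    }
    vals[, j] <- x
  }
  validate_matrix(vals, kind)
  vals
}

#' Write a matrix in the package's TSV format
#'
#' First column header is \code{gene}; remaining headers are sample IDs.
#'
#' @param mat Numeric matrix, genes x samples, with dimnames.
#' @param path Output path (\code{.csv} writes comma-separated).
#' @return Invisibly, \code{path}.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_matrix <- function(vals, kind) {
  if (any(!is.finite(vals))) stop("matrix contains non-finite values")
  if (any(vals < 0)) stop("matrix contains negative values")
  if (kind == "counts" && any(vals != round(vals))) {
    stop("counts matrix contains non-integral values")
  }
  invisible(vals)
}

#' Read a sample annotation table
#'
#' @param path TSV/CSV with columns \code{sample_id} and \code{cell_type}.
#' @param matrix_samples Optional character vector of sample IDs the
#'   annotation must be contained in.
#' @return A data.frame with character columns \code{sample_id},
#'   \code{cell_type}.
#' @export
read_annotation <- function(path, matrix_samples = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("sample_id", "cell_type") %in% colnames(df))) {
    stop("annotation needs columns sample_id and cell_type: ", path)
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  df$cell_type <- trimws(as.character(df$cell_type))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in annotation")
  if (!is.null(matrix_samples)) {
    missing <- setdiff(df$sample_id, matrix_samples)
    if (length(missing) > 0) {
      stop("annotated samples absent from matrix: ", paste(missing, collapse = ", "))
    }
  }
  df[, c("sample_id", "cell_type")]
}

#' Counts-per-million normalization
#'
#' Scales every column so it sums to one million.
#'
#' @param counts Nonnegative matrix, genes x samples.
#' @return Matrix of CPM values with the same dimnames.
#' @export
cpm_normalize <- function(counts) {
  totals <- colSums(counts)
  zero <- which(totals <= 0)
  if (length(zero) > 0) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Quantile normalization onto a common reference distribution
#'
#' Each column's values are replaced by the reference quantiles at their
#' within-column ranks, so every normalized column has the same sorted value
#' vector. Ties receive the mean of the reference values at the tied ranks.
#' The default reference is the row-wise mean of the sorted columns of
#' \code{mat} itself; passing a stored reference maps new samples onto a
#' training scale.
#'
#' @param mat Numeric matrix, genes x samples, >= 1 column.
#' @param reference Optional numeric vector of sorted reference quantiles,
#'   length \code{nrow(mat)}.
#' @return Normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(mat, reference = NULL) {
  if (!is.matrix(mat) || ncol(mat) < 1) stop("mat must be a matrix with >= 1 column")
  n <- nrow(mat)
  if (is.null(reference)) {
    reference <- rowMeans(apply(mat, 2, sort))
  } else {
    if (length(reference) != n) {
      stop("reference length ", length(reference), " does not match gene count ", n)
    }
    if (is.unsorted(reference)) reference <- sort(reference)
  }
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    out[, j] <- (reference[floor(r)] + reference[ceiling(r)]) / 2
  }
  out
}

#' Restrict a mixture matrix and signature matrix to their shared genes
#'
#' @param mixture Expression matrix, genes x samples.
#' @param signature Signature matrix, genes x cell types.
#' @return A list with elements \code{mixture} and \code{signature} (both
#'   restricted to the gene intersection, identically ordered),
#'   \code{n_dropped} (signature genes absent from the mixture) and
#'   \code{low_coverage} (TRUE when more than half the signature genes were
#'   dropped).
#' @export
align_genes <- function(mixture, signature) {
  shared <- intersect(rownames(signature), rownames(mixture))
  if (length(shared) == 0) {
    stop("no genes shared between mixture and signature")
  }
  n_dropped <- nrow(signature) - length(shared)
  low <- n_dropped > nrow(signature) / 2
  if (low) {
    warning("more than 50% of signature genes missing from the mixture (",
            n_dropped, "/", nrow(signature), ")")
  }
  list(mixture = mixture[shared, , drop = FALSE],
       signature = signature[shared, , drop = FALSE],
       n_dropped = n_dropped,
       low_coverage = low)
}

#' Write a signature bundle directory
#'
#' A bundle holds \code{signature.tsv} (genes x cell types),
#' \code{reference_distribution.tsv} (sorted training quantiles used to map
#' new samples onto the training scale) and \code{metadata.yaml} (thresholds
#' and provenance).
#'
#' @param sig A signature object as returned by [build_signature()], or a
#'   list with elements \code{signature}, \code{reference}, \code{metadata}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_signature_bundle <- function(sig, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sig$signature, file.path(dir, "signature.tsv"))
  utils::write.table(
    data.frame(reference = sig$reference),
    file.path(dir, "reference_distribution.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- sig$metadata
  if (is.null(meta)) meta <- list()
  meta$package <- "celldecon"
  meta$version <- as.character(utils::packageVersion("celldecon"))
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a signature bundle directory
#'
#' @param dir Bundle directory written by [write_signature_bundle()].
#' @return List with \code{signature} (matrix), \code{reference} (sorted
#'   numeric vector) and \code{metadata} (list).
#' @export
read_signature_bundle <- function(dir) {
  sig_path <- file.path(dir, "signature.tsv")
  ref_path <- file.path(dir, "reference_distribution.tsv")
  if (!file.exists(sig_path)) stop("not a signature bundle (no signature.tsv): ", dir)
  signature <- read_matrix(sig_path, "expression")
  reference <- NULL
  if (file.exists(ref_path)) {
    reference <- utils::read.table(ref_path, header = TRUE, sep = "\t")$reference
  }
  meta_path <- file.path(dir, "metadata.yaml")
  metadata <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  list(signature = signature, reference = reference, metadata = metadata)
}
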