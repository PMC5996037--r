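#' Configuration for the synthetic mixture benchmark
#'
#' Defaults emulate a 10-immune-cell reference panel: 1000 genes, 20 planted
#' marker genes per type shifted up by 4 log2 units, 4 replicate pure
#' samples per type drawn negative-binomial, multiplicative log-normal
#' mixture noise (sd 0.1 on log2 scale) and a tumor spike-in grid reaching
#' 99.9% tumor content.
#'
#' @param n_cell_types Number of cell types, default 10.
#' @param n_genes Number of genes, default 1000.
#' @param markers_per_type Planted markers per type, default 20.
#' @param marker_log2fc Planted marker shift on log2 scale, default 4.
#' @param replicates_per_type Pure-cell replicates per type, default 4.
#' @param noise_sd_log2 SD of multiplicative log-normal mixture noise on the
#'   log2 scale, default 0.1.
#' @param tumor_fractions Tumor spike-in fractions in [0, 1].
#' @param n_mixtures Number of distinct mixing-fraction vectors, default 20.
#' @param nb_dispersion Negative-binomial dispersion of pure-cell counts
#'   (variance = mu + dispersion * mu^2), default 0.1.
#' @param tumor_marker_fraction Fraction of immune marker genes the synthetic
#'   tumor also expresses at the elevated level, emulating signature
#'   contamination by a real cell line, default 0.05.
#' @param seed Integer master seed; all randomness derives from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_cell_types = 10L,
                       n_genes = 1000L,
                       markers_per_type = 20L,
                       marker_log2fc = 4,
                       replicates_per_type = 4L,
                       noise_sd_log2 = 0.1,
                       tumor_fractions = c(0, 0.001, 0.25, 0.5, 0.9,
                                           0.95, 0.99, 0.999),
                       n_mixtures = 20L,
                       nb_dispersion = 0.1,
                       tumor_marker_fraction = 0.05,
                       seed = 1L) {
  stopifnot(n_cell_types >= 2, n_genes >= 1, markers_per_type >= 1,
            replicates_per_type >= 1, n_mixtures >= 1,
            all(tumor_fractions >= 0 & tumor_fractions <= 1))
  if (n_genes < n_cell_types * markers_per_type) {
    stop("infeasible config: n_genes < n_cell_types * markers_per_type ",
         "(planted markers must be disjoint)")
  }
  structure(list(n_cell_types = as.integer(n_cell_types),
                 n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 marker_log2fc = marker_log2fc,
                 replicates_per_type = as.integer(replicates_per_type),
                 noise_sd_log2 = noise_sd_log2,
                 tumor_fractions = tumor_fractions,
                 n_mixtures = as.integer(n_mixtures),
                 nb_dispersion = nb_dispersion,
                 tumor_marker_fraction = tumor_marker_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

IMMUNE_TYPES <- c("B_cell", "CD4_T", "CD8_T", "Macrophage", "Monocyte",
                  "Neutrophil", "Mast_cell", "Eosinophil", "Dendritic_cell",
                  "NK_cell")

sim_cell_types <- function(n) {
  if (n <= length(IMMUNE_TYPES)) IMMUNE_TYPES[seq_len(n)]
  else c(IMMUNE_TYPES, sprintf("cell_type_%02d", seq_len(n - length(IMMUNE_TYPES))))
}

sim_gene_ids <- function(n) sprintf("gene_%04d", seq_len(n))

#' Generate labeled pure-cell count profiles with planted markers
#'
#' Baseline per-gene means are drawn log-normal and shared across cell
#' types; each type's planted markers (disjoint blocks across types) are
#' shifted up by \code{marker_log2fc} log2 units; replicate counts are drawn
#' negative-binomial around the type mean. Fully reproducible from the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List with \code{counts} (genes x samples), \code{annotation}
#'   (sample_id, cell_type), \code{markers} (named list of planted marker
#'   IDs per type), \code{mean_expr} (true per-type mean matrix, genes x
#'   types, linear scale).
#' @export
synth_pure_profiles <- function(config = sim_config()) {
  genes <- sim_gene_ids(config$n_genes)
  types <- sim_cell_types(config$n_cell_types)

  withr::with_seed(config$seed, {
    base_mean <- stats::rlnorm(config$n_genes, meanlog = log(100), sdlog = 1.2)
    mean_expr <- matrix(base_mean, config$n_genes, config$n_cell_types,
                        dimnames = list(genes, types))
    markers <- list()
    for (i in seq_along(types)) {
      idx <- ((i - 1) * config$markers_per_type + 1):(i * config$markers_per_type)
      markers[[types[i]]] <- genes[idx]
      mean_expr[idx, i] <- mean_expr[idx, i] * 2^config$marker_log2fc
    }
    n_samples <- config$n_cell_types * config$replicates_per_type
    sample_ids <- as.vector(t(outer(types, seq_len(config$replicates_per_type),
                                    function(t, r) paste0(t, "_rep", r))))
    counts <- matrix(0L, config$n_genes, n_samples,
                     dimnames = list(genes, sample_ids))
    size <- 1 / config$nb_dispersion
    col <- 0L
    for (i in seq_along(types)) {
      for (r in seq_len(config$replicates_per_type)) {
        col <- col + 1L
        counts[, col] <- stats::rnbinom(config$n_genes, mu = mean_expr[, i],
                                        size = size)
      }
    }
  })
  annotation <- data.frame(
    sample_id = colnames(counts),
    cell_type = rep(types, each = config$replicates_per_type),
    stringsAsFactors = FALSE)
  list(counts = counts, annotation = annotation, markers = markers,
       mean_expr = mean_expr)
}

#' Draw ground-truth mixing fractions on the simplex
#'
#' Symmetric Dirichlet(alpha = 1) draws, i.e. uniform on the simplex.
#'
#' @param n_mixtures Number of fraction vectors.
#' @param n_cell_types Simplex dimension.
#' @param seed Integer seed.
#' @return Matrix, n_mixtures x n_cell_types; rows sum to 1.
#' @export
sample_fractions <- function(n_mixtures, n_cell_types, seed = 1L) {
  stopifnot(n_mixtures >= 1, n_cell_types >= 2)
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(n_mixtures * n_cell_types, shape = 1),
                n_mixtures, n_cell_types)
  })
  f <- g / rowSums(g)
  colnames(f) <- sim_cell_types(n_cell_types)
  rownames(f) <- sprintf("mix_%03d", seq_len(n_mixtures))
  f
}

#' Mix pure expression profiles at given fractions
#'
#' Computes \eqn{m = \sum_c f_c \cdot \mathrm{profile}_c} on the linear
#' expression scale, then applies multiplicative log-normal noise with the
#' given SD on the log2 scale (sd 0 gives the exact linear combination).
#' Noise is drawn from the current RNG state; seed externally for
#' reproducibility.
#'
#' @param pure_means Expression matrix, genes x cell types (linear scale).
#' @param fractions Fraction vector on the simplex, one entry per cell type.
#' @param noise_sd_log2 Noise SD on the log2 scale, default 0.
#' @return Named expression vector over genes.
#' @export
make_mixture <- function(pure_means, fractions, noise_sd_log2 = 0) {
  stopifnot(length(fractions) == ncol(pure_means))
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    stop("fractions must be nonnegative and sum to 1")
  }
  m <- drop(pure_means %*% fractions)
  if (noise_sd_log2 > 0) {
    m <- m * 2^stats::rnorm(length(m), mean = 0, sd = noise_sd_log2)
  }
  stats::setNames(m, rownames(pure_means))
}

#' Blend an immune mixture with a tumor profile
#'
#' @param m Immune mixture expression vector.
#' @param tumor_profile Tumor expression vector, gene-aligned with \code{m}.
#' @param tumor_fraction Tumor content c in [0, 1]; the result is
#'   \eqn{(1-c) m + c \cdot \mathrm{tumor}}.
#' @return Expression vector.
#' @export
spike_tumor <- function(m, tumor_profile, tumor_fraction) {
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    stop("tumor_fraction must lie in [0, 1]")
  }
  stopifnot(length(m) == length(tumor_profile))
  (1 - tumor_fraction) * m + tumor_fraction * tumor_profile
}

#' Generate a synthetic tumor expression profile
#'
#' An independent log-normal profile over the same gene space with its own
#' high-expressed gene set. Immune marker genes are silenced to a leaky
#' floor (1% of their baseline draw), as a tumor cell line does not express
#' lineage-restricted immune genes, except for a configurable fraction of
#' markers the tumor does express at its ordinary baseline level (signature
#' contamination). Scaled to the same total as a CPM profile.
#'
#' @param config A [sim_config()].
#' @param markers Named list of planted marker genes (from
#'   [synth_pure_profiles()]).
#' @return Named expression vector over genes.
#' @export
synth_tumor_profile <- function(config, markers) {
  genes <- sim_gene_ids(config$n_genes)
  all_markers <- unlist(markers, use.names = FALSE)
  withr::with_seed(config$seed + 2L, {
    prof <- stats::rlnorm(config$n_genes, meanlog = log(100), sdlog = 1.2)
    names(prof) <- genes
    high <- sample(setdiff(genes, all_markers), 50)
    prof[high] <- prof[high] * 2^config$marker_log2fc
    n_contam <- floor(config$tumor_marker_fraction * length(all_markers))
    contam <- if (n_contam > 0) sample(all_markers, n_contam) else character(0)
    silent <- setdiff(all_markers, contam)
    prof[silent] <- prof[silent] * 0.01  # leaky floor: lineage genes are off
  })
  prof / sum(prof) * 1e6
}

#' Simulate the full deconvolution benchmark dataset
#'
#' Generates pure-cell counts with planted markers, draws mixing fractions,
#' builds the full factorial of mixtures x tumor spike-in fractions (noise
#' drawn independently per mixture column), and records the ground truth.
#' Mixing operates on CPM-scale mean expression, where deconvolution also
#' operates. Byte-identical outputs for identical configs.
#'
#' @param config A [sim_config()].
#' @return List with \code{mixtures} (genes x (n_mixtures x tumor
#'   fractions)), \code{truth} (data.frame: sample_id, mixture_id,
#'   tumor_fraction, noise_seed, one column per cell type),
#'   \code{pure_counts}, \code{annotation}, \code{markers},
#'   \code{mean_expr}, \code{tumor_profile} and \code{config}.
#' @export
simulate_benchmark <- function(config = sim_config()) {
  pure <- synth_pure_profiles(config)
  profiles <- sweep(pure$mean_expr, 2, colSums(pure$mean_expr), "/") * 1e6
  fractions <- sample_fractions(config$n_mixtures, config$n_cell_types,
                                seed = config$seed + 1L)
  tumor <- synth_tumor_profile(config, pure$markers)

  n_tf <- length(config$tumor_fractions)
  n_cols <- config$n_mixtures * n_tf
  mixtures <- matrix(0, config$n_genes, n_cols,
                     dimnames = list(rownames(profiles), NULL))
  truth <- vector("list", n_cols)
  col <- 0L
  for (i in seq_len(config$n_mixtures)) {
    for (j in seq_len(n_tf)) {
      col <- col + 1L
      tf <- config$tumor_fractions[j]
      noise_seed <- config$seed + 1000L + col
      m <- withr::with_seed(noise_seed,
        make_mixture(profiles, fractions[i, ], config$noise_sd_log2))
      mixtures[, col] <- spike_tumor(m, tumor, tf)
      truth[[col]] <- data.frame(
        sample_id = sprintf("mix_%03d_tf%g", i, tf),
        mixture_id = rownames(fractions)[i],
        tumor_fraction = tf,
        noise_seed = noise_seed,
        t(fractions[i, ]),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  colnames(mixtures) <- truth$sample_id
  list(mixtures = mixtures, truth = truth, pure_counts = pure$counts,
       annotation = pure$annotation, markers = pure$markers,
       mean_expr = pure$mean_expr, tumor_profile = tumor, config = config)
}

#' Write a simulated benchmark dataset to a directory
#'
#' Writes mixtures.tsv, truth.tsv, pure_counts.tsv, annotation.tsv and
#' tumor_profile.tsv in the package's TSV formats.
#'
#' @param sim Output of [simulate_benchmark()].
#' @param dir Output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_benchmark <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$mixtures, file.path(dir, "mixtures.tsv"))
  write_matrix(sim$pure_counts, file.path(dir, "pure_counts.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(sim$tumor_profile), tumor = sim$tumor_profile),
    file.path(dir, "tumor_profile.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read a simulated benchmark dataset from a directory
#'
#' @param dir Directory written by [write_benchmark()].
#' @return List with \code{mixtures}, \code{truth}, \code{pure_counts},
#'   \code{annotation}, \code{tumor_profile}.
#' @export
read_benchmark <- function(dir) {
  mixtures <- read_matrix(file.path(dir, "mixtures.tsv"), "expression")
  pure_counts <- read_matrix(file.path(dir, "pure_counts.tsv"), "counts")
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE)
  annotation <- read_annotation(file.path(dir, "annotation.tsv"))
  tp <- utils::read.table(file.path(dir, "tumor_profile.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  tumor_profile <- stats::setNames(tp$tumor, tp$gene)
  list(mixtures = mixtures, truth = truth, pure_counts = pure_counts,
       annotation = annotation, tumor_profile = tumor_profile)
}
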