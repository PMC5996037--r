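# helper: two-group counts toy with planted differences
two_group_counts <- function(seed = 2, n_genes = 200, per_group = 4) {
  withr::with_seed(seed, {
    mu <- rlnorm(n_genes, log(80), 1)
    counts <- matrix(rpois(n_genes * 2 * per_group, mu), n_genes, 2 * per_group,
                     dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                     sprintf("s%02d", seq_len(2 * per_group))))
  })
  ann <- data.frame(sample_id = colnames(counts),
                    cell_type = rep(c("A", "B"), each = per_group))
  list(counts = counts, annotation = ann)
}

test_that("voom transform reproduces the log2-CPM offset formula", {
  # one gene with zero count in a library of total 999,999:
  # log2((0 + 0.5) / (999999 + 1) * 1e6) = log2(0.5) = -1
  counts <- rbind(gz = c(0, 5), bulk = c(999999, 999995))
  colnames(counts) <- c("s1", "s2")
  v <- voom_transform(counts)
  expect_equal(unname(v$log_expr["gz", "s1"]), -1)
  expect_equal(unname(v$log_expr["bulk", "s1"]),
               log2((999999 + 0.5) / (999999 + 1) * 1e6))
})

test_that("voom weights increase with mean count and stay finite", {
  tg <- two_group_counts(seed = 4, n_genes = 200, per_group = 3)
  tg$counts[1, ] <- 50L  # constant gene: raw variance 0, weight via trend
  v <- voom_transform(tg$counts, tg$annotation)
  expect_true(all(is.finite(v$weights)) && all(v$weights > 0))
  mean_count <- rowMeans(tg$counts)
  mean_weight <- rowMeans(v$weights)
  expect_gt(cor(rank(mean_count), rank(mean_weight)), 0.8)
})

test_that("voom rejects degenerate inputs", {
  counts <- matrix(c(5, 5), 1, 2, dimnames = list("g", c("a", "b")))
  expect_error(voom_transform(counts[, 1, drop = FALSE]), ">= 2 samples")
  ann <- data.frame(sample_id = c("a", "b"), cell_type = c("A", "B"))
  expect_error(voom_transform(counts, ann), "residual variance")
})

test_that("a gene identical across groups gets log2FC 0 and p 1", {
  tg <- two_group_counts()
  v <- voom_transform(tg$counts, tg$annotation)
  E <- v$log_expr
  E[1, ] <- 5  # identical value in every sample
  de <- moderated_de_test(E, v$weights, tg$annotation, "A")
  expect_equal(de$log2_fc[1], 0)
  expect_equal(de$p_value[1], 1)
})

test_that("swapping the group labels negates log2FC and keeps p-values", {
  tg <- two_group_counts(seed = 9)
  v <- voom_transform(tg$counts, tg$annotation)
  de_a <- moderated_de_test(v$log_expr, v$weights, tg$annotation, "A")
  de_b <- moderated_de_test(v$log_expr, v$weights, tg$annotation, "B")
  expect_equal(de_a$log2_fc, -de_b$log2_fc, tolerance = 1e-12)
  expect_equal(de_a$p_value, de_b$p_value, tolerance = 1e-12)
})

test_that("moderated DE requires >= 2 samples on each side", {
  tg <- two_group_counts()
  v <- voom_transform(tg$counts, tg$annotation)
  ann_bad <- tg$annotation
  ann_bad$cell_type <- c("A", rep("B", 7))
  expect_error(moderated_de_test(v$log_expr, v$weights, ann_bad, "A"),
               "fewer than 2")
  ann_one <- tg$annotation
  ann_one$cell_type <- "A"
  expect_error(moderated_de_test(v$log_expr, v$weights, ann_one, "A"),
               "fewer than 2")
})

test_that("BH adjustment matches the hand-computed step-up values", {
  # p = (0.01, 0.02, 0.03, 0.04) over 4 genes -> all adjusted to 0.04
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(oracle_bh(p), rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  # monotone step function, capped at 1, >= raw p
  withr::with_seed(8, q <- runif(50))
  adj <- p.adjust(q, "BH")
  expect_true(all(adj >= q))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(q)]) >= -1e-15))
})

test_that("significance filter applies both strict thresholds", {
  de <- data.frame(gene_id = c("keep", "down", "edge_p", "edge_fc"),
                   cell_type = "A",
                   log2_fc = c(2.5, -3, 2.5, 2),
                   t_mod = 1, p_value = 0.01,
                   adj_p_value = c(0.04, 0.04, 0.05, 0.04))
  kept <- filter_significant(de, signature_config())
  expect_identical(kept$gene_id, "keep")
})

test_that("tissue-expression filter removes planted high-expressed genes", {
  genes <- sprintf("g%03d", 1:50)
  withr::with_seed(3, prof <- rlnorm(300, log(50), 1))
  names(prof) <- sprintf("g%03d", 1:300)
  planted <- c("g005", "g017", "g042")
  prof[planted] <- max(prof) * 2  # above any 0.95 quantile
  profiles <- matrix(prof, ncol = 1, dimnames = list(names(prof), "tumor"))
  kept <- filter_tissue_expressed(genes, profiles, 0.95)
  expect_length(kept, 47)
  expect_false(any(planted %in% kept))
  # no-op without profiles; quantile domain enforced
  expect_identical(filter_tissue_expressed(genes, NULL), genes)
  expect_error(filter_tissue_expressed(genes, profiles, 1.2), "quantile")
})

test_that("low-count filter keeps max>=100 and drops max<100", {
  counts <- rbind(lo = c(99, 10), hi = c(100, 0), zero = c(0, 0))
  colnames(counts) <- c("a", "b")
  expect_identical(filter_low_count(rownames(counts), counts, 100), "hi")
})

test_that("top-k selection ranks by fold change with stated tie rules", {
  # 30 genes with distinct fold changes: exactly the 20 largest survive
  de <- data.frame(gene_id = sprintf("g%02d", 1:30), cell_type = "A",
                   log2_fc = seq(5, by = -0.1, length.out = 30),
                   adj_p_value = 0.01)
  out <- select_top_k(list(A = de), top_k = 20)
  expect_identical(out$gene_id, sprintf("g%02d", 1:20))

  # tie at log2FC 3.0 broken by smaller adjusted p
  tie <- data.frame(gene_id = c("gA", "gB"), cell_type = "A",
                    log2_fc = c(3, 3), adj_p_value = c(0.01, 0.002))
  out2 <- select_top_k(list(A = tie), top_k = 1)
  expect_identical(out2$gene_id, "gB")

  # overlap across types: counted once, attributed to the larger fold change
  mk <- function(ct, ids, fc) data.frame(gene_id = ids, cell_type = ct,
                                         log2_fc = fc, adj_p_value = 0.01)
  types <- paste0("T", 1:10)
  disjoint <- lapply(seq_along(types), function(i)
    mk(types[i], sprintf("%s_g%02d", types[i], 1:20), seq(4, 3, length.out = 20)))
  names(disjoint) <- types
  expect_equal(nrow(select_top_k(disjoint, 20)), 200)

  overlapping <- disjoint
  shared <- sprintf("shared%02d", 1:5)
  overlapping$T1$gene_id[1:5] <- shared
  overlapping$T2$gene_id[1:5] <- shared
  overlapping$T2$log2_fc[1:5] <- 6  # T2 wins the attribution
  out3 <- select_top_k(overlapping, 20)
  expect_equal(nrow(out3), 195)
  expect_true(all(out3$cell_type[out3$gene_id %in% shared] == "T2"))

  expect_error(select_top_k(list(A = de, B = de[0, ]), 20), "'B'")
})

test_that("signature construction recovers planted markers on the fixture", {
  sim <- synth_pure_profiles(tiny_sim_config())
  sig <- build_signature(sim$counts, sim$annotation,
                         signature_config(top_k = 5))
  planted <- unlist(sim$markers, use.names = FALSE)
  recall <- mean(planted %in% rownames(sig$signature))
  expect_gte(recall, 0.95)

  # a gene selected for type c is strictly highest in column c
  for (i in seq_len(nrow(sig$genes))) {
    g <- sig$genes$gene_id[i]
    ct <- sig$genes$cell_type[i]
    row <- sig$signature[g, ]
    expect_true(all(row[ct] > row[setdiff(names(row), ct)]))
  }
})

test_that("signature construction is deterministic", {
  sim <- synth_pure_profiles(tiny_sim_config())
  cfg <- signature_config(top_k = 5)
  s1 <- build_signature(sim$counts, sim$annotation, cfg)
  s2 <- build_signature(sim$counts, sim$annotation, cfg)
  expect_identical(s1$signature, s2$signature)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$genes, s2$genes)
})

test_that("two indistinguishable cell types abort the build", {
  withr::with_seed(6, {
    counts <- matrix(rpois(100 * 6, 50), 100, 6,
                     dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  })
  ann <- data.frame(sample_id = colnames(counts),
                    cell_type = rep(c("A", "B"), each = 3))
  expect_error(build_signature(counts, ann), "no surviving marker genes")
})
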