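test_that("marker-positive classification is the exact nonzero-count rule", {
  counts <- matrix(c(0, 1, 3, 0,
                     2, 0, 0, 5), 2, 4, byrow = TRUE)
  m <- cell_matrix(counts, genes = c("PGAP3", "other"),
                   cells = paste0("c", 1:4))
  expect_equal(unname(classify_marker_positive(m, "PGAP3")),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_error(classify_marker_positive(m, "absent"), "not present")

  # all-zero gene: everyone negative
  m0 <- cell_matrix(matrix(0, 1, 3), genes = "G", cells = paste0("c", 1:3))
  expect_false(any(classify_marker_positive(m0, "G")))

  # random sparse matrix equals the dense comparison; flipping one zero to 1
  # flips exactly that cell
  set.seed(3)
  dense <- matrix(rpois(200, 0.5), 10, 20,
                  dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  mr <- cell_matrix(dense)
  expect_equal(unname(classify_marker_positive(mr, "g4")),
               unname(dense["g4", ] > 0))
  z <- which(dense["g4", ] == 0)[1]
  dense2 <- dense
  dense2["g4", z] <- 1
  got2 <- classify_marker_positive(cell_matrix(dense2), "g4")
  got1 <- classify_marker_positive(mr, "g4")
  expect_equal(which(got2 != got1), setNames(z, colnames(dense)[z]))
})

test_that("find_markers computes CP10K log2 fold changes and respects its filters", {
  # gene expressed only in positives at normalized mean 3 vs 0: log2fc = 2
  counts <- rbind(sig = c(3, 3, 3, 0, 0, 0),
                  ref = c(7, 7, 7, 10, 10, 10))
  m <- cell_matrix(counts, genes = c("sig", "ref"), cells = paste0("c", 1:6))
  part <- c(rep(TRUE, 3), rep(FALSE, 3))
  res <- find_markers(m, part, lfc_min = 0.5, fdr_max = 1)
  all_genes <- attr(res, "all_genes")
  # CP10K: sig = 3/10*1e4 = 3000 in positives, 0 in negatives
  expect_equal(all_genes$log2fc[all_genes$gene == "sig"], log2(3001 / 1))
  expect_true("sig" %in% res$gene)

  # a gene with identical normalized expression in both groups has log2fc 0
  # and is excluded (per-cell totals fixed at 20 so CP10K leaves it constant)
  counts2 <- rbind(flat = rep(5, 8),
                   up = c(5, 6, 5, 6, 0, 1, 0, 1),
                   rest = c(10, 9, 10, 9, 15, 14, 15, 14))
  m2 <- cell_matrix(counts2, genes = c("flat", "up", "rest"),
                    cells = paste0("c", 1:8))
  res2 <- find_markers(m2, rep(c(TRUE, FALSE), each = 4), fdr_max = 1)
  ag2 <- attr(res2, "all_genes")
  expect_equal(ag2$log2fc[ag2$gene == "flat"], 0)
  expect_false("flat" %in% res2$gene)

  # reported rows always satisfy the thresholds; BH fdr >= p and is monotone
  m3 <- simulate_counts(n_genes = 30, n_cells = 120, seed = 6)
  part3 <- classify_marker_positive(m3, "PGAP3")
  res3 <- find_markers(m3, part3)
  expect_true(all(abs(res3$log2fc) >= 0.5))
  expect_true(all(res3$fdr < 0.05))
  ag <- attr(res3, "all_genes")
  expect_true(all(ag$fdr >= ag$pval - 1e-15))
  ord <- order(ag$pval)
  expect_true(all(diff(ag$fdr[ord]) >= -1e-15))
  expect_error(find_markers(m3, rep(TRUE, 120)), "non-empty")
})

test_that("median dichotomization sends ties to the low group", {
  p1 <- median_dichotomize(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(as.character(p1), c("low", "low", "high", "high"))
  p2 <- median_dichotomize(c(1, 2, 2, 3))
  expect_equal(as.character(p2), c("low", "low", "low", "high"))
  expect_error(median_dichotomize(5), ">= 2")

  # permuting sample order yields the same partition by sample id
  set.seed(10)
  v <- setNames(rnorm(21), paste0("s", 1:21))
  perm <- sample(21)
  a <- median_dichotomize(v)
  b <- median_dichotomize(v[perm])
  expect_equal(a[names(b)], b)

  # size imbalance bounded by ties at the median
  ties <- sum(v == median(v))
  expect_lte(abs(sum(a == "low") - sum(a == "high")), max(ties, 1))
})

test_that("Mann-Whitney exact branch enumerates all arrangements", {
  r <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$method, "exact")
  expect_true(r$u %in% c(0, 9))
  expect_equal(r$pval, 0.1)  # 2 of 20 arrangements as extreme

  # identical groups: p = 1
  r2 <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r2$pval, 1)
  expect_error(compare_groups(1:3, c("a", "a", "a")), "two levels")
})

test_that("Mann-Whitney normal branch matches the tie-corrected oracle", {
  set.seed(21)
  for (i in 1:20) {
    x <- sample(1:8, 15, replace = TRUE)
    y <- sample(2:9, 12, replace = TRUE)
    got <- compare_groups(c(x, y), rep(c("x", "y"), c(15, 12)))
    expect_equal(got$method, "normal_approx")
    oracle <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(got$pval, oracle, tolerance = 1e-10)
  }
})

test_that("exact and normal branches agree closely at n1 = n2 = 8", {
  # the continuity-corrected normal approximation tracks the exact two-sided
  # tail to within 0.011 uniformly over the whole U range at n1 = n2 = 8 (the
  # worst case sits mid-range, where a plain approximation errs by 0.046)
  set.seed(33)
  for (i in 1:20) {
    v <- rnorm(16)
    part <- rep(c("a", "b"), each = 8)
    p_exact <- compare_groups(v, part, exact_max = 8)$pval
    p_norm <- compare_groups(v, part, exact_max = 0)$pval
    expect_lt(abs(p_exact - p_norm), 0.011)
  }
})

test_that("Spearman correlation is a midrank Pearson with t-approximate p", {
  x <- c(1, 4, 2, 8, 5, 7)
  expect_equal(spearman_corr(x, exp(x))$rho, 1)     # monotone transform
  expect_equal(spearman_corr(x, -x^3)$rho, -1)      # reversal
  expect_warning(r0 <- spearman_corr(x, rep(2, 6)), "constant")
  expect_true(is.na(r0$rho))

  set.seed(13)
  for (i in 1:10) {
    a <- sample(1:5, 12, replace = TRUE)  # ties guaranteed
    b <- sample(1:5, 12, replace = TRUE)
    if (length(unique(a)) == 1L || length(unique(b)) == 1L) next
    got <- spearman_corr(a, b)
    rho_hand <- cor(rank(a), rank(b))
    expect_equal(got$rho, rho_hand, tolerance = 1e-12)
    expect_gte(got$rho, -1)
    expect_lte(got$rho, 1)
    if (abs(rho_hand) < 1) {
      t_hand <- rho_hand * sqrt(10 / (1 - rho_hand^2))
      expect_equal(got$pval, 2 * pt(-abs(t_hand), 10), tolerance = 1e-12)
    }
    # invariance under strictly monotone transforms
    expect_equal(spearman_corr(2^a, b)$rho, got$rho)
  }
})

test_that("the immune-factor panel reports direction and BH-corrected p-values", {
  b <- simulate_bulk(n_samples = 80, seed = 40)
  panel <- immune_factor_panel(b, "PGAP3")
  expect_equal(panel$gene, c("CXCL14", "TNFSF13B", "TNFSF18"))
  expect_true(all(panel$direction < 0))  # planted lower in marker-high
  expect_true(all(panel$fdr < 0.05))
  expect_equal(panel$fdr, p.adjust(panel$pval, "BH"))

  # constant panel gene is skipped, others unaffected
  b2 <- b
  b2$expression["CXCL14", ] <- 1
  expect_warning(panel2 <- immune_factor_panel(b2, "PGAP3"), "constant")
  expect_equal(panel2$gene, c("TNFSF13B", "TNFSF18"))
  expect_warning(panel3 <- immune_factor_panel(b, "PGAP3",
                                               panel = c("NOPE", "CXCL14")),
                 "missing")
  expect_equal(panel3$gene, "CXCL14")
})
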