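#' Construct a sparse single-cell count matrix container
#'
#' @param counts gene x cell matrix of non-negative integer counts (coerced to
#'   a sparse \code{dgCMatrix}); dimnames supply gene and cell names unless
#'   given explicitly.
#' @param genes,cells Optional name vectors overriding the dimnames.
#' @return An object of class \code{cell_matrix}.
#' @export
cell_matrix <- function(counts, genes = rownames(counts), cells = colnames(counts)) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  stopifnot(!is.null(genes), !is.null(cells),
            length(genes) == nrow(counts), length(cells) == ncol(counts))
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(genes, cells)
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("Cell matrix:", length(x$genes), "genes x", length(x$cells), "cells;",
      sprintf("%.1f%% nonzero\n",
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' Classify cells as marker-positive by detectable expression
#'
#' A cell is positive for the marker gene when its raw count exceeds zero
#' (detectable expression, accounting for single-cell sparsity); all other
#' cells are negative.
#'
#' @param m A \code{\link{cell_matrix}}.
#' @param gene Marker gene name.
#' @return Named logical vector over cells: TRUE = positive.
#' @export
classify_marker_positive <- function(m, gene) {
  stopifnot(inherits(m, "cell_matrix"))
  if (!gene %in% m$genes) stop("gene not present: ", gene)
  stats::setNames(as.vector(m$counts[gene, ] > 0), m$cells)
}

#' Marker-gene screen between two cell groups
#'
#' Normalizes each cell to counts per 10k, then per gene computes the log2
#' fold change \code{log2((mean_pos + 1)/(mean_neg + 1))} on the normalized
#' values, a two-sided Wilcoxon rank-sum p on the normalized values, and
#' Benjamini-Hochberg FDR over all tested genes. Reported genes satisfy
#' \code{|log2fc| >= lfc_min} and \code{fdr < fdr_max}.
#'
#' @param m A \code{\link{cell_matrix}}.
#' @param partition Logical vector over cells (TRUE = positive group); both
#'   groups must be non-empty.
#' @param lfc_min Absolute log2 fold-change threshold (default 0.5).
#' @param fdr_max FDR threshold (default 0.05).
#' @return data.frame \code{gene, log2fc, pval, fdr, mean_pos, mean_neg} of
#'   reported genes, ordered by ascending p; the full per-gene table is
#'   attached as attribute \code{"all_genes"}.
#' @export
find_markers <- function(m, partition, lfc_min = 0.5, fdr_max = 0.05) {
  stopifnot(inherits(m, "cell_matrix"), length(partition) == length(m$cells))
  partition <- as.logical(partition)
  if (!any(partition) || all(partition)) stop("both groups must be non-empty")
  norm <- normalize_cp10k(m$counts)
  pos <- which(partition)
  neg <- which(!partition)
  mean_pos <- Matrix::rowMeans(norm[, pos, drop = FALSE])
  mean_neg <- Matrix::rowMeans(norm[, neg, drop = FALSE])
  log2fc <- log2((mean_pos + 1) / (mean_neg + 1))
  pval <- vapply(seq_along(m$genes), function(i) {
    v <- as.vector(norm[i, ])
    if (length(unique(v)) == 1L) return(1)
    stats::wilcox.test(v[pos], v[neg], exact = FALSE, correct = FALSE)$p.value
  }, numeric(1))
  fdr <- stats::p.adjust(pval, "BH")
  all_genes <- data.frame(gene = m$genes, log2fc = log2fc, pval = pval,
                          fdr = fdr, mean_pos = mean_pos, mean_neg = mean_neg,
                          stringsAsFactors = FALSE, row.names = NULL)
  out <- all_genes[abs(all_genes$log2fc) >= lfc_min & all_genes$fdr < fdr_max, ,
                   drop = FALSE]
  out <- out[order(out$pval), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_genes") <- all_genes
  out
}

normalize_cp10k <- function(counts) {
  totals <- Matrix::colSums(counts)
  totals[totals == 0] <- 1
  counts %*% Matrix::Diagonal(x = 1e4 / totals)
}

#' Median dichotomization into high/low groups
#'
#' Splits samples at the empirical median (50th percentile): values at or
#' below the median are "low", values above it are "high" (ties go to the low
#' group). Deterministic and invariant to sample order.
#'
#' @param values Named (or unnamed) numeric vector, length >= 2.
#' @return Factor with levels \code{low}, \code{high}, names preserved.
#' @export
median_dichotomize <- function(values) {
  if (length(values) < 2L) stop("median_dichotomize: need >= 2 samples")
  med <- stats::median(values)
  out <- factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
  names(out) <- names(values)
  out
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U test. Uses the normal approximation with tie and
#' continuity corrections, switching to exact enumeration of all group
#' assignments when both groups have at most \code{exact_max} observations
#' (where the approximation is checkable and the exact distribution cheap).
#'
#' @param values Numeric vector.
#' @param partition Two-level factor/logical splitting \code{values}; both
#'   groups non-empty.
#' @param exact_max Exact-enumeration cutoff per group (default 8).
#' @return List: \code{u} (number of (x, y) pairs with x > y, ties counting
#'   half, x = first group), \code{pval}, \code{medians} (per group),
#'   \code{method}.
#' @export
compare_groups <- function(values, partition, exact_max = 8) {
  f <- as.factor(partition)
  if (nlevels(f) != 2L) stop("partition must have exactly two levels")
  x <- values[f == levels(f)[1]]
  y <- values[f == levels(f)[2]]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  u <- u_statistic(values, f == levels(f)[1])
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    mid <- n1 * n2 / 2
    u_all <- apply(combos, 2L, function(ix) {
      mask <- logical(n1 + n2)
      mask[ix] <- TRUE
      u_statistic(values, mask)
    })
    pval <- mean(abs(u_all - mid) >= abs(u - mid) - 1e-12)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(values)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      pval <- 1  # all values tied: no evidence either way
    } else {
      # continuity-corrected two-sided normal approximation
      z <- max(abs(u - n1 * n2 / 2) - 0.5, 0) / sqrt(sigma2)
      pval <- 2 * stats::pnorm(-z)
    }
    method <- "normal_approx"
  }
  list(u = u, pval = min(pval, 1),
       medians = c(stats::median(x), stats::median(y)), method = method)
}

u_statistic <- function(values, mask) {
  # U = sum of ranks of group 1 minus its minimum rank sum (midranks for ties)
  r <- rank(values)
  n1 <- sum(mask)
  sum(r[mask]) - n1 * (n1 + 1) / 2
}

#' Spearman rank correlation
#'
#' Pearson correlation of the midrank-transformed vectors, with a two-sided
#' p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 df.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List: \code{rho}, \code{pval}. A constant input yields NA rho with
#'   a warning.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("spearman_corr: constant input, rho undefined")
    return(list(rho = NA_real_, pval = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, pval = 0))
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, pval = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

#' Construct a bulk expression cohort
#'
#' @param expression gene x sample numeric matrix on the log2 TPM scale, with
#'   dimnames.
#' @return An object of class \code{bulk_cohort}.
#' @export
bulk_cohort <- function(expression) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  structure(list(expression = expression,
                 genes = rownames(expression),
                 samples = colnames(expression)),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat("Bulk cohort:", length(x$genes), "genes x", length(x$samples),
      "samples (log2 scale)\n")
  invisible(x)
}

#' Immune-factor panel comparison across marker-high/low groups
#'
#' Dichotomizes samples at the median expression of the marker gene, then for
#' each panel gene compares the two groups with the Mann-Whitney U test,
#' applies Benjamini-Hochberg correction across the panel, and reports the
#' direction as the high-group median minus the low-group median (negative =
#' lower immune-factor expression in marker-high samples).
#'
#' @param cohort A \code{\link{bulk_cohort}}.
#' @param marker_gene Gene used for the median split.
#' @param panel Character vector of panel genes (default the chemokine CXCL14
#'   and immune stimulators TNFSF13B, TNFSF18).
#' @return data.frame \code{gene, direction, median_high, median_low, u, pval,
#'   fdr}; panel genes missing from the cohort or constant are skipped with a
#'   warning.
#' @export
immune_factor_panel <- function(cohort, marker_gene,
                                panel = c("CXCL14", "TNFSF13B", "TNFSF18")) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  if (!marker_gene %in% cohort$genes) stop("marker gene not present: ", marker_gene)
  groups <- median_dichotomize(cohort$expression[marker_gene, ])
  rows <- list()
  for (g in panel) {
    if (!g %in% cohort$genes) {
      warning("panel gene missing, skipped: ", g)
      next
    }
    v <- cohort$expression[g, ]
    if (max(v) == min(v)) {
      warning("panel gene constant, skipped: ", g)
      next
    }
    cmp <- compare_groups(v, groups == "high")
    med_high <- stats::median(v[groups == "high"])
    med_low <- stats::median(v[groups == "low"])
    rows[[g]] <- data.frame(gene = g, direction = med_high - med_low,
                            median_high = med_high, median_low = med_low,
                            u = cmp$u, pval = cmp$pval,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no usable panel genes")
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pval, "BH")
  rownames(out) <- NULL
  out
}
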