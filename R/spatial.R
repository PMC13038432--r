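#' Construct a spot grid
#'
#' Container for spatial-transcriptomics spots: coordinates plus named
#' per-spot signals (real vectors, e.g. a marker score or a CTL score) and
#' labels (boolean masks, e.g. marker_high).
#'
#' @param spot_ids Character vector of spot identifiers (unique).
#' @param x,y Numeric coordinates (array or micron units); duplicated
#'   coordinates are rejected.
#' @param signals Named list of numeric vectors, one value per spot.
#' @param labels Named list of logical vectors, one value per spot.
#' @return An object of class \code{spot_grid}.
#' @export
spot_grid <- function(spot_ids, x, y, signals = list(), labels = list()) {
  n <- length(spot_ids)
  stopifnot(length(x) == n, length(y) == n, !anyDuplicated(spot_ids))
  if (anyDuplicated(cbind(x, y))) stop("duplicate spot coordinates")
  for (nm in names(signals))
    if (length(signals[[nm]]) != n)
      stop("signal '", nm, "' does not have one value per spot")
  for (nm in names(labels)) {
    if (length(labels[[nm]]) != n)
      stop("label '", nm, "' does not have one value per spot")
    labels[[nm]] <- as.logical(labels[[nm]])
  }
  structure(list(spot_ids = as.character(spot_ids),
                 coords = cbind(x = as.numeric(x), y = as.numeric(y)),
                 signals = signals, labels = labels),
            class = "spot_grid")
}

#' @export
print.spot_grid <- function(x, ...) {
  cat("Spot grid:", length(x$spot_ids), "spots;",
      length(x$signals), "signal(s):", paste(names(x$signals), collapse = ", "),
      ";", length(x$labels), "label(s):", paste(names(x$labels), collapse = ", "),
      "\n")
  invisible(x)
}

n_spots <- function(grid) length(grid$spot_ids)

grid_signal <- function(grid, signal) {
  if (is.character(signal)) {
    if (!signal %in% names(grid$signals)) stop("unknown signal: ", signal)
    grid$signals[[signal]]
  } else {
    stopifnot(length(signal) == n_spots(grid))
    as.numeric(signal)
  }
}

grid_mask <- function(grid, mask) {
  if (is.character(mask) && length(mask) == 1L) {
    if (!mask %in% names(grid$labels)) stop("unknown label: ", mask)
    grid$labels[[mask]]
  } else {
    stopifnot(length(mask) == n_spots(grid))
    as.logical(mask)
  }
}

#' Build the k-nearest-neighbor graph of a spot grid
#'
#' Euclidean distances; each spot's k nearest other spots, ties broken by
#' ascending spot index. Deterministic.
#'
#' @param grid A \code{\link{spot_grid}} with at least k + 1 spots.
#' @param k Number of neighbors (default 6).
#' @return An object of class \code{neighbor_graph}: \code{k},
#'   \code{neighbor_indices} (n x k integer matrix), \code{distances}
#'   (matching n x k matrix).
#' @export
build_knn <- function(grid, k = 6) {
  n <- n_spots(grid)
  if (n < k + 1L)
    stop("build_knn: need at least k + 1 = ", k + 1L, " spots, have ", n)
  d <- as.matrix(stats::dist(grid$coords))
  idx <- matrix(0L, n, k)
  dd <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    dd[i, ] <- d[i, ord]
  }
  structure(list(k = k, neighbor_indices = idx, distances = dd),
            class = "neighbor_graph")
}

#' Threshold a per-spot signal into a high/low mask
#'
#' Marks spots whose signal strictly exceeds the empirical quantile of that
#' signal across all spots (upper quartile by default). A constant signal
#' yields an all-false mask with a warning.
#'
#' @param grid A \code{\link{spot_grid}}.
#' @param signal_name Name of the signal to threshold.
#' @param quantile Quantile cut (default 0.75).
#' @return Logical mask, one entry per spot.
#' @export
threshold_spots <- function(grid, signal_name, quantile = 0.75) {
  v <- grid_signal(grid, signal_name)
  if (max(v) == min(v)) {
    warning("constant signal '", signal_name, "': all-false mask")
    return(rep(FALSE, length(v)))
  }
  v > stats::quantile(v, quantile, names = FALSE)
}

#' Neighborhood statistic: mean local signal around source spots
#'
#' For each source spot, the mean of the signal over its k nearest neighbors
#' (the source spot itself excluded); the statistic is the mean of those
#' per-spot means over all source spots. Under immune exclusion the local
#' immune signal around marker-high spots is depressed, so small values are
#' the interesting tail.
#'
#' @param grid A \code{\link{spot_grid}}.
#' @param graph A \code{\link{build_knn}} graph on the same grid.
#' @param source_mask Logical mask (or label name) of source spots; non-empty.
#' @param signal Signal name or numeric vector to average over neighborhoods.
#' @return The statistic (a single number).
#' @export
neighborhood_statistic <- function(grid, graph, source_mask, signal) {
  src <- which(grid_mask(grid, source_mask))
  if (length(src) == 0L) stop("neighborhood_statistic: empty source mask")
  v <- grid_signal(grid, signal)
  nb <- graph$neighbor_indices[src, , drop = FALSE]
  mean(rowMeans(matrix(v[nb], nrow = length(src))))
}

#' Nearest-neighbor distance statistic between two spot sets
#'
#' For each source spot, the Euclidean distance to the nearest target spot
#' (a spot belonging to both sets contributes 0); the statistic is the mean of
#' those distances over source spots. Under immune exclusion marker-high
#' regions sit far from immune-high spots, so large values are the interesting
#' tail.
#'
#' @param grid A \code{\link{spot_grid}}.
#' @param source_mask,target_mask Logical masks (or label names); both
#'   non-empty.
#' @return The statistic (a single number).
#' @export
nn_distance_statistic <- function(grid, source_mask, target_mask) {
  src <- which(grid_mask(grid, source_mask))
  tgt <- which(grid_mask(grid, target_mask))
  if (length(src) == 0L) stop("nn_distance_statistic: empty source mask")
  if (length(tgt) == 0L) stop("nn_distance_statistic: empty target mask")
  D <- cross_dist(grid$coords[src, , drop = FALSE],
                  grid$coords[tgt, , drop = FALSE])
  mean(row_mins(D))
}

cross_dist <- function(a, b) {
  # pairwise Euclidean distances, rows of a vs rows of b; computed from
  # coordinate differences so self-distances are exactly zero
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

row_mins <- function(m) {
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmin(out, m[, j])
  out
}

#' Coordinate-preserving permutation test for a spatial statistic
#'
#' Computes the observed statistic once, then generates B null draws by
#' uniformly permuting the immune signal values (statistic =
#' \code{"neighborhood"}) or the binary target labels (statistic =
#' \code{"nn_distance"}, or \code{permute = "labels"}) across all spots while
#' coordinates and the source mask stay fixed. The empirical p-value carries
#' the +1 correction: \eqn{p = (1 + \#extreme)/(B + 1)}, with ties counting as
#' extreme, so p is bounded in \eqn{[1/(B+1), 1]}.
#'
#' @param grid A \code{\link{spot_grid}}.
#' @param statistic "neighborhood" or "nn_distance".
#' @param source_mask Source mask or label name (fixed under the null).
#' @param signal Signal name/values for the neighborhood statistic.
#' @param target_mask Target mask or label name for the nn-distance statistic.
#' @param k Neighbors for the neighborhood statistic (default 6); ignored if
#'   \code{graph} is supplied.
#' @param graph Optional precomputed \code{\link{build_knn}} graph.
#' @param B Number of permutations (default 10000).
#' @param alternative "less" (observed in the lower tail) or "greater".
#' @param two_sided If TRUE, doubles the smaller one-sided p, capped at 1.
#' @param seed Integer seed; the null stream is fully determined by it.
#' @return An object of class \code{perm_test}: \code{observed},
#'   \code{null_draws}, \code{pval}, \code{alternative}, \code{B}, \code{seed}.
#' @export
permutation_test <- function(grid, statistic = c("neighborhood", "nn_distance"),
                             source_mask, signal = NULL, target_mask = NULL,
                             k = 6, graph = NULL, B = 10000,
                             alternative = c("less", "greater"),
                             two_sided = FALSE, seed) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("permutation_test: seed is required")
  if (B < 1) stop("permutation_test: B must be >= 1")
  n <- n_spots(grid)
  src <- grid_mask(grid, source_mask)

  if (statistic == "neighborhood") {
    if (is.null(signal)) stop("neighborhood statistic needs a signal")
    v <- grid_signal(grid, signal)
    if (is.null(graph)) graph <- build_knn(grid, k)
    nb <- graph$neighbor_indices[which(src), , drop = FALSE]
    stat_fun <- function(values) mean(rowMeans(
      matrix(values[nb], nrow = nrow(nb))))
    observed <- stat_fun(v)
    null_draws <- withr_seed(seed, vapply(seq_len(B), function(i)
      stat_fun(v[sample.int(n)]), numeric(1)))
  } else {
    if (is.null(target_mask)) stop("nn_distance statistic needs a target mask")
    tgt <- grid_mask(grid, target_mask)
    if (!any(tgt)) stop("nn_distance_statistic: empty target mask")
    if (!any(src)) stop("nn_distance_statistic: empty source mask")
    D <- cross_dist(grid$coords[src, , drop = FALSE], grid$coords)
    stat_fun <- function(mask) mean(row_mins(D[, mask, drop = FALSE]))
    observed <- stat_fun(tgt)
    null_draws <- withr_seed(seed, vapply(seq_len(B), function(i)
      stat_fun(sample(tgt)), numeric(1)))
  }

  extreme_le <- sum(null_draws <= observed)
  extreme_ge <- sum(null_draws >= observed)
  p_less <- (1 + extreme_le) / (B + 1)
  p_greater <- (1 + extreme_ge) / (B + 1)
  pval <- if (two_sided) min(1, 2 * min(p_less, p_greater))
    else if (alternative == "less") p_less else p_greater
  structure(list(observed = observed, null_draws = null_draws, pval = pval,
                 alternative = if (two_sided) "two.sided" else alternative,
                 statistic = statistic, B = B, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s statistic)\n", x$statistic))
  cat(sprintf("observed = %.6g, B = %d, alternative = %s, p = %.4g\n",
              x$observed, x$B, x$alternative, x$pval))
  invisible(x)
}

#' Immune-exclusion report for a spot grid
#'
#' The two-test screen for spatial immune exclusion around marker-high tumor
#' regions: (1) the kNN neighborhood statistic of the immune signal around
#' marker-high spots, tested against permutations of the immune values with
#' alternative "less" (exclusion = depressed local immune signal); (2) the
#' nearest-neighbor distance from marker-high spots to immune-high spots,
#' tested against permutations of the immune-high labels with alternative
#' "greater" (exclusion = increased separation). Both signals are thresholded
#' into high masks at \code{quantile}.
#'
#' @param grid A \code{\link{spot_grid}}.
#' @param marker_signal,immune_signal Signal names.
#' @param k Neighbors (default 6).
#' @param B Permutations per test (default 10000).
#' @param quantile High-mask quantile (default 0.75).
#' @param seed Integer seed; the two tests use seed and seed + 1.
#' @return An object of class \code{exclusion_report}: the two
#'   \code{\link{permutation_test}} results plus settings.
#' @export
exclusion_report <- function(grid, marker_signal, immune_signal, k = 6,
                             B = 10000, quantile = 0.75, seed) {
  if (missing(seed)) stop("exclusion_report: seed is required")
  marker_high <- threshold_spots(grid, marker_signal, quantile)
  immune_high <- threshold_spots(grid, immune_signal, quantile)
  neighborhood <- permutation_test(
    grid, "neighborhood", source_mask = marker_high, signal = immune_signal,
    k = k, B = B, alternative = "less", seed = seed)
  nn_distance <- permutation_test(
    grid, "nn_distance", source_mask = marker_high, target_mask = immune_high,
    B = B, alternative = "greater", seed = seed + 1L)
  structure(list(neighborhood = neighborhood, nn_distance = nn_distance,
                 settings = list(marker_signal = marker_signal,
                                 immune_signal = immune_signal, k = k, B = B,
                                 quantile = quantile, seed = seed,
                                 n_marker_high = sum(marker_high),
                                 n_immune_high = sum(immune_high))),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Immune-exclusion report\n")
  cat(sprintf("  marker-high spots: %d; immune-high spots: %d (quantile %.2f)\n",
              x$settings$n_marker_high, x$settings$n_immune_high,
              x$settings$quantile))
  cat(sprintf("  neighborhood (k=%d, less):   observed %.4g, p = %.4g\n",
              x$settings$k, x$neighborhood$observed, x$neighborhood$pval))
  cat(sprintf("  nn distance (greater):       observed %.4g, p = %.4g\n",
              x$nn_distance$observed, x$nn_distance$pval))
  invisible(x)
}
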