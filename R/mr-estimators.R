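mr_estimate <- function(method, beta, se, pval = NA_real_) {
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 or_ = exp(beta)), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: beta = %.*g (se %.*g), OR = %.*g, p = %.*g\n",
              x$method, digits, x$beta, digits, x$se, digits, x$or_,
              digits, x$pval))
  invisible(x)
}

ratios_and_weights <- function(iset) {
  s <- iset$snps
  list(b = s$beta_out / s$beta_exp, w = s$beta_exp^2 / s$se_out^2)
}

#' Wald ratio estimate from a single instrument
#'
#' The single-SNP causal effect: outcome effect divided by exposure effect.
#' The standard error uses the first-order delta approximation
#' \code{se_out / |beta_exp|}; exposure uncertainty is ignored, the usual
#' two-sample convention.
#'
#' @param beta_exp,se_exp Exposure effect and its standard error.
#' @param beta_out,se_out Outcome effect and its standard error.
#' @return An \code{mr_estimate} (two-sided normal p).
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) stop("wald_ratio undefined: beta_exp = 0")
  beta <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  mr_estimate("wald", beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

#' Inverse-variance weighted estimate
#'
#' Fixed-effects inverse-variance weighted meta-analysis of the per-SNP Wald
#' ratios, with weights \eqn{w_j = \beta_{exp,j}^2 / se_{out,j}^2} (the inverse
#' first-order variance of each ratio). Optionally inflates the standard error
#' multiplicatively by \eqn{\sqrt{Q/(n-1)}} when the heterogeneity ratio
#' exceeds 1 (multiplicative random effects).
#'
#' @param iset An \code{\link{instrument_set}} with at least one SNP.
#' @param random_effects Apply the multiplicative random-effects inflation.
#' @return An \code{mr_estimate}.
#' @export
ivw <- function(iset, random_effects = FALSE) {
  stopifnot(inherits(iset, "instrument_set"), length(iset) >= 1L)
  if (length(iset) == 1L) {
    s <- iset$snps
    est <- wald_ratio(s$beta_exp, s$se_exp, s$beta_out, s$se_out)
    est$method <- "ivw"
    return(est)
  }
  rw <- ratios_and_weights(iset)
  beta <- sum(rw$w * rw$b) / sum(rw$w)
  se <- 1 / sqrt(sum(rw$w))
  if (random_effects && length(iset) >= 2L) {
    q <- sum(rw$w * (rw$b - beta)^2)
    se <- se * max(1, sqrt(q / (length(iset) - 1L)))
  }
  mr_estimate("ivw", beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept (weights \eqn{1/se_{out}^2}), after orienting all exposure
#' effects non-negative. The intercept estimates directional horizontal
#' pleiotropy; its two-sided p uses a t distribution with n - 2 df.
#'
#' @param iset An \code{\link{instrument_set}} with at least 3 SNPs.
#' @return A list: \code{slope} (an \code{mr_estimate}), \code{intercept},
#'   \code{intercept_se}, \code{intercept_pval}.
#' @export
mr_egger <- function(iset) {
  stopifnot(inherits(iset, "instrument_set"))
  if (length(iset) < 3L) stop("insufficient instruments for Egger (need >= 3)")
  s <- iset$snps
  flip <- sign(s$beta_exp)
  flip[flip == 0] <- 1
  bx <- s$beta_exp * flip
  by <- s$beta_out * flip
  fit <- stats::lm(by ~ bx, weights = 1 / s$se_out^2)
  cf <- summary(fit)$coefficients
  df <- length(iset) - 2L
  slope_p <- 2 * stats::pt(-abs(cf["bx", "Estimate"] / cf["bx", "Std. Error"]), df)
  list(
    slope = mr_estimate("egger_slope", cf["bx", "Estimate"],
                        cf["bx", "Std. Error"], slope_p),
    intercept = cf["(Intercept)", "Estimate"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    intercept_pval = 2 * stats::pt(
      -abs(cf["(Intercept)", "Estimate"] / cf["(Intercept)", "Std. Error"]), df)
  )
}

weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(b[1])
  if (cw[length(cw)] <= 0.5) return(b[length(b)])
  stats::approx(cw, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' Weighted median of the per-SNP Wald ratios (interpolated at cumulative
#' weight 0.5), consistent when at least half the weight comes from valid
#' instruments. The standard error comes from a seeded parametric bootstrap
#' that redraws both exposure and outcome effects from their sampling
#' distributions.
#'
#' @param iset An \code{\link{instrument_set}} with at least 3 SNPs.
#' @param boot_reps Bootstrap resamples for the SE (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return An \code{mr_estimate}.
#' @export
weighted_median <- function(iset, boot_reps = 200, seed = 1L) {
  stopifnot(inherits(iset, "instrument_set"))
  if (length(iset) < 3L) stop("insufficient instruments for weighted median (need >= 3)")
  s <- iset$snps
  rw <- ratios_and_weights(iset)
  beta <- weighted_median_point(rw$b, rw$w)
  n <- nrow(s)
  boots <- withr_seed(seed, {
    vapply(seq_len(boot_reps), function(i) {
      bx <- stats::rnorm(n, s$beta_exp, s$se_exp)
      by <- stats::rnorm(n, s$beta_out, s$se_out)
      weighted_median_point(by / bx, bx^2 / s$se_out^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("weighted_median", beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

# evaluate code with a local RNG state so callers' streams are untouched
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

silverman_bw <- function(b) {
  n <- length(b)
  s <- stats::sd(b)
  m <- stats::mad(b)
  h <- 0.9 * (if (m > 0) min(s, m) else s) * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) h <- 1e-8
  h
}

kde_mode <- function(b, w, h, n_grid = 512L) {
  w <- w / sum(w)
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = n_grid)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm((g - b) / h)), numeric(1))
  grid[which.max(dens)]
}

#' Simple and weighted mode estimates
#'
#' Mode of the Gaussian-kernel-smoothed density of the Wald ratios, unweighted
#' (simple mode) and inverse-variance weighted (weighted mode). Bandwidth is a
#' modified Silverman rule, \eqn{0.9 \min(sd, mad) n^{-1/5}}, scaled by
#' \code{bandwidth_mult}; the density is evaluated on a 512-point grid spanning
#' the ratio range plus three bandwidths. Reported without p-values
#' (diagnostic estimators).
#'
#' @param iset An \code{\link{instrument_set}} with at least 3 SNPs.
#' @param bandwidth_mult Multiplier on the Silverman bandwidth.
#' @return List with \code{simple_mode} and \code{weighted_mode} estimates.
#' @export
mode_estimates <- function(iset, bandwidth_mult = 1.0) {
  stopifnot(inherits(iset, "instrument_set"))
  if (length(iset) < 3L) stop("insufficient instruments for mode estimators (need >= 3)")
  rw <- ratios_and_weights(iset)
  if (stats::sd(rw$b) == 0) {
    m <- rw$b[1]
    return(list(simple_mode = mr_estimate("simple_mode", m, NA_real_),
                weighted_mode = mr_estimate("weighted_mode", m, NA_real_)))
  }
  h <- bandwidth_mult * silverman_bw(rw$b)
  list(
    simple_mode = mr_estimate("simple_mode",
                              kde_mode(rw$b, rep(1, length(rw$b)), h), NA_real_),
    weighted_mode = mr_estimate("weighted_mode", kde_mode(rw$b, rw$w, h), NA_real_)
  )
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j w_j (b_j - \beta_{IVW})^2} over the Wald ratios, referred to
#' a chi-square distribution with n - 1 df.
#'
#' @param iset An \code{\link{instrument_set}} with at least 2 SNPs.
#' @param beta_ivw The IVW point estimate; computed from \code{iset} if NULL.
#' @return List with \code{q} and \code{pval}.
#' @export
cochran_q <- function(iset, beta_ivw = NULL) {
  stopifnot(inherits(iset, "instrument_set"))
  if (length(iset) < 2L) stop("Cochran's Q needs >= 2 instruments")
  rw <- ratios_and_weights(iset)
  if (is.null(beta_ivw)) beta_ivw <- sum(rw$w * rw$b) / sum(rw$w)
  q <- sum(rw$w * (rw$b - beta_ivw)^2)
  list(q = q, pval = stats::pchisq(q, df = length(iset) - 1L, lower.tail = FALSE))
}

#' Fit the full panel of MR estimators to one instrument set
#'
#' Runs the Wald ratio (single instrument) or, with multiple instruments, IVW
#' (the primary estimator), MR-Egger, weighted median, simple and weighted
#' modes, plus the Egger-intercept pleiotropy test and Cochran's Q
#' heterogeneity test.
#'
#' @param iset An \code{\link{instrument_set}}.
#' @param boot_reps,seed Passed to \code{\link{weighted_median}}.
#' @param random_effects Passed to \code{\link{ivw}}.
#' @return An object of class \code{mr_fit} with \code{print}, \code{summary}
#'   and \code{coef} methods. \code{$primary} is the IVW (or Wald) estimate;
#'   \code{$pleiotropy_pval} and \code{$heterogeneity_pval} are NA when fewer
#'   than 3 (resp. 2) instruments are available.
#' @export
mr_fit <- function(iset, boot_reps = 200, seed = 1L, random_effects = FALSE) {
  stopifnot(inherits(iset, "instrument_set"))
  n <- length(iset)
  est <- list()
  if (n == 1L) {
    s <- iset$snps
    est$ivw <- wald_ratio(s$beta_exp, s$se_exp, s$beta_out, s$se_out)
    est$ivw$method <- "ivw"
    pleio <- list(intercept = NA_real_, intercept_se = NA_real_,
                  intercept_pval = NA_real_)
    het <- list(q = NA_real_, pval = NA_real_)
  } else {
    est$ivw <- ivw(iset, random_effects = random_effects)
    het <- cochran_q(iset, est$ivw$beta)
    if (n >= 3L) {
      eg <- mr_egger(iset)
      est$egger_slope <- eg$slope
      pleio <- eg[c("intercept", "intercept_se", "intercept_pval")]
      est$weighted_median <- weighted_median(iset, boot_reps, seed)
      modes <- mode_estimates(iset)
      est$simple_mode <- modes$simple_mode
      est$weighted_mode <- modes$weighted_mode
    } else {
      pleio <- list(intercept = NA_real_, intercept_se = NA_real_,
                    intercept_pval = NA_real_)
    }
  }
  structure(list(gene = iset$gene, n_snps = n, estimates = est,
                 primary = est$ivw, pleiotropy = pleio,
                 pleiotropy_pval = pleio$intercept_pval,
                 heterogeneity_q = het$q, heterogeneity_pval = het$pval),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("MR fit:", x$gene, "(", x$n_snps, "instruments )\n")
  for (e in x$estimates) print(e)
  cat(sprintf("Egger intercept p = %.4g; Cochran's Q p = %.4g\n",
              x$pleiotropy_pval, x$heterogeneity_pval))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$estimates, function(e)
    data.frame(method = e$method, beta = e$beta, se = e$se, or = e$or_,
               pval = e$pval, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  structure(list(gene = object$gene, n_snps = object$n_snps, table = tab,
                 pleiotropy_pval = object$pleiotropy_pval,
                 heterogeneity_pval = object$heterogeneity_pval),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  cat("Gene:", x$gene, "-", x$n_snps, "instruments\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("pleiotropy p = %.4g, heterogeneity p = %.4g\n",
              x$pleiotropy_pval, x$heterogeneity_pval))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}
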