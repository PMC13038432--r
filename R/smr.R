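#' Summary-data-based MR (SMR) test for one top SNP
#'
#' Uses the top cis-eQTL SNP as the sole instrument. The effect is the ratio
#' \eqn{b_{SMR} = \beta_{GWAS}/\beta_{eQTL}}; with z-scores
#' \eqn{z_1 = \beta_{eQTL}/se_{eQTL}} and \eqn{z_2 = \beta_{GWAS}/se_{GWAS}},
#' the test statistic is \eqn{T = z_1^2 z_2^2 / (z_1^2 + z_2^2)}, referred to
#' chi-square with 1 df. T is symmetric in (z1, z2) and bounded above by
#' \eqn{\min(z_1^2, z_2^2)}: the weaker of the two associations limits the
#' evidence.
#'
#' @param beta_eqtl,se_eqtl Top-SNP eQTL effect and standard error.
#' @param beta_gwas,se_gwas Top-SNP GWAS effect and standard error.
#' @return List with \code{b_smr}, \code{t_smr}, \code{p_smr}.
#' @export
smr_test <- function(beta_eqtl, se_eqtl, beta_gwas, se_gwas) {
  if (beta_eqtl == 0) stop("smr_test undefined: beta_eqtl = 0")
  stopifnot(se_eqtl > 0, se_gwas > 0)
  z1 <- beta_eqtl / se_eqtl
  z2 <- beta_gwas / se_gwas
  t_smr <- z1^2 * z2^2 / (z1^2 + z2^2)
  list(b_smr = beta_gwas / beta_eqtl, t_smr = t_smr,
       p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE))
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant from linkage of distinct
#' variants at a cis locus. For each eligible flanking SNP i, the contrast
#' \eqn{d_i = b_{SMR}(i) - b_{SMR}(top)} should be zero under a shared
#' variant. The covariance of d is obtained by the delta method from the
#' per-SNP sampling variances and the LD correlations (eQTL and GWAS samples
#' independent). The statistic is the sum of squared standardized contrasts;
#' its null distribution - a sum of correlated chi-squares - is approximated
#' by Satterthwaite moment matching: with correlation matrix R of the
#' standardized contrasts, \eqn{T/c \sim \chi^2_\nu} where
#' \eqn{c = tr(R^2)/m} and \eqn{\nu = m^2/tr(R^2)}. Under identity LD this is
#' exactly chi-square with m df. A large p is consistent with one shared
#' causal variant.
#'
#' Eligible flanking SNPs must have eQTL p below \code{eqtl_p_max} and LD
#' \eqn{r^2} with the top SNP within \code{r2_range}; at most \code{max_snps}
#' are used, taken by ascending eQTL p.
#'
#' @param cis data.frame with columns \code{beta_eqtl}, \code{se_eqtl},
#'   \code{beta_gwas}, \code{se_gwas} (one row per cis SNP).
#' @param ld Signed LD correlation (r) matrix covering all cis SNPs, in the
#'   same order as \code{cis}.
#' @param top_index Row index of the top SNP in \code{cis}.
#' @param max_snps Cap on flanking SNPs (default 20).
#' @param eqtl_p_max Eligibility threshold on flanking eQTL p (default 1.57e-3).
#' @param r2_range Eligible LD r-squared window with the top SNP.
#' @param min_snps Minimum eligible flanking SNPs; below this the p is NA.
#' @return List with \code{p_heidi}, \code{statistic}, \code{n_snps} (flanking
#'   SNPs used). \code{p_heidi} is NA when too few SNPs are eligible.
#' @export
heidi_test <- function(cis, ld, top_index, max_snps = 20,
                       eqtl_p_max = 1.57e-3, r2_range = c(0.05, 0.9),
                       min_snps = 3) {
  stopifnot(nrow(cis) == nrow(ld), top_index >= 1, top_index <= nrow(cis))
  z_e <- cis$beta_eqtl / cis$se_eqtl
  p_e <- 2 * stats::pnorm(-abs(z_e))
  r_top <- ld[, top_index]
  idx <- setdiff(which(p_e < eqtl_p_max &
                         r_top^2 >= r2_range[1] & r_top^2 <= r2_range[2]),
                 top_index)
  if (length(idx) < min_snps)
    return(list(p_heidi = NA_real_, statistic = NA_real_, n_snps = length(idx)))
  if (length(idx) > max_snps) idx <- idx[order(p_e[idx])][seq_len(max_snps)]
  idx <- sort(idx)

  bg <- cis$beta_gwas
  be <- cis$beta_eqtl
  sg <- cis$se_gwas
  se <- cis$se_eqtl
  t <- top_index
  b_smr <- bg / be
  d <- b_smr[idx] - b_smr[t]
  m <- length(idx)

  # delta-method covariance of d over the joint sampling of (beta_gwas,
  # beta_eqtl) at the flanking SNPs and the top SNP; eQTL and GWAS effect
  # estimates are independent, within each study cov(beta_i, beta_j) =
  # r_ij * se_i * se_j
  V <- matrix(0, m, m)
  for (a in seq_len(m)) {
    i <- idx[a]
    for (b in a:m) {
      j <- idx[b]
      cov_g <- ld[i, j] * sg[i] * sg[j] / (be[i] * be[j]) -
        ld[i, t] * sg[i] * sg[t] / (be[i] * be[t]) -
        ld[j, t] * sg[j] * sg[t] / (be[j] * be[t]) +
        sg[t]^2 / be[t]^2
      cov_e <- ld[i, j] * se[i] * se[j] * bg[i] * bg[j] / (be[i]^2 * be[j]^2) -
        ld[i, t] * se[i] * se[t] * bg[i] * bg[t] / (be[i]^2 * be[t]^2) -
        ld[j, t] * se[j] * se[t] * bg[j] * bg[t] / (be[j]^2 * be[t]^2) +
        se[t]^2 * bg[t]^2 / be[t]^4
      V[a, b] <- V[b, a] <- cov_g + cov_e
    }
  }
  z_d <- d / sqrt(diag(V))
  statistic <- sum(z_d^2)
  R <- stats::cov2cor(V)
  tr_r2 <- sum(R^2)
  c_scale <- tr_r2 / m
  nu <- m^2 / tr_r2
  p <- stats::pchisq(statistic / c_scale, df = nu, lower.tail = FALSE)
  list(p_heidi = p, statistic = statistic, n_snps = m)
}

#' Run the SMR/HEIDI screen on a cis locus
#'
#' Selects the top cis-eQTL SNP (smallest eQTL p, required to pass
#' \code{top_p_max}), computes the SMR statistic at that SNP and the HEIDI
#' test over the eligible flanking SNPs.
#'
#' @param cis data.frame with \code{snp}, \code{beta_eqtl}, \code{se_eqtl},
#'   \code{beta_gwas}, \code{se_gwas}.
#' @param ld Signed LD (r) matrix in the row order of \code{cis}.
#' @param gene,cohort Labels for the resulting record.
#' @param top_p_max Instrument eligibility threshold on the top eQTL p
#'   (default 1e-5).
#' @param ... Passed to \code{\link{heidi_test}}.
#' @return data.frame row: gene, cohort, top_snp, b_smr, p_smr, p_heidi, or
#'   NULL when no SNP passes \code{top_p_max}.
#' @export
smr_locus <- function(cis, ld, gene = "gene", cohort = "cohort",
                      top_p_max = 1e-5, ...) {
  z_e <- cis$beta_eqtl / cis$se_eqtl
  p_e <- 2 * stats::pnorm(-abs(z_e))
  top <- which.min(p_e)
  if (p_e[top] >= top_p_max) return(NULL)
  s <- smr_test(cis$beta_eqtl[top], cis$se_eqtl[top],
                cis$beta_gwas[top], cis$se_gwas[top])
  h <- heidi_test(cis, ld, top, ...)
  data.frame(gene = gene, cohort = cohort, top_snp = cis$snp[top],
             b_smr = s$b_smr, p_smr = s$p_smr, p_heidi = h$p_heidi,
             stringsAsFactors = FALSE)
}
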