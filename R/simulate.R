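NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)

#' Simulate exposure and outcome summary statistics for one gene
#'
#' Generates an instrument-grade cis-eQTL exposure (strong effects, all
#' reported for the expression-increasing allele, so every SNP passes the
#' genome-wide significance and F >= 10 filters by construction) and a GWAS
#' outcome obeying \eqn{\beta_{out} = \beta \cdot \beta_{exp} + \delta +
#' \epsilon}. A controlled fraction of SNPs gets palindromic alleles with EAF
#' near 0.5 (dropped at harmonization), and a fraction of outcome records is
#' reported on the opposite allele (sign-flipped) to exercise harmonization.
#' Fully reproducible from the seed.
#'
#' @param n_snps Number of instruments (>= 1).
#' @param true_beta Causal effect of exposure on outcome.
#' @param pleiotropy_delta Constant directional pleiotropy added to every
#'   outcome effect (default 0).
#' @param se_exp,se_out Exposure/outcome standard errors (> 0).
#' @param beta_exp_range Range of true exposure effect sizes (uniform draw).
#' @param maf_range Range of effect-allele frequencies for non-palindromic SNPs.
#' @param frac_palindromic Fraction of SNPs given ambiguous palindromic alleles.
#' @param frac_flipped Fraction of outcome records reported on the swapped
#'   allele.
#' @param n_exp,n_out Sample sizes recorded in the tables.
#' @param seed Integer seed.
#' @return List with \code{exposure} and \code{outcome} data.frames in the
#'   summary-statistics schema (snp, effect_allele, other_allele, eaf, beta,
#'   se, pval, n).
#' @export
simulate_mr_dataset <- function(n_snps = 50, true_beta = 0.1,
                                pleiotropy_delta = 0, se_exp = 0.01,
                                se_out = 0.01,
                                beta_exp_range = c(0.08, 0.2),
                                maf_range = c(0.1, 0.45),
                                frac_palindromic = 0.1, frac_flipped = 0.3,
                                n_exp = 30000, n_out = 120000, seed = 1L) {
  stopifnot(n_snps >= 1, se_exp > 0, se_out > 0,
            frac_palindromic >= 0, frac_palindromic < 1)
  withr_seed(seed, {
    snp <- sprintf("rs%06d", sort(sample.int(999999, n_snps)))
    beta_exp_true <- stats::runif(n_snps, beta_exp_range[1], beta_exp_range[2])
    beta_exp <- beta_exp_true + stats::rnorm(n_snps, 0, se_exp)
    beta_out_true <- true_beta * beta_exp_true + pleiotropy_delta
    beta_out <- beta_out_true + stats::rnorm(n_snps, 0, se_out)

    pal <- stats::runif(n_snps) < frac_palindromic
    ea <- oa <- character(n_snps)
    pair <- NON_PALINDROMIC_PAIRS[sample.int(nrow(NON_PALINDROMIC_PAIRS),
                                             n_snps, replace = TRUE), ,
                                  drop = FALSE]
    ea[!pal] <- pair[!pal, 1]
    oa[!pal] <- pair[!pal, 2]
    pal_at <- stats::runif(n_snps) < 0.5
    ea[pal & pal_at] <- "A"; oa[pal & pal_at] <- "T"
    ea[pal & !pal_at] <- "C"; oa[pal & !pal_at] <- "G"
    eaf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    eaf[pal] <- stats::runif(sum(pal), 0.45, 0.55)  # ambiguous by construction

    flip <- stats::runif(n_snps) < frac_flipped
    exposure <- data.frame(
      snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = beta_exp, se = se_exp,
      pval = 2 * stats::pnorm(-abs(beta_exp / se_exp)), n = n_exp,
      stringsAsFactors = FALSE)
    outcome <- data.frame(
      snp = snp,
      effect_allele = ifelse(flip, oa, ea),
      other_allele = ifelse(flip, ea, oa),
      eaf = ifelse(flip, 1 - eaf, eaf),
      beta = ifelse(flip, -beta_out, beta_out), se = se_out,
      pval = 2 * stats::pnorm(-abs(beta_out / se_out)), n = n_out,
      stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome)
  })
}

#' Simulate a cis locus for the SMR/HEIDI screen
#'
#' Builds an AR(1)-style signed LD matrix (\eqn{r_{ij} = decay^{|i-j|}}) and
#' draws eQTL and GWAS z-score vectors from the standard summary-statistic
#' model \eqn{z \sim N(z_c \cdot r_{\cdot c}, R)}. When \code{true_shared},
#' one causal variant drives both traits (b_SMR constant across SNPs,
#' HEIDI-consistent); otherwise the GWAS signal comes from a second, distinct
#' causal variant (HEIDI-inconsistent).
#'
#' @param n_snps Number of cis SNPs (>= 5).
#' @param ld_decay AR(1) decay per SNP step, in (0, 1).
#' @param true_shared Single shared causal variant (TRUE) or two distinct
#'   variants (FALSE).
#' @param z_eqtl,z_gwas z-scores at the causal variant(s).
#' @param n_sample Nominal sample size setting the standard errors
#'   (se = 1/sqrt(n)).
#' @param seed Integer seed.
#' @return List: \code{cis} (data.frame snp, beta_eqtl, se_eqtl, beta_gwas,
#'   se_gwas), \code{ld} (signed r matrix), \code{causal_eqtl},
#'   \code{causal_gwas} (indices).
#' @export
simulate_smr_locus <- function(n_snps = 31, ld_decay = 0.9, true_shared = TRUE,
                               z_eqtl = 9, z_gwas = 6, n_sample = 10000,
                               seed = 1L) {
  stopifnot(n_snps >= 5)
  if (!(ld_decay > 0 && ld_decay < 1)) stop("ld_decay must be in (0, 1)")
  R <- ld_decay^abs(outer(seq_len(n_snps), seq_len(n_snps), "-"))
  c_e <- (n_snps + 1L) %/% 2L
  c_g <- if (true_shared) c_e else max(1L, c_e - max(3L, n_snps %/% 4L))
  withr_seed(seed, {
    L <- t(chol(R))
    z_e <- z_eqtl * R[, c_e] + as.vector(L %*% stats::rnorm(n_snps))
    z_g <- z_gwas * R[, c_g] + as.vector(L %*% stats::rnorm(n_snps))
  })
  se <- 1 / sqrt(n_sample)
  snp <- sprintf("snp_%03d", seq_len(n_snps))
  dimnames(R) <- list(snp, snp)
  list(cis = data.frame(snp = snp, beta_eqtl = z_e * se, se_eqtl = se,
                        beta_gwas = z_g * se, se_gwas = se,
                        stringsAsFactors = FALSE),
       ld = R, causal_eqtl = c_e, causal_gwas = c_g)
}

#' Simulate a spot lattice with a planted spatial pattern
#'
#' An n_side x n_side unit lattice. A contiguous tumor patch (the spots
#' nearest a random center, about \code{tumor_fraction} of the lattice)
#' receives a high marker score. The immune score is
#' \code{immune_baseline + noise} everywhere; under \code{pattern =
#' "exclusion"} it is lowered by \code{effect} inside the patch, under
#' \code{"colocalized"} raised by \code{effect}, and under \code{"null"} it
#' carries no spatial structure (effect forced to 0), so immune values are
#' exchangeable across spots.
#'
#' @param n_side Lattice side length (>= 4).
#' @param pattern "null", "exclusion" or "colocalized".
#' @param effect Magnitude of the planted immune shift inside the patch.
#' @param tumor_fraction Fraction of spots in the tumor patch.
#' @param immune_baseline Mean immune score outside the patch.
#' @param noise_sd Gaussian noise sd for both scores.
#' @param marker_contrast Marker-score elevation inside the patch.
#' @param seed Integer seed.
#' @return A \code{\link{spot_grid}} with signals \code{marker},
#'   \code{immune} and the ground-truth label \code{tumor}.
#' @export
simulate_spot_grid <- function(n_side = 16,
                               pattern = c("null", "exclusion", "colocalized"),
                               effect = 2, tumor_fraction = 0.25,
                               immune_baseline = 1, noise_sd = 0.5,
                               marker_contrast = 3, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(n_side >= 4, effect >= 0, noise_sd > 0,
            tumor_fraction > 0, tumor_fraction < 1)
  if (pattern == "null") effect <- 0
  n <- n_side^2
  coords <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))
  withr_seed(seed, {
    center <- coords[sample.int(n, 1L), ]
    d2 <- (coords$x - center$x)^2 + (coords$y - center$y)^2
    n_tumor <- max(1L, round(tumor_fraction * n))
    tumor <- seq_len(n) %in% order(d2, seq_len(n))[seq_len(n_tumor)]
    marker <- marker_contrast * tumor + stats::rnorm(n, 0, noise_sd)
    shift <- switch(pattern, null = 0, exclusion = -effect, colocalized = effect)
    immune <- immune_baseline + shift * tumor + stats::rnorm(n, 0, noise_sd)
  })
  spot_grid(sprintf("spot_%04d", seq_len(n)), coords$x, coords$y,
            signals = list(marker = marker, immune = immune),
            labels = list(tumor = tumor))
}

#' Simulate a sparse single-cell count matrix with a marker-positive subset
#'
#' Negative-binomial counts with lognormal gene base means. The marker gene is
#' nonzero exactly in the planted positive fraction of cells (zero-truncated
#' counts there, zero elsewhere); genes named in \code{de_genes} have their
#' mean multiplied by the given fold in positive cells.
#'
#' @param n_genes Total genes including the marker and DE genes.
#' @param n_cells Total cells.
#' @param marker_gene Marker gene name.
#' @param frac_positive Fraction of cells positive for the marker, in (0, 1).
#' @param de_genes Named numeric vector, gene -> fold change in positive cells.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return A \code{\link{cell_matrix}} with attribute \code{"positive_cells"}
#'   giving the planted positive-cell names.
#' @export
simulate_counts <- function(n_genes = 50, n_cells = 400, marker_gene = "PGAP3",
                            frac_positive = 0.5,
                            de_genes = stats::setNames(rep(4, 5), paste0("DE", 1:5)),
                            dispersion = 2, seed = 1L) {
  stopifnot(frac_positive > 0, frac_positive < 1,
            n_genes >= length(de_genes) + 1L)
  n_filler <- n_genes - length(de_genes) - 1L
  genes <- c(marker_gene, names(de_genes),
             sprintf("gene%03d", seq_len(n_filler)))
  cells <- sprintf("cell%04d", seq_len(n_cells))
  withr_seed(seed, {
    positive <- sort(sample.int(n_cells, round(frac_positive * n_cells)))
    # marker and DE genes get low base expression relative to the filler
    # background so the planted folds perturb per-cell library composition
    # only mildly, as a handful of regulated genes does in a real transcriptome
    base_mu <- c(2, rep(1, length(de_genes)),
                 stats::rlnorm(n_filler, meanlog = log(5), sdlog = 0.4))
    mu <- matrix(base_mu, n_genes, n_cells)
    fold <- stats::setNames(rep(1, n_genes), genes)
    fold[names(de_genes)] <- de_genes
    mu[, positive] <- mu[, positive] * fold
    counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                    size = dispersion),
                     n_genes, n_cells)
    counts[1, ] <- 0
    counts[1, positive] <- stats::rnbinom(length(positive),
                                          mu = base_mu[1], size = dispersion) + 1L
  })
  m <- cell_matrix(counts, genes = genes, cells = cells)
  attr(m, "positive_cells") <- cells[positive]
  m
}

#' Simulate a bulk expression cohort with planted panel effects
#'
#' Log2-scale expression. The marker gene is drawn around a fixed mean; panel
#' genes are shifted downward by their \code{panel_effects} entry in the
#' samples whose marker expression lies above the marker median (emulating
#' immune-factor depletion in marker-high tumors).
#'
#' @param n_samples Number of samples (>= 4).
#' @param marker_gene Marker gene name.
#' @param panel_effects Named numeric vector, gene -> downward shift in
#'   marker-high samples.
#' @param n_filler Additional unstructured genes.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param seed Integer seed.
#' @return A \code{\link{bulk_cohort}}.
#' @export
simulate_bulk <- function(n_samples = 100, marker_gene = "PGAP3",
                          panel_effects = c(CXCL14 = 2, TNFSF13B = 2,
                                            TNFSF18 = 2),
                          n_filler = 20, noise_sd = 0.5, seed = 1L) {
  stopifnot(n_samples >= 4, noise_sd > 0)
  genes <- c(marker_gene, names(panel_effects),
             sprintf("gene%03d", seq_len(n_filler)))
  samples <- sprintf("sample%03d", seq_len(n_samples))
  withr_seed(seed, {
    marker <- stats::rnorm(n_samples, 5, 1)
    high <- marker > stats::median(marker)
    expr <- matrix(stats::rnorm(length(genes) * n_samples, 5, noise_sd),
                   length(genes), n_samples,
                   dimnames = list(genes, samples))
    expr[marker_gene, ] <- marker
    for (g in names(panel_effects))
      expr[g, high] <- expr[g, high] - panel_effects[[g]]
  })
  bulk_cohort(expr)
}
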