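# Independent brute-force oracles used across test files. These deliberately
# re-derive each quantity with the most literal formulation available so they
# stay independent of the package's code paths.

# generic weighted least squares via the normal equations
wls_solve <- function(X, y, w) {
  W <- diag(w, nrow = length(w))
  solve(t(X) %*% W %*% X, t(X) %*% W %*% y)[, 1]
}

# full-sort k nearest neighbors, ties by ascending index
naive_knn <- function(coords, k) {
  n <- nrow(coords)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt((coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2)
    ord <- order(d, seq_len(n))
    ord[ord != i][seq_len(k)]
  }, integer(k)))
}

# double-loop neighborhood statistic
naive_neighborhood <- function(coords, source, values, k) {
  nb <- naive_knn(coords, k)
  means <- vapply(which(source), function(i) mean(values[nb[i, ]]), numeric(1))
  mean(means)
}

# all-pairs minimum-distance statistic
naive_nn_distance <- function(coords, source, target) {
  ti <- which(target)
  mean(vapply(which(source), function(i) {
    min(sqrt((coords[ti, 1] - coords[i, 1])^2 +
               (coords[ti, 2] - coords[i, 2])^2))
  }, numeric(1)))
}

# cumulative-weight interpolation for the weighted median, written as an
# explicit scan rather than approx()
naive_weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(b[1])
  for (j in seq_along(cw)[-1]) {
    if (cw[j] >= 0.5) {
      return(b[j - 1] + (b[j] - b[j - 1]) * (0.5 - cw[j - 1]) / (cw[j] - cw[j - 1]))
    }
  }
  b[length(b)]
}

# small harmonized instrument set straight from vectors
toy_iset <- function(beta_exp, se_exp, beta_out, se_out, gene = "toy") {
  n <- length(beta_exp)
  instrument_set(gene, data.frame(
    snp = sprintf("rs%03d", seq_len(n)),
    beta_exp = beta_exp, se_exp = se_exp,
    pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
    beta_out = beta_out, se_out = se_out))
}

random_iset <- function(n, seed) {
  set.seed(seed)
  toy_iset(runif(n, 0.05, 0.3), runif(n, 0.005, 0.02),
           rnorm(n, 0.02, 0.02), runif(n, 0.005, 0.02))
}

random_grid <- function(n, seed, n_signals = 1) {
  set.seed(seed)
  signals <- stats::setNames(
    lapply(seq_len(n_signals), function(i) rnorm(n)),
    paste0("sig", seq_len(n_signals)))
  spot_grid(sprintf("s%03d", seq_len(n)), runif(n, 0, 50), runif(n, 0, 50),
            signals = signals)
}

# swap alleles and negate effects of a summary-statistics table
flip_alleles <- function(d) {
  data.frame(snp = d$snp, effect_allele = d$other_allele,
             other_allele = d$effect_allele, eaf = 1 - d$eaf,
             beta = -d$beta, se = d$se, pval = d$pval, n = d$n,
             stringsAsFactors = FALSE)
}

write_table1_cohorts <- function(dir) {
  t1 <- load_table1_cohorts()
  disc <- file.path(dir, "disc.tsv")
  repl <- file.path(dir, "repl.tsv")
  write.table(t1$discovery, disc, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(t1$replication, repl, sep = "\t", quote = FALSE, row.names = FALSE)
  list(disc = disc, repl = repl,
       smr = system.file("extdata", "table1_smr.tsv", package = "excluscope"))
}

load_table1_cohorts <- function() {
  t1 <- load_candidate_tables()
  list(tmr = t1$tmr, smr = t1$smr,
       discovery = t1$tmr[t1$tmr$cohort == "GCST90274714", ],
       replication = t1$tmr[t1$tmr$cohort == "FinnGenR10", ])
}
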