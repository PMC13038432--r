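#' Construct an instrument set
#'
#' An instrument set holds, for one gene, the harmonized per-SNP exposure and
#' outcome effects that every MR estimator consumes. Alleles are assumed
#' already aligned so that \code{beta_exp} and \code{beta_out} refer to the
#' same effect allele.
#'
#' @param gene Gene symbol the instruments proxy.
#' @param snps data.frame with columns \code{snp}, \code{beta_exp},
#'   \code{se_exp}, \code{pval_exp}, \code{beta_out}, \code{se_out}.
#' @return An object of class \code{instrument_set}.
#' @export
instrument_set <- function(gene, snps) {
  required <- c("snp", "beta_exp", "se_exp", "pval_exp", "beta_out", "se_out")
  missing <- setdiff(required, names(snps))
  if (length(missing) > 0L)
    stop("instrument_set: missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(snps$snp))
    stop("instrument_set: duplicate snp ids")
  if (any(snps$se_exp <= 0) || any(snps$se_out <= 0))
    stop("instrument_set: all standard errors must be > 0")
  snps <- snps[order(snps$snp), required, drop = FALSE]
  rownames(snps) <- NULL
  snps$f_stat <- (snps$beta_exp / snps$se_exp)^2
  structure(list(gene = gene, snps = snps), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for", x$gene, "-", nrow(x$snps), "SNP(s)\n")
  print(utils::head(x$snps, 10L))
  if (nrow(x$snps) > 10L) cat("...", nrow(x$snps) - 10L, "more\n")
  invisible(x)
}

#' @export
length.instrument_set <- function(x) nrow(x$snps)

VALID_BASES <- c("A", "C", "G", "T")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

check_variant_records <- function(d, what = "records") {
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L)
    stop(what, ": missing columns: ", paste(missing, collapse = ", "))
  if (!"eaf" %in% names(d)) d$eaf <- NA_real_
  d$effect_allele <- toupper(d$effect_allele)
  d$other_allele <- toupper(d$other_allele)
  ok <- d$effect_allele %in% VALID_BASES & d$other_allele %in% VALID_BASES &
    d$effect_allele != d$other_allele & d$se > 0 &
    d$pval > 0 & d$pval <= 1
  attr(d, "rejected") <- d$snp[!ok]
  d[ok, , drop = FALSE]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele for the SNPs shared
#' between the two tables. Outcome records whose alleles are swapped relative
#' to the exposure have their effect sign flipped; allele-mismatched SNPs are
#' dropped; palindromic SNPs (A/T or C/G) are dropped when the exposure EAF is
#' missing or too close to 0.5 to resolve strand.
#'
#' @param exposure,outcome data.frames with columns \code{snp},
#'   \code{effect_allele}, \code{other_allele}, \code{eaf} (optional),
#'   \code{beta}, \code{se}, \code{pval}, \code{n} (optional).
#' @param palindrome_eaf_window Palindromic SNPs with
#'   \code{|eaf - 0.5| <} this window (or missing EAF) are dropped.
#' @param gene Gene label carried into the resulting instrument set.
#' @return An \code{\link{instrument_set}}, ordered by ascending snp id, with a
#'   \code{"dropped"} attribute recording per-SNP rejection reasons.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      gene = "gene") {
  exposure <- check_variant_records(exposure, "exposure")
  outcome <- check_variant_records(outcome, "outcome")
  dropped <- character(0)
  reason <- character(0)
  note <- function(snps, why) {
    dropped <<- c(dropped, snps)
    reason <<- c(reason, rep(why, length(snps)))
  }
  note(attr(exposure, "rejected"), "invalid exposure record")
  note(attr(outcome, "rejected"), "invalid outcome record")

  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L) stop("no shared instruments")
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]

  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swap <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  mismatch <- !(same | swap)
  note(shared[mismatch], "allele mismatch")

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  ambiguous <- pal & (is.na(ex$eaf) | abs(ex$eaf - 0.5) < palindrome_eaf_window)
  note(shared[ambiguous & !mismatch], "palindromic with ambiguous EAF")

  keep <- !(mismatch | ambiguous)
  beta_out <- ifelse(swap, -ou$beta, ou$beta)
  snps <- data.frame(
    snp = shared[keep],
    beta_exp = ex$beta[keep], se_exp = ex$se[keep], pval_exp = ex$pval[keep],
    beta_out = beta_out[keep], se_out = ou$se[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(snps) == 0L) stop("no shared instruments after harmonization")
  out <- instrument_set(gene, snps)
  attr(out, "dropped") <- data.frame(snp = dropped, reason = reason,
                                     stringsAsFactors = FALSE)
  out
}

#' Filter instruments on exposure significance and strength
#'
#' Retains SNPs whose exposure association is genome-wide significant and
#' whose F-statistic \eqn{(\beta_{exp}/se_{exp})^2} meets the weak-instrument
#' cutoff.
#'
#' @param iset An \code{\link{instrument_set}}.
#' @param p_max Exposure p-value threshold (default 5e-8).
#' @param f_min Minimum F-statistic (default 10; weaker instruments excluded).
#' @return A filtered \code{instrument_set}. If no SNP survives, an error of
#'   class \code{"no_valid_instruments"} is signalled so callers can skip the
#'   gene rather than abort.
#' @export
filter_instruments <- function(iset, p_max = 5e-8, f_min = 10) {
  stopifnot(inherits(iset, "instrument_set"))
  s <- iset$snps
  keep <- s$pval_exp < p_max & s$f_stat >= f_min
  if (!any(keep)) {
    stop(structure(
      class = c("no_valid_instruments", "error", "condition"),
      list(message = paste0("no valid instruments for ", iset$gene),
           call = sys.call(-1))
    ))
  }
  instrument_set(iset$gene, s[keep, , drop = FALSE])
}

#' Greedy LD clumping of variant records
#'
#' Orders records by ascending p-value (ties broken by snp id) and keeps each
#' SNP only if its LD \eqn{r^2} with every already-kept SNP is below
#' \code{r2_max}. Deterministic.
#'
#' @param records data.frame with at least \code{snp} and \code{pval} columns.
#' @param ld Symmetric matrix of \eqn{r^2}, dimnames = snp ids, unit diagonal.
#' @param r2_max Exclusion threshold (default 0.001).
#' @return The retained rows of \code{records}, in the greedy keep order.
#' @export
ld_clump <- function(records, ld, r2_max = 0.001) {
  if (is.null(rownames(ld)) || is.null(colnames(ld)))
    stop("ld matrix must carry snp ids as dimnames")
  missing <- setdiff(records$snp, rownames(ld))
  if (length(missing) > 0L)
    stop("missing LD entries for: ", paste(missing, collapse = ", "))
  ord <- order(records$pval, records$snp)
  snps <- records$snp[ord]
  kept <- character(0)
  for (s in snps) {
    if (length(kept) == 0L || all(ld[s, kept] < r2_max)) kept <- c(kept, s)
  }
  records[match(kept, records$snp), , drop = FALSE]
}
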