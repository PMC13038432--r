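#' Two-stage TMR retention filter
#'
#' A gene survives the two-stage transcriptome-wide MR screen when its
#' discovery IVW p is below \code{p_thresh}, its discovery Egger-intercept
#' (pleiotropy) p is above \code{pleio_thresh}, its replication IVW p is below
#' \code{p_thresh}, and the effect direction (sign of log OR) agrees between
#' the two cohorts. Optionally the Cochran's Q heterogeneity p can be required
#' to exceed \code{het_thresh} in the discovery cohort as well.
#'
#' @param discovery,replication data.frames with columns \code{gene},
#'   \code{or}, \code{pval}, \code{pleiotropy_pval} (and
#'   \code{heterogeneity_pval} if \code{het_thresh} is used).
#' @param p_thresh IVW p-value threshold in both cohorts (default 0.05).
#' @param pleio_thresh Pleiotropy p must exceed this (default 0.05).
#' @param het_thresh Optional: require heterogeneity p above this (default
#'   NULL, heterogeneity reported but not filtered on).
#' @return Character vector of retained genes, with a \code{"log"} attribute
#'   recording why each non-retained gene dropped out.
#' @export
two_stage_filter <- function(discovery, replication, p_thresh = 0.05,
                             pleio_thresh = 0.05, het_thresh = NULL) {
  stopifnot(all(c("gene", "or", "pval", "pleiotropy_pval") %in% names(discovery)),
            all(c("gene", "or", "pval") %in% names(replication)))
  log <- character(0)
  kept <- character(0)
  rep_idx <- match(discovery$gene, replication$gene)
  for (i in seq_len(nrow(discovery))) {
    g <- discovery$gene[i]
    j <- rep_idx[i]
    why <- NULL
    if (is.na(j)) why <- "missing in replication"
    else if (!(discovery$pval[i] < p_thresh)) why <- "discovery p >= threshold"
    else if (!(discovery$pleiotropy_pval[i] > pleio_thresh)) why <- "pleiotropy evidence in discovery"
    else if (!is.null(het_thresh) &&
             !(discovery$heterogeneity_pval[i] > het_thresh)) why <- "heterogeneity evidence in discovery"
    else if (!(replication$pval[j] < p_thresh)) why <- "replication p >= threshold"
    else if (sign(log(discovery$or[i])) != sign(log(replication$or[j])))
      why <- "direction flip between cohorts"
    if (is.null(why)) kept <- c(kept, g)
    else log <- c(log, stats::setNames(why, g))
  }
  structure(kept, log = log)
}

#' Classify the risk direction of a candidate gene
#'
#' A gene is \code{risk_increasing} when OR > 1 in both TMR cohorts and
#' b_SMR > 0 in both SMR cohorts; \code{protective} when OR < 1 and
#' b_SMR < 0 throughout; anything else - including boundary values OR = 1 or
#' b_SMR = 0 - is \code{discordant}.
#'
#' @param ors Odds ratios from the two TMR cohorts.
#' @param b_smrs SMR effects from the two SMR cohorts.
#' @return One of "risk_increasing", "protective", "discordant".
#' @export
classify_direction <- function(ors, b_smrs) {
  stopifnot(length(ors) == 2L, length(b_smrs) == 2L,
            all(is.finite(ors)), all(is.finite(b_smrs)), all(ors > 0))
  if (all(ors > 1) && all(b_smrs > 0)) return("risk_increasing")
  if (all(ors < 1) && all(b_smrs < 0)) return("protective")
  "discordant"
}

#' Prioritize robust candidate genes from TMR and SMR evidence
#'
#' The intersection step: a TMR-supported gene is retained when the SMR
#' criterion (p_SMR below \code{p_smr_thresh} and p_HEIDI above
#' \code{p_heidi_thresh}, i.e. consistent with a single shared causal variant)
#' holds in at least one cohort (\code{smr_cohort_rule = "any"}, the default)
#' or in both (\code{"all"}). Each retained gene is classified by
#' \code{\link{classify_direction}} using its two TMR odds ratios and two SMR
#' effects.
#'
#' @param tmr_supported Character vector of TMR-supported genes (the output of
#'   \code{\link{two_stage_filter}}).
#' @param tmr data.frame \code{gene, cohort, or, pval, pleiotropy_pval,
#'   heterogeneity_pval} (two rows per gene).
#' @param smr data.frame \code{gene, cohort, top_snp, b_smr, p_smr, p_heidi}
#'   (two rows per gene). A missing (NA) p_heidi fails the criterion for that
#'   cohort.
#' @param p_smr_thresh,p_heidi_thresh SMR screen thresholds (defaults 0.05).
#' @param smr_cohort_rule "any" or "all".
#' @return data.frame \code{gene, retained, direction, reason}; direction is
#'   NA for genes lacking the full set of four records.
#' @export
prioritize_candidates <- function(tmr_supported, tmr, smr,
                                  p_smr_thresh = 0.05, p_heidi_thresh = 0.05,
                                  smr_cohort_rule = c("any", "all")) {
  smr_cohort_rule <- match.arg(smr_cohort_rule)
  genes <- unique(c(tmr_supported, smr$gene))
  rows <- lapply(genes, function(g) {
    s <- smr[smr$gene == g, , drop = FALSE]
    t <- tmr[tmr$gene == g, , drop = FALSE]
    pass <- !is.na(s$p_smr) & s$p_smr < p_smr_thresh &
      !is.na(s$p_heidi) & s$p_heidi > p_heidi_thresh
    smr_ok <- if (smr_cohort_rule == "any") any(pass) else
      (length(pass) >= 2L && all(pass))
    retained <- g %in% tmr_supported && smr_ok
    reason <- if (!g %in% tmr_supported) "not TMR-supported"
      else if (!smr_ok) "SMR/HEIDI criterion not met"
      else "TMR- and SMR-supported"
    direction <- if (nrow(t) == 2L && nrow(s) == 2L)
      classify_direction(t$or, s$b_smr) else NA_character_
    data.frame(gene = g, retained = retained,
               direction = if (retained) direction else NA_character_,
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$retained, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
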