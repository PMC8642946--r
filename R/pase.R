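#' Allelic expression ratios for variant peptide pairs
#'
#' The allelic expression ratio is log2(B-allele abundance) minus
#' log2(D-allele abundance). The parental ratio rP averages log2(B in B6
#' samples) and subtracts the average log2(D in D2 samples) — each allele
#' measured in its carrier strain — while the F1 ratio rF1 averages the
#' within-sample log2(B) - log2(D) over all F1 samples, where both alleles
#' share one cellular environment. Pairs whose allele is entirely missing
#' in its carrier samples are excluded with a reason.
#'
#' @param pairs `pase_pairs` object (generator output or
#'   [match_identified_peptides()]).
#' @return data.frame with `pair_id`, `r_parent`, `r_f1`, sample counts and
#'   `excluded`/`reason` columns.
#' @export
compute_allelic_ratios <- function(pairs) {
  stopifnot(inherits(pairs, "pase_pairs"))
  md <- pairs$metadata
  geno <- as.character(md$genotype)
  b6 <- geno == "B6"; d2 <- geno == "D2"
  f1 <- geno %in% c("B6D2F1", "D2B6F1")
  lb <- log2(pairs$b_abund); ld <- log2(pairs$d_abund)
  n_b6 <- rowSums(!is.na(lb[, b6, drop = FALSE]))
  n_d2 <- rowSums(!is.na(ld[, d2, drop = FALSE]))
  f1_diff <- lb[, f1, drop = FALSE] - ld[, f1, drop = FALSE]
  n_f1 <- rowSums(!is.na(f1_diff))
  r_parent <- rowMeans(lb[, b6, drop = FALSE], na.rm = TRUE) -
    rowMeans(ld[, d2, drop = FALSE], na.rm = TRUE)
  r_f1 <- rowMeans(f1_diff, na.rm = TRUE)
  excluded <- n_b6 == 0 | n_d2 == 0 | n_f1 == 0
  reason <- ifelse(!excluded, NA_character_,
                   ifelse(n_b6 == 0, "b_allele_missing_in_B6",
                          ifelse(n_d2 == 0, "d_allele_missing_in_D2",
                                 "no_complete_f1_measurement")))
  data.frame(pair_id = rownames(lb),
             r_parent = ifelse(excluded, NA_real_, r_parent),
             r_f1 = ifelse(excluded, NA_real_, r_f1),
             n_b6 = n_b6, n_d2 = n_d2, n_f1 = n_f1,
             excluded = excluded, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Moderated test for protein allele-specific expression
#'
#' Contrasts log2 B-allele vs D-allele abundances across the samples
#' carrying each allele (B: B6 + F1 samples; D: D2 + F1 samples) with the
#' shared empirical-Bayes moderated t engine, BH-adjusted across pairs.
#' Pairs with fewer than 2 samples per allele are flagged untestable.
#'
#' @param pairs `pase_pairs` object.
#' @return data.frame with `pair_id`, `log2fc` (B - D), `t`, `p`, `adj_p`,
#'   `untestable` flag.
#' @export
pase_test <- function(pairs) {
  stopifnot(inherits(pairs, "pase_pairs"))
  geno <- as.character(pairs$metadata$genotype)
  b_cols <- geno %in% c("B6", "B6D2F1", "D2B6F1")
  d_cols <- geno %in% c("D2", "B6D2F1", "D2B6F1")
  lb <- log2(pairs$b_abund[, b_cols, drop = FALSE])
  ld <- log2(pairs$d_abund[, d_cols, drop = FALSE])
  nb <- rowSums(!is.na(lb)); nd <- rowSums(!is.na(ld))
  untestable <- nb < 2 | nd < 2
  # complete-case matrix for the shared moderated engine
  ok <- !untestable & rowSums(is.na(lb)) == 0 & rowSums(is.na(ld)) == 0
  out <- data.frame(pair_id = rownames(pairs$b_abund),
                    log2fc = rowMeans(lb, na.rm = TRUE) -
                      rowMeans(ld, na.rm = TRUE),
                    t = NA_real_, p = NA_real_, adj_p = NA_real_,
                    untestable = untestable,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(ok)) {
    m <- cbind(lb[ok, , drop = FALSE], ld[ok, , drop = FALSE])
    colnames(m) <- c(paste0("B_", seq_len(ncol(lb))),
                     paste0("D_", seq_len(ncol(ld))))
    rownames(m) <- out$pair_id[ok]
    res <- moderated_ttest(m, colnames(m)[seq_len(ncol(lb))],
                           colnames(m)[-seq_len(ncol(lb))])
    out$t[ok] <- res$t
    out$p[ok] <- res$p
    out$adj_p[ok] <- bh_adjust(res$p)
  }
  out
}

#' Classify regulation from parental and F1 allelic ratios
#'
#' Total five-way partition of the (rP, rF1) plane at threshold `tau`
#' (default 1 log2 unit, the printed ratio threshold):
#' both ratios beyond tau with the same sign = cis (the parental imbalance
#' persists in the shared F1 trans environment); parental only = trans;
#' F1 only = compensatory (offsetting cis and trans effects); neither =
#' conserved; both beyond tau with opposite signs = unexpected bias.
#' `mode = "proximity"` replaces the cis rule by |rF1 - rP| < tau (F1
#' tracks the parental ratio), the diagonal-band reading.
#' Optionally gate "change" on per-pair significance.
#'
#' @param r_parent,r_f1 numeric vectors of log2 allelic ratios.
#' @param tau ratio threshold (> 0), log2 units.
#' @param mode `"partition"` (default) or `"proximity"`.
#' @param significant optional logical vector; when supplied, a ratio only
#'   counts as changed if also significant.
#' @return factor with levels cis, trans, compensatory, conserved,
#'   unexpected (NA where a ratio is NA).
#' @export
classify_regulation <- function(r_parent, r_f1, tau = 1,
                                mode = c("partition", "proximity"),
                                significant = NULL) {
  mode <- match.arg(mode)
  if (tau <= 0) stop("tau must be > 0")
  stopifnot(length(r_parent) == length(r_f1))
  p_change <- abs(r_parent) >= tau
  f_change <- abs(r_f1) >= tau
  if (!is.null(significant)) {
    p_change <- p_change & significant
    f_change <- f_change & significant
  }
  same_sign <- sign(r_parent) == sign(r_f1)
  cat <- ifelse(p_change & f_change & same_sign, "cis",
         ifelse(p_change & !f_change, "trans",
         ifelse(!p_change & f_change, "compensatory",
         ifelse(!p_change & !f_change, "conserved", "unexpected"))))
  if (mode == "proximity") {
    tracks <- abs(r_f1 - r_parent) < tau
    cat <- ifelse(p_change & tracks, "cis",
           ifelse(p_change & !f_change, "trans",
           ifelse(!p_change & f_change, "compensatory",
           ifelse(!p_change & !f_change, "conserved", "unexpected"))))
  }
  factor(cat, levels = c("cis", "trans", "compensatory", "conserved",
                         "unexpected"))
}

#' Classify every variant peptide pair and tally the categories
#'
#' @param ratios output of [compute_allelic_ratios()].
#' @param tau,mode,significant passed to [classify_regulation()].
#' @return `ratios` with a `category` column; the category tally is in the
#'   `counts` attribute.
#' @export
classify_pase <- function(ratios, tau = 1, mode = "partition",
                          significant = NULL) {
  ratios$category <- classify_regulation(ratios$r_parent, ratios$r_f1,
                                         tau = tau, mode = mode,
                                         significant = significant)
  attr(ratios, "counts") <- table(ratios$category)
  ratios
}
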