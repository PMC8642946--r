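#' Empirical-Bayes moderated two-sample t-test
#'
#' Per feature, the pooled two-sample variance s^2 with d = n_a + n_b - 2
#' degrees of freedom is shrunk towards a common prior: the prior degrees of
#' freedom d0 and prior variance s0^2 are estimated by moment-matching a
#' scaled inverse chi-square model on the log sample variances
#' (via [limma::squeezeVar()]), giving the posterior variance
#' (d0*s0^2 + d*s^2) / (d0 + d). The moderated t uses the posterior variance
#' with d0 + d degrees of freedom. Setting `d0 = 0` recovers the ordinary
#' pooled t-test; `d0 = Inf` replaces every variance by s0^2 (supplied via
#' `s02` in that case).
#'
#' @param mat [protein_abundance()] object or log2 matrix
#'   (features x samples).
#' @param group_a,group_b disjoint character vectors of sample (column)
#'   names, each of size >= 2.
#' @param d0 optional prior degrees-of-freedom override (0, finite, or Inf).
#' @param s02 prior variance, required when `d0` is given and the data-based
#'   estimate is bypassed (defaults to the moment-matched estimate).
#' @return data.frame with per-feature group means, log2 fold change
#'   (a - b), moderated t, raw and BH-adjusted p-values, posterior variance,
#'   and the prior (d0, s02) used.
#' @export
moderated_ttest <- function(mat, group_a, group_b, d0 = NULL, s02 = NULL) {
  m <- .resolve_matrix(mat)
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs >= 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  ssa <- rowSums((a - mean_a)^2); ssb <- rowSums((b - mean_b)^2)
  df <- na + nb - 2
  s2 <- (ssa + ssb) / df

  if (is.null(d0)) {
    sq <- limma::squeezeVar(s2, df)
    d0 <- sq$df.prior
    s02 <- sq$var.prior
    s2_post <- sq$var.post
  } else {
    if (is.null(s02)) s02 <- limma::squeezeVar(s2, df)$var.prior
    s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
      (d0 * s02 + df * s2) / (d0 + df)
    }
  }
  df_total <- if (is.infinite(d0)) Inf else d0 + df
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- (mean_a - mean_b) / se
  tstat[se == 0] <- 0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(feature = rownames(m), mean_a = mean_a, mean_b = mean_b,
             log2fc = mean_a - mean_b, t = tstat, df_total = df_total,
             p = p, adj_p = bh_adjust(p), s2_post = s2_post,
             d0 = d0, s02 = s02, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in [0, 1]; NA/NaN entries are rejected with
#'   their indices.
#' @return adjusted p-values (capped at 1, step-up monotone over the ranked
#'   list).
#' @export
bh_adjust <- function(pvalues) {
  bad <- which(is.na(pvalues))
  if (length(bad)) {
    stop("NA/NaN p-values at indices: ", paste(bad, collapse = ", "))
  }
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed proteins
#'
#' A feature is differentially expressed iff its BH-adjusted p-value is
#' below `fdr` and |log2 fold change| exceeds `fc_cut`. The defaults are
#' the thresholds of the B6-vs-D2 contrast (adjusted p < 0.05,
#' |log2FC| > 1.5); named presets `"strict"` (4-fold, 1% FDR) and
#' `"lenient"` (2-fold, 5% FDR) match the volcano-plot annotations.
#'
#' @param results output of [moderated_ttest()].
#' @param fc_cut log2 fold-change cut-off.
#' @param fdr adjusted p-value cut-off.
#' @param preset optional `"strict"` or `"lenient"` overriding the cuts.
#' @return `results` with logical `dep` and character `direction`
#'   (`"up_a"`/`"up_b"`/NA) columns.
#' @export
call_deps <- function(results, fc_cut = 1.5, fdr = 0.05, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("strict", "lenient"))
    if (preset == "strict") { fc_cut <- 2; fdr <- 0.01 }
    else { fc_cut <- 1; fdr <- 0.05 }
  }
  results$dep <- results$adj_p < fdr & abs(results$log2fc) > fc_cut
  results$direction <- ifelse(!results$dep, NA_character_,
                              ifelse(results$log2fc > 0, "up_a", "up_b"))
  results
}

#' Coefficient of variation and high-variation flags
#'
#' CV = sd/mean of linear-scale abundance across all samples; a protein is
#' flagged high-variation when its CV exceeds mean(CV) + 2 sd(CV). Proteins
#' with zero mean (CV undefined) are excluded and listed in the `excluded`
#' attribute.
#'
#' @param mat [protein_abundance()] object (absolute log2 values used when
#'   available, else 2^relative) or a linear-scale matrix with
#'   `log2_input = FALSE`.
#' @param log2_input is a plain matrix on the log2 scale?
#' @return data.frame with `protein`, `cv`, `high_variation`.
#' @export
compute_cv <- function(mat, log2_input = TRUE) {
  if (inherits(mat, "protein_abundance")) {
    lin <- 2^(if (!is.null(mat$log2_abs)) mat$log2_abs else mat$log2_rel)
  } else {
    lin <- if (log2_input) 2^as.matrix(mat) else as.matrix(mat)
  }
  if (is.null(rownames(lin))) {
    rownames(lin) <- sprintf("feature%d", seq_len(nrow(lin)))
  }
  mu <- rowMeans(lin)
  excluded <- rownames(lin)[mu == 0]
  keep <- mu != 0
  cv <- apply(lin[keep, , drop = FALSE], 1, stats::sd) / mu[keep]
  thr <- mean(cv) + 2 * stats::sd(cv)
  if (is.na(thr)) thr <- Inf        # a single protein has no CV distribution
  out <- data.frame(protein = rownames(lin)[keep], cv = cv,
                    high_variation = cv > thr,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Call single-parent expression (SPE)
#'
#' The extreme form of differential expression in which one parental strain
#' expresses a protein while the other is effectively silent. Per parental
#' strain, log2 abundances (replicate means) are z-scored across proteins;
#' a protein is SPE when one parent's z-score lies above that strain's
#' `high_pct` percentile cut-off while the other parent's z-score lies
#' below its `low_pct` percentile cut-off.
#'
#' @param mat [protein_abundance()] object or log2 matrix.
#' @param metadata sample sheet (needed when `mat` is a plain matrix).
#' @param high_pct,low_pct percentile cut-offs (defaults 25 and 5).
#' @param proteins optional subset of protein ids to screen (e.g. autosomal
#'   differentially expressed proteins); percentiles are still computed on
#'   all proteins.
#' @return data.frame with per-strain z-scores, `spe` flag and
#'   `silent_parent` label.
#' @export
call_spe <- function(mat, metadata = NULL, high_pct = 25, low_pct = 5,
                     proteins = NULL) {
  if (inherits(mat, "protein_abundance")) {
    metadata <- mat$metadata
    m <- if (!is.null(mat$log2_abs)) mat$log2_abs else mat$log2_rel
  } else m <- as.matrix(mat)
  if (is.null(metadata)) stop("sample metadata required")
  if (nrow(m) < 20) warning("fewer than 20 proteins: percentiles unstable")
  z_of <- function(strain) {
    cols <- metadata$sample[metadata$genotype == strain]
    x <- rowMeans(m[, cols, drop = FALSE])
    (x - mean(x)) / stats::sd(x)
  }
  z_b6 <- z_of("B6"); z_d2 <- z_of("D2")
  hi_b6 <- stats::quantile(z_b6, high_pct / 100)
  lo_b6 <- stats::quantile(z_b6, low_pct / 100)
  hi_d2 <- stats::quantile(z_d2, high_pct / 100)
  lo_d2 <- stats::quantile(z_d2, low_pct / 100)
  d2_silent <- z_b6 > hi_b6 & z_d2 < lo_d2
  b6_silent <- z_d2 > hi_d2 & z_b6 < lo_b6
  out <- data.frame(protein = rownames(m), z_b6 = z_b6, z_d2 = z_d2,
                    spe = d2_silent | b6_silent,
                    silent_parent = ifelse(d2_silent, "D2",
                                           ifelse(b6_silent, "B6",
                                                  NA_character_)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(proteins)) {
    out$spe <- out$spe & out$protein %in% proteins
    out$silent_parent[!out$spe] <- NA_character_
  }
  out
}

#' Reciprocal-hybrid comparison (imprinting-candidate screen)
#'
#' Moderated test of B6D2F1 vs D2B6F1; candidates satisfy raw p < `p_cut`
#' and |log2FC| > `fc_cut` (defaults 0.01 and 0.3). Because the reciprocal
#' F1s are autosomally identical, expression differences point to
#' parent-of-origin effects.
#'
#' @param mat [protein_abundance()] object or log2 matrix.
#' @param metadata sample sheet (when `mat` is a plain matrix).
#' @param p_cut,fc_cut thresholds.
#' @return test results with `candidate` flag and `direction`
#'   (`"maternal_B6_higher"` / `"maternal_D2_higher"`).
#' @export
compare_reciprocal_hybrids <- function(mat, metadata = NULL, p_cut = 0.01,
                                       fc_cut = 0.3) {
  if (inherits(mat, "protein_abundance")) metadata <- mat$metadata
  if (is.null(metadata)) stop("sample metadata required")
  f1a <- metadata$sample[metadata$genotype == "B6D2F1"]
  f1b <- metadata$sample[metadata$genotype == "D2B6F1"]
  if (!length(f1a) || !length(f1b)) stop("both F1 genotypes must be present")
  res <- moderated_ttest(mat, f1a, f1b)
  res$candidate <- res$p < p_cut & abs(res$log2fc) > fc_cut
  res$direction <- ifelse(!res$candidate, NA_character_,
                          ifelse(res$log2fc > 0, "maternal_B6_higher",
                                 "maternal_D2_higher"))
  res
}

#' Power simulation for the differential-expression screen
#'
#' For each effect size, simulates `n_reps` experiments of `n_features`
#' Normal(0, sd^2) features with a planted log2 shift in the non-null
#' fraction, runs the moderated test with BH control at `alpha`, and
#' reports the mean detected fraction of planted features (power) together
#' with the observed false-discovery proportion.
#'
#' @param n_per_group samples per group (>= 2).
#' @param effect_sizes log2 effect sizes to scan.
#' @param n_features features per simulated experiment.
#' @param frac_nonnull planted non-null fraction.
#' @param n_reps replicate experiments per effect size.
#' @param alpha BH FDR level.
#' @param sd residual SD of the simulated log2 data.
#' @param seed integer seed.
#' @return data.frame with `effect`, `power`, `fdp`.
#' @export
simulate_power <- function(n_per_group = 2,
                           effect_sizes = c(0, 0.5, 1, 1.5, 2, 3),
                           n_features = 1000, frac_nonnull = 0.1,
                           n_reps = 5, alpha = 0.05, sd = 0.5, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  set.seed(seed)
  n_true <- round(frac_nonnull * n_features)
  cols <- c(paste0("A", seq_len(n_per_group)), paste0("B", seq_len(n_per_group)))
  ga <- cols[seq_len(n_per_group)]; gb <- setdiff(cols, ga)
  one_rep <- function(effect) {
    m <- matrix(stats::rnorm(n_features * 2 * n_per_group, 0, sd),
                n_features, dimnames = list(sprintf("F%05d", seq_len(n_features)),
                                            cols))
    m[seq_len(n_true), ga] <- m[seq_len(n_true), ga] + effect
    res <- moderated_ttest(m, ga, gb)
    hit <- res$adj_p < alpha
    c(power = mean(hit[seq_len(n_true)]),
      fdp = if (any(hit)) mean(!seq_len(n_features)[hit] %in% seq_len(n_true))
            else 0)
  }
  rows <- lapply(effect_sizes, function(e) {
    reps <- vapply(seq_len(n_reps), function(i) one_rep(e), c(power = 0, fdp = 0))
    data.frame(effect = e, power = mean(reps["power", ]),
               fdp = mean(reps["fdp", ]))
  })
  do.call(rbind, rows)
}
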