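#' Study design for a two-parent reciprocal-F1 TMT experiment
#'
#' Builds the sample sheet for the four-genotype design: the two parental
#' inbred strains (B6, D2) and their reciprocal F1 hybrids (B6D2F1, D2B6F1),
#' each represented by both sexes. One animal per genotype x sex cell gives
#' the 8-sample, single-plex layout used throughout (an 11-plex TMT batch
#' holds it comfortably).
#'
#' @param n_rep animals per genotype x sex cell (default 1, i.e. n = 2
#'   biological replicates per genotype with sex as the replicate axis).
#' @param genotypes genotype labels, in canonical order.
#' @return data.frame with columns `sample`, `genotype`, `sex`, `replicate`,
#'   `channel`; genotype is a factor with the canonical level order.
#' @export
strain_design <- function(n_rep = 1,
                          genotypes = c("B6", "D2", "B6D2F1", "D2B6F1")) {
  stopifnot(length(genotypes) == 4L, n_rep >= 1L)
  grid <- expand.grid(replicate = seq_len(n_rep), sex = c("F", "M"),
                      genotype = genotypes, stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "sex", "replicate")]
  design <- data.frame(
    sample   = sprintf("%s_%s%d", grid$genotype, grid$sex, grid$replicate),
    genotype = factor(grid$genotype, levels = genotypes),
    sex      = grid$sex,
    replicate = grid$replicate,
    channel  = seq_len(nrow(grid)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(design$channel)) stop("channel indices must be unique")
  design
}

#' Simulation parameters for the proteome generator
#'
#' All effect scales are on the log2 abundance scale. PSM-level reporter
#' intensities are linear-scale lognormal draws around the protein level,
#' distorted by per-channel loading-bias multipliers and mixed by the
#' isotope-impurity matrix, mirroring how raw TMT reporter data arise.
#'
#' @param n_proteins number of proteins to simulate.
#' @param sigma_a additive effect scale (SD of per-protein additive effect).
#' @param sigma_d dominance effect scale.
#' @param sigma_s sex effect scale.
#' @param sigma_e residual (within-genotype) SD.
#' @param frac_null fraction of proteins with no genetic or sex effect.
#' @param base_log2,base_sd mean and SD of per-protein baseline log2 level.
#' @param mean_extra_psms PSM count per protein is 1 + Poisson(mean_extra_psms).
#' @param psm_cv coefficient of variation of multiplicative lognormal PSM
#'   channel noise (0 = noise-free reporter intensities).
#' @param loading_bias per-channel multiplicative loading bias (> 0), or NULL
#'   for a fixed +-20% spread across channels.
#' @param impurity isotope impurity matrix (channels x channels; entry (i, j)
#'   is the fraction of channel j's signal read in channel i), or NULL for
#'   identity. Column sums must be <= 1 + 1e-6.
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @return validated parameter list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 500, sigma_a = 1, sigma_d = 0.5,
                       sigma_s = 0.2, sigma_e = 0.5, frac_null = 0.3,
                       base_log2 = 16, base_sd = 1.5,
                       mean_extra_psms = 3, psm_cv = 0.1,
                       loading_bias = NULL, impurity = NULL, seed = 1L) {
  if (n_proteins <= 0) stop("n_proteins must be positive")
  scales <- c(sigma_a = sigma_a, sigma_d = sigma_d, sigma_s = sigma_s,
              sigma_e = sigma_e, psm_cv = psm_cv, base_sd = base_sd)
  if (any(scales < 0)) stop("all scale parameters must be >= 0")
  if (frac_null < 0 || frac_null > 1) stop("frac_null must be in [0, 1]")
  if (!is.null(loading_bias) && any(loading_bias <= 0)) {
    stop("loading_bias multipliers must be > 0")
  }
  if (!is.null(impurity)) {
    impurity <- as.matrix(impurity)
    if (nrow(impurity) != ncol(impurity)) stop("impurity matrix must be square")
    if (any(impurity < 0)) stop("impurity entries must be non-negative")
    if (any(colSums(impurity) > 1 + 1e-6)) {
      stop("impurity column sums must be <= 1 (+ tolerance)")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins), sigma_a = sigma_a,
                 sigma_d = sigma_d, sigma_s = sigma_s, sigma_e = sigma_e,
                 frac_null = frac_null, base_log2 = base_log2,
                 base_sd = base_sd, mean_extra_psms = mean_extra_psms,
                 psm_cv = psm_cv, loading_bias = loading_bias,
                 impurity = impurity, seed = as.integer(seed)),
            class = "sim_params")
}

# genotype score vectors of the cross-mean parameterisation:
# additive g = +1 (B6), -1 (D2), 0 (F1s); dominance h = 1 for F1s.
.genotype_scores <- function(genotype) {
  g <- c(B6 = 1, D2 = -1, B6D2F1 = 0, D2B6F1 = 0)[as.character(genotype)]
  h <- c(B6 = 0, D2 = 0, B6D2F1 = 1, D2B6F1 = 1)[as.character(genotype)]
  list(g = unname(g), h = unname(h))
}

#' Simulate a TMT proteome for the four-genotype design
#'
#' Per protein, genotype means follow mu + a*g + d*h with additive scores
#' g = +1 (B6), -1 (D2), 0 (F1) and dominance scores h = 0 (parents),
#' 1 (F1s); sample values add a sex effect (0/1 coding, males shifted) and
#' Normal(0, sigma_e^2) residual noise on the log2 scale. PSM reporter
#' intensities are linear-scale lognormal draws around each protein's
#' per-sample level, multiplied by the channel loading bias and mixed by the
#' impurity matrix.
#'
#' `additive_model = "pedigree"` instead draws the genotype-level additive
#' and dominance effects from N(0, sigma_a^2 R1) and N(0, sigma_d^2 R2),
#' the exact generative model assumed by the REML variance-component
#' estimator (see [build_relatedness_matrices()]); use it for parameter-
#' recovery studies of that estimator.
#'
#' @param design sample sheet from [strain_design()].
#' @param params parameters from [sim_params()].
#' @param additive_model `"cross"` (genotype means mu + a*g + d*h; default)
#'   or `"pedigree"` (effects drawn from the relatedness-matrix model).
#' @return list with `psms` (PSM table; see [as_psm_table()]), `abundance`
#'   (true protein x sample log2 matrix wrapped with sample metadata), and
#'   `truth` (per-protein effects and true broad-sense heritability).
#' @export
simulate_proteome <- function(design, params,
                              additive_model = c("cross", "pedigree")) {
  additive_model <- match.arg(additive_model)
  stopifnot(inherits(params, "sim_params"))
  if (!all(c("B6", "D2", "B6D2F1", "D2B6F1") %in% design$genotype)) {
    stop("design must contain all four genotypes")
  }
  n <- nrow(design)
  p <- params$n_proteins
  if (!is.null(params$impurity) && nrow(params$impurity) != n) {
    stop("impurity matrix dimension does not match channel count")
  }
  set.seed(params$seed)

  null_protein <- seq_len(p) <= round(params$frac_null * p)
  null_protein <- sample(null_protein)           # shuffle null positions
  a <- stats::rnorm(p, 0, params$sigma_a) * !null_protein
  d <- stats::rnorm(p, 0, params$sigma_d) * !null_protein
  s <- stats::rnorm(p, 0, params$sigma_s) * !null_protein
  mu <- stats::rnorm(p, params$base_log2, params$base_sd)

  sex01 <- as.numeric(design$sex == "M")
  sc <- .genotype_scores(design$genotype)
  if (additive_model == "cross") {
    genetic <- outer(a, sc$g) + outer(d, sc$h)
    # realised genetic variance of each protein across the sample population
    va_true <- a^2 * stats::var(sc$g) * (n - 1) / n
    vd_true <- d^2 * stats::var(sc$h) * (n - 1) / n
  } else {
    R <- build_relatedness_matrices(design)
    ca <- chol(R$R1 + diag(1e-8, n))
    cd <- chol(R$R2 + diag(1e-8, n))
    A <- (matrix(stats::rnorm(p * n), p, n) %*% ca) * params$sigma_a *
      !null_protein
    D <- (matrix(stats::rnorm(p * n), p, n) %*% cd) * params$sigma_d *
      !null_protein
    genetic <- A + D
    va_true <- rep(params$sigma_a^2, p) * !null_protein
    vd_true <- rep(params$sigma_d^2, p) * !null_protein
    a[] <- NA_real_   # per-genotype effects replace the scalar cross effects
    d[] <- NA_real_
  }
  vs_true <- s^2 * stats::var(sex01) * (n - 1) / n
  vg <- va_true + vd_true
  vtot <- vg + vs_true + params$sigma_e^2
  h2_true <- ifelse(vtot > 0, vg / vtot, 0)

  y <- mu + genetic + outer(s, sex01) +
    matrix(stats::rnorm(p * n, 0, params$sigma_e), p, n)
  proteins <- sprintf("PROT%05d", seq_len(p))
  dimnames(y) <- list(proteins, design$sample)

  truth <- data.frame(protein = proteins, is_null = null_protein,
                      a = a, d = d, sex_effect = s,
                      va_true = va_true, vd_true = vd_true,
                      vs_true = vs_true, h2_true = h2_true,
                      stringsAsFactors = FALSE)

  # PSM layer: linear-scale intensities around 2^y with multiplicative noise
  n_psm <- 1L + stats::rpois(p, params$mean_extra_psms)
  prot_idx <- rep.int(seq_len(p), n_psm)
  total_psm <- length(prot_idx)
  eff <- 2^stats::rnorm(total_psm, 0, 0.5)     # per-PSM ionisation efficiency
  noise_sd <- sqrt(log(1 + params$psm_cv^2))
  lin <- 2^y[prot_idx, , drop = FALSE] * eff *
    exp(matrix(stats::rnorm(total_psm * n, 0, noise_sd), total_psm, n))
  bias <- params$loading_bias
  if (is.null(bias)) bias <- 2^seq(-0.3, 0.3, length.out = n)
  if (length(bias) != n) stop("loading_bias length must equal channel count")
  lin <- sweep(lin, 2, bias, `*`)
  if (!is.null(params$impurity)) lin <- t(params$impurity %*% t(lin))

  peptides <- vapply(seq_len(total_psm), function(i) {
    paste0(paste(sample(setdiff(LETTERS, c("B", "J", "K", "O", "P", "R",
                                           "U", "X", "Z")),
                        7 + i %% 6, replace = TRUE), collapse = ""),
           c("K", "R")[1 + i %% 2])
  }, character(1))
  psms <- data.frame(psm_id = sprintf("PSM%06d", seq_len(total_psm)),
                     peptide = peptides,
                     protein = proteins[prot_idx],
                     stringsAsFactors = FALSE)
  psms <- cbind(psms, as.data.frame(lin))
  names(psms)[-(1:3)] <- design$sample
  psms <- as_psm_table(psms, channels = design$sample)

  abundance <- protein_abundance(log2_rel = sweep(y, 1, rowMeans(y)),
                                 abs_intensity = stats::setNames(2^mu, proteins),
                                 metadata = design, log2_abs = y)
  list(psms = psms, abundance = abundance, truth = truth)
}

.pair_categories <- c("cis", "trans", "compensatory", "conserved", "unexpected")

.category_ratios <- function(category, effect, sign) {
  rp <- switch(category,
               cis = sign * effect, trans = sign * effect,
               compensatory = 0, conserved = 0, unexpected = sign * effect)
  rf1 <- switch(category,
                cis = sign * effect, trans = 0,
                compensatory = sign * effect, conserved = 0,
                unexpected = -sign * effect)
  c(rp = rp, rf1 = rf1)
}

# residues that can never create or destroy a tryptic cleavage site
.safe_aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "Q",
              "S", "T", "V", "W", "Y")

#' Simulate allele-distinguishing variant peptide pairs
#'
#' Each pair carries a B-allele (reference) and a D-allele (substituted)
#' tryptic peptide sequence and linear-scale per-sample abundances under a
#' planted regulatory category: cis pairs have equal parental and F1 log2
#' allelic ratios (+-effect, same sign), trans pairs have the parental ratio
#' only, compensatory pairs the F1 ratio only, conserved pairs neither, and
#' unexpected-bias pairs opposite signs. The B-allele peptide is missing
#' (NA) in D2 animals and the D-allele peptide missing in B6 animals, as
#' each parent carries only its own allele.
#'
#' @param design sample sheet from [strain_design()].
#' @param n_pairs number of peptide pairs.
#' @param category_mix named proportions over
#'   `c("cis","trans","compensatory","conserved","unexpected")`; must sum
#'   to 1.
#' @param effect planted log2 allelic-ratio magnitude (> 0).
#' @param noise_sd per-sample log2 measurement noise SD (0 = noise-free).
#' @param seed integer seed.
#' @return list with `pairs` (an object of class `pase_pairs`: pair table
#'   plus B/D abundance matrices), `truth` (planted category and ratios),
#'   and `proteome` (a synthetic reference FASTA as a named character
#'   vector, plus the missense variant table realising the pairs).
#' @export
simulate_variant_peptides <- function(design, n_pairs = 500,
                                      category_mix = c(cis = 0.2, trans = 0.2,
                                                       compensatory = 0.2,
                                                       conserved = 0.2,
                                                       unexpected = 0.2),
                                      effect = 2, noise_sd = 0.25, seed = 1L) {
  if (n_pairs < 0) stop("n_pairs must be non-negative")
  if (effect <= 0) stop("effect must be > 0")
  if (any(category_mix < 0) || any(category_mix > 1)) {
    stop("category proportions must lie in [0, 1]")
  }
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category proportions must sum to 1")
  }
  miss <- setdiff(names(category_mix), .pair_categories)
  if (length(miss)) stop("unknown categories: ", paste(miss, collapse = ", "))
  set.seed(seed)

  counts <- round(category_mix * n_pairs)
  while (sum(counts) != n_pairs) {   # fix rounding drift on the largest class
    i <- which.max(counts)
    counts[i] <- counts[i] + sign(n_pairs - sum(counts))
  }
  category <- sample(rep(names(counts), counts))
  sgn <- sample(c(-1, 1), n_pairs, replace = TRUE)

  # peptide sequences: internal residues avoid K/R/P so substitution can
  # never change the cleavage pattern; C-terminal K/R makes them tryptic
  pep_len <- sample(8:14, n_pairs, replace = TRUE)
  b_pep <- d_pep <- character(n_pairs)
  var_pos <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    core <- sample(.safe_aa, pep_len[i] - 1L, replace = TRUE)
    var_pos[i] <- sample(seq_len(pep_len[i] - 1L), 1L)
    alt <- sample(setdiff(.safe_aa, core[var_pos[i]]), 1L)
    b_pep[i] <- paste0(paste(core, collapse = ""), sample(c("K", "R"), 1L))
    core[var_pos[i]] <- alt
    d_pep[i] <- paste0(paste(core, collapse = ""), sample(c("K", "R"), 1L))
    substr(d_pep[i], pep_len[i], pep_len[i]) <- substr(b_pep[i], pep_len[i],
                                                       pep_len[i])
  }

  ratios <- t(vapply(seq_len(n_pairs),
                     function(i) .category_ratios(category[i], effect, sgn[i]),
                     c(rp = 0, rf1 = 0)))
  geno <- as.character(design$genotype)
  is_f1 <- geno %in% c("B6D2F1", "D2B6F1")
  n <- nrow(design)
  c0 <- stats::rnorm(n_pairs, 14, 1)
  b_log2 <- d_log2 <- matrix(NA_real_, n_pairs, n,
                             dimnames = list(sprintf("PAIR%04d", seq_len(n_pairs)),
                                             design$sample))
  for (j in seq_len(n)) {
    if (geno[j] == "B6") {
      b_log2[, j] <- c0 + ratios[, "rp"] / 2
    } else if (geno[j] == "D2") {
      d_log2[, j] <- c0 - ratios[, "rp"] / 2
    } else {
      b_log2[, j] <- c0 - 1 + ratios[, "rf1"] / 2
      d_log2[, j] <- c0 - 1 - ratios[, "rf1"] / 2
    }
  }
  if (noise_sd > 0) {
    b_log2 <- b_log2 + matrix(stats::rnorm(n_pairs * n, 0, noise_sd), n_pairs, n)
    d_log2 <- d_log2 + matrix(stats::rnorm(n_pairs * n, 0, noise_sd), n_pairs, n)
  }

  pair_id <- rownames(b_log2)
  # synthetic reference proteome realising each B peptide as a tryptic product
  pad1 <- vapply(seq_len(n_pairs), function(i) {
    paste0("M", paste(sample(.safe_aa, 6, replace = TRUE), collapse = ""), "R")
  }, character(1))
  pad2 <- vapply(seq_len(n_pairs), function(i) {
    paste(sample(.safe_aa, 5, replace = TRUE), collapse = "")
  }, character(1))
  accession <- sprintf("SYN%04d", seq_len(n_pairs))
  reference <- stats::setNames(paste0(pad1, b_pep, pad2), accession)
  variants <- data.frame(
    gene = sprintf("GENE%05d", seq_len(n_pairs)),
    accession = accession,
    position = nchar(pad1) + var_pos,
    ref = substr(b_pep, var_pos, var_pos),
    alt = substr(d_pep, var_pos, var_pos),
    stringsAsFactors = FALSE
  )

  pair_table <- data.frame(pair_id = pair_id, accession = accession,
                           b_peptide = b_pep, d_peptide = d_pep,
                           variant_pos = var_pos, stringsAsFactors = FALSE)
  pairs <- structure(list(pairs = pair_table, b_abund = 2^b_log2,
                          d_abund = 2^d_log2, metadata = design),
                     class = "pase_pairs")
  truth <- data.frame(pair_id = pair_id, category = category,
                      rp_true = ratios[, "rp"], rf1_true = ratios[, "rf1"],
                      stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth,
       proteome = list(reference = reference, variants = variants))
}

#' Simulate hybrid allele read counts and parental expression levels
#'
#' Per gene, hybrid B-allele counts are drawn Binomial(n_g, p_g) with
#' p_g = 2^r / (1 + 2^r) for the planted F1 log2 allelic ratio r and a
#' Poisson(depth) per-sample total; parental expression levels encode the
#' planted parental log2 ratio.
#'
#' @param n_genes number of genes.
#' @param depth mean reads per gene per hybrid sample (>= 1).
#' @param category_mix,effect,seed as in [simulate_variant_peptides()].
#' @param n_hybrid_samples number of F1 samples with allele counts.
#' @param noise_sd log2 noise SD on parental expression levels.
#' @return list with `counts` (gene x hybrid sample B/D read counts, long
#'   format), `parental` (per-gene linear-scale B6 and D2 expression), and
#'   `truth` (planted category and ratios).
#' @export
simulate_allele_counts <- function(n_genes = 1000, depth = 100,
                                   category_mix = c(cis = 0.2, trans = 0.2,
                                                    compensatory = 0.2,
                                                    conserved = 0.2,
                                                    unexpected = 0.2),
                                   effect = 2, n_hybrid_samples = 4,
                                   noise_sd = 0.1, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  if (n_genes <= 0) stop("n_genes must be positive")
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category proportions must sum to 1")
  }
  set.seed(seed)
  counts_per <- round(category_mix * n_genes)
  while (sum(counts_per) != n_genes) {
    i <- which.max(counts_per)
    counts_per[i] <- counts_per[i] + sign(n_genes - sum(counts_per))
  }
  category <- sample(rep(names(counts_per), counts_per))
  sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
  ratios <- t(vapply(seq_len(n_genes),
                     function(i) .category_ratios(category[i], effect, sgn[i]),
                     c(rp = 0, rf1 = 0)))
  gene <- sprintf("GENE%05d", seq_len(n_genes))

  p_g <- 2^ratios[, "rf1"] / (1 + 2^ratios[, "rf1"])
  counts <- do.call(rbind, lapply(seq_len(n_hybrid_samples), function(j) {
    total <- stats::rpois(n_genes, depth)
    b <- stats::rbinom(n_genes, total, p_g)
    data.frame(gene = gene, sample = sprintf("F1_%d", j),
               b_count = b, d_count = total - b, stringsAsFactors = FALSE)
  }))
  base <- stats::rnorm(n_genes, 10, 1)
  parental <- data.frame(
    gene = gene,
    b6_expr = 2^(base + ratios[, "rp"] / 2 + stats::rnorm(n_genes, 0, noise_sd)),
    d2_expr = 2^(base - ratios[, "rp"] / 2 + stats::rnorm(n_genes, 0, noise_sd)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(gene = gene, category = category,
                      rp_true = ratios[, "rp"], rf1_true = ratios[, "rf1"],
                      stringsAsFactors = FALSE)
  list(counts = counts, parental = parental, truth = truth)
}
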