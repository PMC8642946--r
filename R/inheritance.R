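#' Pedigree-expected additive and dominance relatedness matrices
#'
#' For the two-parent reciprocal-F1 design, the strain-level 4x4 matrices
#' (genotype order B6, D2, B6D2F1, D2B6F1) are the pedigree expectations:
#' the additive matrix R1 has unrelated parents (0), parent-F1 and F1-F1
#' relatedness 0.5 and unit diagonal; the dominance matrix R2 is zero off
#' the diagonal except for the F1-F1 entry of 0.25. When a sample sheet is
#' given, the matrices are expanded to sample level with same-genotype
#' animal pairs set to 1 in both matrices (inbred and F1 animals of a
#' genotype are isogenic).
#'
#' @param design optional sample sheet from [strain_design()].
#' @return list with `R1_strain`, `R2_strain` (4x4) and, when `design` is
#'   given, sample-level `R1`, `R2`.
#' @export
build_relatedness_matrices <- function(design = NULL) {
  genotypes <- c("B6", "D2", "B6D2F1", "D2B6F1")
  R1s <- matrix(c(1,   0,   0.5, 0.5,
                  0,   1,   0.5, 0.5,
                  0.5, 0.5, 1,   0.5,
                  0.5, 0.5, 0.5, 1), 4, 4, byrow = TRUE,
                dimnames = list(genotypes, genotypes))
  R2s <- matrix(c(1, 0, 0,    0,
                  0, 1, 0,    0,
                  0, 0, 1,    0.25,
                  0, 0, 0.25, 1), 4, 4, byrow = TRUE,
                dimnames = list(genotypes, genotypes))
  out <- list(R1_strain = R1s, R2_strain = R2s)
  if (!is.null(design)) {
    g <- as.character(design$genotype)
    unknown <- setdiff(g, genotypes)
    if (length(unknown)) {
      stop("unknown genotype label(s): ", paste(unique(unknown), collapse = ", "))
    }
    expand <- function(Rs) {
      R <- Rs[g, g]
      same <- outer(g, g, `==`)
      R[same] <- 1            # isogenic animals share all genetic effects
      dimnames(R) <- list(design$sample, design$sample)
      R
    }
    out$R1 <- expand(R1s)
    out$R2 <- expand(R2s)
  }
  out
}

#' Dominance-to-additivity ratio
#'
#' D/A = [mean(F1s) - mid-parent] / [max(B6, D2) - mid-parent]. The
#' denominator (additivity) is half the absolute parental difference and is
#' always positive when the parents differ; 0 marks purely additive
#' inheritance, +-1 complete dominance, and |D/A| > 1 over/under-dominance.
#' Pairs of equal parents (within `tol`) are flagged undefined and excluded
#' from downstream D/A distributions. The class boundaries (additive
#' |D/A| <= 0.25, dominant <= 1.25, over/under-dominant beyond) are a
#' labelling convention for the continuous ratio.
#'
#' @param b6_mean,d2_mean parental genotype means (log2), vectorised.
#' @param f1_mean mean of the two F1 genotype means (or a 2-column matrix
#'   of the per-genotype means).
#' @param tol equal-parent tolerance.
#' @return data.frame with `additivity`, `dominance`, `da_ratio`, `class`
#'   and `undefined` flag.
#' @export
dominance_additivity_ratio <- function(b6_mean, d2_mean, f1_mean,
                                       tol = 1e-12) {
  if (is.matrix(f1_mean)) f1_mean <- rowMeans(f1_mean)
  mid <- (b6_mean + d2_mean) / 2
  additivity <- pmax(b6_mean, d2_mean) - mid
  dominance <- f1_mean - mid
  undefined <- abs(b6_mean - d2_mean) <= tol
  da <- ifelse(undefined, NA_real_, dominance / additivity)
  cls <- ifelse(is.na(da), NA_character_,
                ifelse(abs(da) <= 0.25, "additive",
                       ifelse(abs(da) <= 1.25, "dominant",
                              "over_under_dominant")))
  data.frame(additivity = additivity, dominance = dominance, da_ratio = da,
             class = cls, undefined = undefined, stringsAsFactors = FALSE)
}

# restricted log-likelihood of y ~ X beta + N(0, V); V given by components
.reml_ll <- function(theta, y, X, R1, R2, Ssex = NULL) {
  v <- exp(theta)
  n <- length(y)
  V <- v[1] * R1 + v[2] * R2 + v[length(v)] * diag(n)
  if (!is.null(Ssex)) V <- V + v[3] * Ssex
  diag(V) <- diag(V) + 1e-8 * mean(diag(V))     # rank-deficiency ridge
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    diag(V) <- diag(V) + 1e-4 * mean(diag(V))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
  }
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(-1e10)
  beta <- backsolve(chX, forwardsolve(t(chX), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  as.numeric(-0.5 * (logdetV + 2 * sum(log(diag(chX))) + crossprod(r, Vi_r)))
}

.reml_beta <- function(theta, y, X, R1, R2, Ssex = NULL) {
  v <- exp(theta)
  n <- length(y)
  V <- v[1] * R1 + v[2] * R2 + v[length(v)] * diag(n)
  if (!is.null(Ssex)) V <- V + v[3] * Ssex
  diag(V) <- diag(V) + 1e-8 * mean(diag(V))
  Vi <- solve(V)
  solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
}

#' REML variance components and broad-sense heritability for one protein
#'
#' Fits y = mu + A + D + S + e with random additive effect
#' A ~ N(0, sigma_a^2 R1), random dominance effect D ~ N(0, sigma_d^2 R2),
#' sex S as a fixed effect and residual e ~ N(0, sigma_e^2 I), maximising
#' the restricted likelihood by Nelder-Mead search over log-variances from
#' three fixed starting points. The sex variance Vs is the population
#' variance across samples of the fitted sex term (beta^2/4 for a balanced
#' 0/1-coded design), the only reading under which the printed H^2 with a
#' fixed sex effect is computable; `sex = "random"` instead adds a
#' same-sex covariance component and reports its REML estimate as Vs.
#'
#' @param y numeric vector of per-sample log2 abundances (>= 6 samples).
#' @param design sample sheet aligned with `y`.
#' @param matrices output of [build_relatedness_matrices()] for `design`
#'   (built on the fly when NULL).
#' @param sex `"fixed"` (default) or `"random"`.
#' @param reltol convergence tolerance on the restricted log-likelihood.
#' @return one-row data.frame with Va, Vd, Vs, Ve, H2, loglik (restricted
#'   log-likelihood, reported on the variance-standardised scale the
#'   optimiser works on) and convergence/boundary/degenerate flags.
#' @export
estimate_variance_components <- function(y, design, matrices = NULL,
                                         sex = c("fixed", "random"),
                                         reltol = 1e-8) {
  sex <- match.arg(sex)
  n <- length(y)
  if (n < 6) stop("need >= 6 samples for variance estimation")
  if (n != nrow(design)) stop("y and design lengths differ")
  if (is.null(matrices)) matrices <- build_relatedness_matrices(design)
  R1 <- matrices$R1; R2 <- matrices$R2
  vy <- stats::var(y)
  if (vy < 1e-14) {
    return(data.frame(va = 0, vd = 0, vs = 0, ve = 0, h2 = 0,
                      loglik = NA_real_, converged = TRUE, boundary = TRUE,
                      degenerate = TRUE))
  }
  # fit on variance-standardised data so the estimator is exactly
  # scale-equivariant (components scale back by var(y))
  y_std <- y / sqrt(vy)
  sex01 <- as.numeric(design$sex == "M")
  if (sex == "fixed") {
    X <- cbind(1, sex01)
    Ssex <- NULL
    k <- 3L
  } else {
    X <- matrix(1, n, 1)
    Ssex <- outer(sex01, sex01, `==`) * 1
    k <- 4L
  }
  starts <- list(log(rep(1 / k, k)),
                 log(c(0.8, rep(0.05, k - 2), 0.1)),
                 log(c(0.05, rep(0.05, k - 2), 0.85)))
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, .reml_ll, y = y_std, X = X, R1 = R1, R2 = R2,
                        Ssex = Ssex, method = "Nelder-Mead",
                        control = list(fnscale = -1, reltol = reltol,
                                       maxit = 500))
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  v <- exp(best$par) * vy
  if (sex == "fixed") {
    beta <- .reml_beta(best$par, y_std, X, R1, R2) * sqrt(vy)
    sfit <- sex01 * beta[2]
    vs <- mean((sfit - mean(sfit))^2)
    va <- v[1]; vd <- v[2]; ve <- v[3]
  } else {
    va <- v[1]; vd <- v[2]; vs <- v[3]; ve <- v[4]
  }
  floor_tol <- 1e-6 * vy
  boundary <- any(c(va, vd, ve) < floor_tol)
  va <- ifelse(va < floor_tol, 0, va)
  vd <- ifelse(vd < floor_tol, 0, vd)
  ve <- ifelse(ve < floor_tol, 0, ve)
  vs <- ifelse(vs < floor_tol, 0, vs)
  h <- heritability(data.frame(va = va, vd = vd, vs = vs, ve = ve))
  data.frame(va = va, vd = vd, vs = vs, ve = ve, h2 = h$h2,
             loglik = best$value, converged = best$convergence == 0,
             boundary = boundary, degenerate = h$degenerate)
}

#' Variance components for every protein of a matrix
#'
#' @param mat [protein_abundance()] object or log2 matrix.
#' @param design sample sheet (taken from the object when omitted).
#' @param ... passed to [estimate_variance_components()].
#' @return data.frame, one row per protein.
#' @export
estimate_vc_all <- function(mat, design = NULL, ...) {
  if (inherits(mat, "protein_abundance")) {
    design <- mat$metadata
    m <- if (!is.null(mat$log2_abs)) mat$log2_abs else mat$log2_rel
  } else m <- as.matrix(mat)
  if (is.null(design)) stop("sample design required")
  matrices <- build_relatedness_matrices(design)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    estimate_variance_components(m[i, ], design, matrices, ...)
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(protein = rownames(m), stringsAsFactors = FALSE), out)
}

#' Broad-sense heritability from variance components
#'
#' H2 = (Va + Vd) / (Va + Vd + Vs + Ve): the fraction of total phenotypic
#' variance explained by genetic (additive plus dominance) variance. A zero
#' total variance is flagged degenerate with H2 reported as 0.
#'
#' @param vc data.frame with columns `va`, `vd`, `vs`, `ve` (all >= 0).
#' @return data.frame with `h2` and `degenerate` flag.
#' @export
heritability <- function(vc) {
  stopifnot(all(c("va", "vd", "vs", "ve") %in% names(vc)))
  comp <- as.matrix(vc[, c("va", "vd", "vs", "ve")])
  if (any(comp < 0)) stop("variance components must be non-negative")
  total <- rowSums(comp)
  genetic <- vc$va + vc$vd
  degenerate <- total == 0
  h2 <- ifelse(degenerate, 0, genetic / total)
  data.frame(h2 = h2, degenerate = degenerate)
}

#' Per-protein inheritance summary (additivity, dominance, D/A)
#'
#' @param mat [protein_abundance()] object or log2 matrix.
#' @param design sample sheet (taken from the object when omitted).
#' @return data.frame with genotype means and [dominance_additivity_ratio()]
#'   columns per protein.
#' @export
inheritance_summary <- function(mat, design = NULL) {
  if (inherits(mat, "protein_abundance")) {
    design <- mat$metadata
    m <- if (!is.null(mat$log2_abs)) mat$log2_abs else mat$log2_rel
  } else m <- as.matrix(mat)
  if (is.null(design)) stop("sample design required")
  gm <- function(strain) {
    rowMeans(m[, design$sample[design$genotype == strain], drop = FALSE])
  }
  b6 <- gm("B6"); d2 <- gm("D2")
  f1 <- cbind(gm("B6D2F1"), gm("D2B6F1"))
  cbind(data.frame(protein = rownames(m), b6_mean = b6, d2_mean = d2,
                   f1_mean = rowMeans(f1), row.names = NULL,
                   stringsAsFactors = FALSE),
        dominance_additivity_ratio(b6, d2, f1))
}
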