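# Shared fixtures, built in code at test time.

make_psm_table <- function(intensities, proteins = NULL, peptides = NULL,
                           channels = NULL) {
  m <- as.matrix(intensities)
  if (is.null(channels)) channels <- paste0("S", seq_len(ncol(m)))
  colnames(m) <- channels
  n <- nrow(m)
  df <- data.frame(psm_id = sprintf("PSM%03d", seq_len(n)),
                   peptide = if (is.null(peptides))
                     sprintf("PEPTIDE%03dK", seq_len(n)) else peptides,
                   protein = if (is.null(proteins))
                     sprintf("PROT%03d", seq_len(n)) else proteins,
                   stringsAsFactors = FALSE)
  as_psm_table(cbind(df, as.data.frame(m)), channels = channels)
}

# independent brute-force BH step-up, straight from the definition
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# exact two-sided binomial p by exhaustive minimum-likelihood enumeration
binom_two_sided_brute <- function(x, n, p0 = 0.5) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

random_protein_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
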