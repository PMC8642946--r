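#' Exact binomial test for transcript allelic imbalance
#'
#' Hybrid B- and D-allele read counts are pooled (summed) across hybrid
#' samples per gene and tested against the balanced proportion `p0` with
#' the exact two-sided binomial test (minimum-likelihood two-sided
#' convention: the sum of probabilities of all outcomes no more likely
#' than the observed one); BH adjustment is applied across tested genes.
#' Genes with pooled total below `min_total` are skipped with a reason.
#'
#' @param counts long-format data.frame with columns `gene`, `b_count`,
#'   `d_count` (a `sample` column is allowed and pooled over).
#' @param p0 null B-allele proportion.
#' @param min_total minimum pooled read count for testing.
#' @return data.frame with `gene`, `b_total`, `d_total`, `p`, `adj_p`,
#'   `tested`, `reason`.
#' @export
binomial_ase_test <- function(counts, p0 = 0.5, min_total = 10) {
  stopifnot(all(c("gene", "b_count", "d_count") %in% names(counts)))
  if (any(counts$b_count < 0 | counts$d_count < 0)) {
    stop("read counts must be non-negative")
  }
  b <- tapply(counts$b_count, counts$gene, sum)
  d <- tapply(counts$d_count, counts$gene, sum)
  genes <- sort(unique(counts$gene), method = "radix")
  b <- b[genes]; d <- d[genes]
  total <- b + d
  tested <- total >= min_total
  reason <- ifelse(tested, NA_character_,
                   ifelse(total == 0, "zero_total", "below_min_total"))
  p <- rep(NA_real_, length(genes))
  p[tested] <- vapply(which(tested), function(i) {
    stats::binom.test(b[i], total[i], p = p0)$p.value
  }, numeric(1))
  adj <- rep(NA_real_, length(genes))
  adj[tested] <- bh_adjust(p[tested])
  data.frame(gene = genes, b_total = as.integer(b), d_total = as.integer(d),
             p = p, adj_p = adj, tested = tested, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Five-way regulatory classification at the transcript level
#'
#' The parental ratio is log2(B6 expression) - log2(D2 expression); the F1
#' ratio is log2(pooled B-allele counts + pseudocount) - log2(pooled
#' D-allele counts + pseudocount). Classification uses the same
#' [classify_regulation()] decision tree as the protein level (single
#' source of truth).
#'
#' @param counts hybrid allele counts (as in [binomial_ase_test()]).
#' @param parental data.frame with `gene`, `b6_expr`, `d2_expr`
#'   (linear scale).
#' @param tau ratio threshold, log2 units.
#' @param pseudocount added to each pooled allele count before log2.
#' @param mode passed to [classify_regulation()].
#' @return data.frame with `gene`, `r_parent`, `r_f1`, `category`; tally in
#'   the `counts` attribute.
#' @export
classify_transcript_regulation <- function(counts, parental, tau = 1,
                                           pseudocount = 0.5,
                                           mode = "partition") {
  b <- tapply(counts$b_count, counts$gene, sum)
  d <- tapply(counts$d_count, counts$gene, sum)
  genes <- sort(intersect(names(b), parental$gene), method = "radix")
  if (!length(genes)) stop("no genes shared between counts and parental table")
  pi <- match(genes, parental$gene)
  r_parent <- log2(parental$b6_expr[pi]) - log2(parental$d2_expr[pi])
  r_f1 <- log2(b[genes] + pseudocount) - log2(d[genes] + pseudocount)
  out <- data.frame(gene = genes, r_parent = r_parent,
                    r_f1 = unname(r_f1),
                    category = classify_regulation(r_parent, r_f1, tau = tau,
                                                   mode = mode),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$category)
  out
}

#' Compare protein- and transcript-level regulation
#'
#' Over the genes assessed at both levels, builds the 2x2 table of ASE
#' vs non-ASE membership (ASE = any non-conserved category) and tests
#' overlap with the two-sided exact hypergeometric (Fisher) test; also
#' tallies per-category co-membership.
#'
#' @param protein_calls data.frame with `pair_id` (or `gene`) and
#'   `category`.
#' @param transcript_calls data.frame with `gene` and `category`.
#' @param mapping data.frame mapping `pair_id` to `gene`; NULL when
#'   `protein_calls` already has a `gene` column.
#' @return list with `table` (2x2), `odds_ratio`, `p_value`,
#'   `category_table` (protein x transcript categories), `n_genes`.
#' @export
compare_levels <- function(protein_calls, transcript_calls, mapping = NULL) {
  pc <- protein_calls
  if (!"gene" %in% names(pc)) {
    if (is.null(mapping)) stop("mapping required when protein calls lack gene")
    pc$gene <- mapping$gene[match(pc$pair_id, mapping$pair_id)]
  }
  pc <- pc[!is.na(pc$gene) & !is.na(pc$category), , drop = FALSE]
  tc <- transcript_calls[!is.na(transcript_calls$category), , drop = FALSE]
  shared <- intersect(pc$gene, tc$gene)
  if (!length(shared)) stop("no genes shared between protein and transcript calls")
  pi <- match(shared, pc$gene)
  ti <- match(shared, tc$gene)
  p_ase <- pc$category[pi] != "conserved"
  t_ase <- tc$category[ti] != "conserved"
  tab <- table(factor(p_ase, c(TRUE, FALSE), c("protein_ASE", "protein_non")),
               factor(t_ase, c(TRUE, FALSE), c("transcript_ASE",
                                               "transcript_non")))
  ft <- stats::fisher.test(tab)
  cat_tab <- table(protein = factor(as.character(pc$category[pi]),
                                    levels = levels(classify_regulation(0, 0))),
                   transcript = factor(as.character(tc$category[ti]),
                                       levels = levels(classify_regulation(0, 0))))
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       category_table = cat_tab, n_genes = length(shared))
}
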