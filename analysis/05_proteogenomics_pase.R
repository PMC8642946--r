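#!/usr/bin/env Rscript
# Proteogenomic allele-specific expression: build the customised protein
# database from missense variants, enumerate tryptic B/D variant peptide
# pairs, match the identified-peptide quant table, compute parental and F1
# allelic ratios, test allelic imbalance, and classify each pair as cis /
# trans / compensatory / conserved / unexpected bias.

suppressPackageStartupMessages(library(f1proteome))
ind <- "results/01_simulate"
out <- "results/05_pase"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- utils::read.delim(file.path(ind, "design.tsv"))
design$genotype <- factor(design$genotype,
                          levels = c("B6", "D2", "B6D2F1", "D2B6F1"))
reference <- read_protein_fasta(file.path(ind, "reference.fasta"))
variants <- utils::read.delim(file.path(ind, "missense_variants.tsv"))

custom <- apply_missense_variants(reference, variants)
write_protein_fasta(custom, file.path(out, "custom_db.fasta"))
pairs <- enumerate_variant_peptide_pairs(reference, variants)

read_ab <- function(f) {
  t <- utils::read.delim(file.path(ind, f), check.names = FALSE)
  m <- as.matrix(t[, design$sample]); rownames(m) <- t$pair_id
  m
}
ptab <- utils::read.delim(file.path(ind, "variant_pairs.tsv"))
b_ab <- read_ab("pair_b_abundance.tsv")
d_ab <- read_ab("pair_d_abundance.tsv")
quant <- rbind(data.frame(peptide = ptab$b_peptide, as.data.frame(b_ab),
                          check.names = FALSE),
               data.frame(peptide = ptab$d_peptide, as.data.frame(d_ab),
                          check.names = FALSE))
matched <- match_identified_peptides(quant, pairs, design)

ratios <- compute_allelic_ratios(matched)
test <- pase_test(matched)
calls <- classify_pase(ratios)
calls$adj_p <- test$adj_p[match(calls$pair_id, test$pair_id)]

tsv <- function(df, f) utils::write.table(df, file.path(out, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
tsv(pairs, "variant_peptide_pairs.tsv")
tsv(calls, "pase_calls.tsv")

truth <- utils::read.delim(file.path(ind, "pair_truth.tsv"))
key <- matched$pairs$d_peptide[match(calls$pair_id, matched$pairs$pair_id)]
tcat <- truth$category[match(key, ptab$d_peptide)]
acc <- mean(as.character(calls$category) == tcat, na.rm = TRUE)

cnt <- attr(calls, "counts")
cat(sprintf("enumerated %d pair rows (%d singletons); %d complete pairs\n",
            nrow(pairs), sum(!is.na(pairs$singleton_reason)),
            sum(matched$pairs$complete)))
cat("category tally:", paste(names(cnt), cnt, sep = "=", collapse = ", "),
    "\n")
cat(sprintf("recovery of planted categories: %.1f%%\n", 100 * acc))
cat(sprintf("pairs with significant allelic imbalance (BH < 0.05): %d\n",
            sum(calls$adj_p < 0.05, na.rm = TRUE)))
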