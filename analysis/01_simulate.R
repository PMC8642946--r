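#!/usr/bin/env Rscript
# Generate the synthetic study: a four-genotype (B6, D2 and reciprocal F1)
# TMT proteome with planted additive/dominance/sex effects, allele-
# distinguishing variant peptide pairs under the five regulatory
# categories, and hybrid allele read counts. All later steps consume these
# tables; ground truth is kept alongside for validation.

suppressPackageStartupMessages(library(f1proteome))
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

design <- strain_design()
params <- sim_params(n_proteins = 1000, seed = seed)
sim <- simulate_proteome(design, params)

vp <- simulate_variant_peptides(design, n_pairs = 500, effect = 2,
                                seed = seed + 1L)
ac <- simulate_allele_counts(n_genes = 2000, depth = 100, effect = 2,
                             seed = seed + 2L)

tsv <- function(df, f) utils::write.table(df, file.path(out, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
tsv(design, "design.tsv")
tsv(as.data.frame(sim$psms), "psms.tsv")
tsv(sim$truth, "protein_truth.tsv")
tsv(cbind(protein = rownames(sim$abundance$log2_abs),
          as.data.frame(sim$abundance$log2_abs)), "protein_true_log2.tsv")
write_protein_fasta(vp$proteome$reference, file.path(out, "reference.fasta"))
tsv(vp$proteome$variants, "missense_variants.tsv")
tsv(vp$pairs$pairs, "variant_pairs.tsv")
tsv(cbind(pair_id = rownames(vp$pairs$b_abund),
          as.data.frame(vp$pairs$b_abund)), "pair_b_abundance.tsv")
tsv(cbind(pair_id = rownames(vp$pairs$d_abund),
          as.data.frame(vp$pairs$d_abund)), "pair_d_abundance.tsv")
tsv(vp$truth, "pair_truth.tsv")
tsv(ac$counts, "allele_counts.tsv")
tsv(ac$parental, "parental_expression.tsv")
tsv(ac$truth, "gene_truth.tsv")

cat(sprintf("simulated %d samples, %d proteins (%d PSMs), %d variant pairs, %d genes\n",
            nrow(design), params$n_proteins, nrow(sim$psms),
            nrow(vp$pairs$pairs), 2000))
cat(sprintf("null proteins: %d; median |additive effect| of non-null: %.2f log2\n",
            sum(sim$truth$is_null),
            median(abs(sim$truth$a[!sim$truth$is_null]))))
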