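#!/usr/bin/env Rscript
# Genetic architecture of protein expression: pedigree relatedness
# matrices, per-protein REML variance components (Va, Vd, Vs, Ve),
# broad-sense heritability H2 = (Va + Vd) / (Va + Vd + Vs + Ve), and the
# dominance/additivity (D/A) spectrum.

suppressPackageStartupMessages(library(f1proteome))
out <- "results/04_inheritance"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- utils::read.delim("results/01_simulate/design.tsv")
design$genotype <- factor(design$genotype,
                          levels = c("B6", "D2", "B6D2F1", "D2B6F1"))
tab <- utils::read.delim("results/02_quantify/protein_abundance.tsv",
                         check.names = FALSE)
m <- as.matrix(tab[, design$sample]); rownames(m) <- tab$protein

R <- build_relatedness_matrices(design)
vc <- estimate_vc_all(m, design)
da <- inheritance_summary(m, design)
merged <- merge(vc, da, by = "protein", sort = TRUE)

tsv <- function(df, f) utils::write.table(df, file.path(out, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
tsv(cbind(genotype = rownames(R$R1_strain), as.data.frame(R$R1_strain)),
    "R1_strain.tsv")
tsv(cbind(genotype = rownames(R$R2_strain), as.data.frame(R$R2_strain)),
    "R2_strain.tsv")
tsv(merged, "inheritance.tsv")

cat(sprintf("median H2 across %d proteins: %.1f%%; %d (%.1f%%) above 50%%\n",
            nrow(merged), 100 * median(merged$h2),
            sum(merged$h2 > 0.5), 100 * mean(merged$h2 > 0.5)))
cls <- table(merged$class, useNA = "ifany")
cat("D/A classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
cat(sprintf("boundary fits: %d; non-converged: %d\n",
            sum(merged$boundary), sum(!merged$converged)))
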