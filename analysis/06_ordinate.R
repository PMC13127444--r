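#!/usr/bin/env Rscript
# Step 6 — ordination of the widespread-taxa subcommunity.
#
# Compositional PCA of the widespread families' CLR subtable, and
# distance-based redundancy analysis of their Aitchison distances
# constrained on the four standardized log concentrations.

library(redoxtaxa)

fam <- read_community(file.path("results", "family", "counts.tsv"),
                      file.path("results", "family", "taxonomy.tsv"),
                      file.path("results", "family", "metadata.tsv"))
chem <- read.delim(file.path("results", "sample_chemistry.tsv"))
ws <- read.delim(file.path("results", "widespread.tsv"))

clrm <- clr(zero_impute_counts(t(fam$counts)))
rownames(clrm) <- colnames(fam$counts)
clr_sub <- clrm[, ws$taxon, drop = FALSE]

pca <- coda_pca(clr_sub)
write.table(data.frame(axis = paste0("PC", seq_along(pca$eigenvalues)),
                       eigenvalue = pca$eigenvalues,
                       proportion = pca$proportions),
            file.path("results", "pca.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ok <- Reduce(`&`, lapply(c("O2", "NO3", "NH4", "Mn"), function(con)
  chem[[paste0(con, "_flag")]] %in%
    c("measured", "interpolated", "imputed_anoxic")))
ids <- chem$sample_id[ok]
Z <- vapply(c("O2", "NO3", "NH4", "Mn"), function(con)
  scale(log(zero_impute_conc(chem[[con]][match(ids, chem$sample_id)])))[, 1],
  numeric(length(ids)))
dbr <- db_rda(aitchison_dist(clr_sub[ids, , drop = FALSE]), Z)
write.table(data.frame(axis = paste0("RDA", seq_along(dbr$eigenvalues)),
                       eigenvalue = dbr$eigenvalues,
                       proportion = dbr$proportions),
            file.path("results", "dbrda.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("CoDa-PCA: PC1+PC2 explain %.1f%% of the widespread-taxa variance\n",
            100 * sum(pca$proportions[1:2])))
cat(sprintf("db-RDA (%d samples with complete chemistry):\n", length(ids)))
cat(sprintf("  RDA1 %.1f%%, RDA1+RDA2 %.1f%%, constrained fraction %.1f%%\n",
            100 * dbr$proportions[1], 100 * sum(dbr$proportions[1:2]),
            100 * dbr$constrained_fraction))
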