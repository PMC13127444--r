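#!/usr/bin/env Rscript
# Step 4 — Monte-Carlo cross-validated decision-tree rule mining.
#
# For each constituent, fits CART regressors (CLR-transformed
# concentration) and classifiers (presence/absence) over repeated 70/30
# splits, accumulating per-family usage into stability importance.
# 200 iterations per miner here; permutation p-values from 19 response
# permutations.

library(redoxtaxa)

seed <- 42
n_iter <- 200

fam <- read_community(file.path("results", "family", "counts.tsv"),
                      file.path("results", "family", "taxonomy.tsv"),
                      file.path("results", "family", "metadata.tsv"))
chem <- read.delim(file.path("results", "sample_chemistry.tsv"))
class(chem) <- c("sample_chemistry", "data.frame")
candidates <- readLines(file.path("results", "candidates.txt"))

clrm <- clr(zero_impute_counts(t(fam$counts)))
rownames(clrm) <- colnames(fam$counts)

summary_rows <- list()
for (i in seq_along(c("O2", "NO3", "NH4", "Mn"))) {
  con <- c("O2", "NO3", "NH4", "Mn")[i]
  rows <- which(chem[[paste0(con, "_flag")]] %in%
                  c("measured", "interpolated", "imputed_anoxic"))
  ids <- chem$sample_id[rows]
  X <- clrm[ids, candidates, drop = FALSE]
  y_reg <- as.numeric(chem_transform(chem[[con]][rows]))
  y_cls <- presence_labels(chem, con)[ids]
  for (task in c("regression", "classification")) {
    y <- if (task == "regression") y_reg else y_cls
    mr <- monte_carlo_importance(X, y, task = task, n_iter = n_iter,
                                 seed = derive_seed(seed, 100 + 10 * i +
                                                      (task == "classification")))
    p <- permutation_pvalue(X, y, task = task, B = 19, n_iter = 10,
                            seed = derive_seed(seed, 300 + 10 * i +
                                                 (task == "classification")))$p
    suffix <- if (task == "regression") "" else "_classifier"
    write.table(mr$importance,
                file.path("results", sprintf("importance_%s%s.tsv", con, suffix)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary_rows[[paste(con, task)]] <- data.frame(
      constituent = con, task = task, n_iter = n_iter,
      n_samples = length(ids),
      mean_accuracy = mean(mr$accuracy, na.rm = TRUE),
      sd_accuracy = sd(mr$accuracy, na.rm = TRUE), permutation_p = p)
    cat(sprintf("%-3s %-14s: accuracy %.3f +/- %.3f (perm p = %.3f), top: %s\n",
                con, task, mean(mr$accuracy, na.rm = TRUE),
                sd(mr$accuracy, na.rm = TRUE), p, mr$importance$taxon[1]))
  }
}
write.table(do.call(rbind, c(summary_rows, make.row.names = FALSE)),
            file.path("results", "mining_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
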