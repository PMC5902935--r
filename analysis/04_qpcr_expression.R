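#!/usr/bin/env Rscript
# Stage 4: AluS expression by the 2^-ddCt method — pooled ASD vs control
# and each subgroup against its matched control set, with BH adjustment
# across the comparisons. Writes qpcr.tsv and relative_expression.tsv.

suppressPackageStartupMessages(library(alupipe))

data_dir <- "results/data"
ct <- read_ct_table(file.path(data_dir, "ct.csv"))

pooled <- ct
pooled$group[pooled$group %in% c("M", "L", "S")] <- "ASD"
res <- rbind(
  run_fold_changes(pooled, list(c("ASD", "control"))),
  run_fold_changes(ct, list(c("M", "control_M"),
                            c("L", "control_L"),
                            c("S", "control")))
)
# one BH family across the four comparisons reported together
res$adj_p <- bh_adjust(res$raw_p)
write.table(res, "results/qpcr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (i in seq_len(nrow(res))) {
  message(sprintf("%s: FC = %.2f, log2FC = %.2f, adj p = %.3f%s",
                  res$comparison[i], res$fold_change[i], res$log2_fc[i],
                  res$adj_p[i], if (res$adj_p[i] < 0.05) " *" else ""))
}

rel <- relative_expression(ct, control_label = "control")
write.table(rel, "results/relative_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("per-sample relative expression written for %d samples",
                nrow(rel)))
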