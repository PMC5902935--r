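#!/usr/bin/env Rscript
# Stage 3: COBRA quantification of AluS methylation level and patterns per
# lane, and group comparisons: pooled ASD vs control, and each phenotypic
# subgroup against its matched control set (BH across the five metrics of
# each comparison). Writes methylation.tsv and methylation_comparisons.tsv.

suppressPackageStartupMessages(library(alupipe))

data_dir <- "results/data"
profiles <- read_band_profiles(file.path(data_dir, "bands.csv"))
summ <- compute_methylation(profiles)
write.table(as.data.frame(summ), "results/methylation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("quantified %d lanes; control uCmC mean %.2f%%",
                nrow(summ),
                mean(summ$pct_uCmC[profiles$group == "control"])))

# pooled ASD = M + L + S against the full control set
pooled <- ifelse(profiles$group %in% c("M", "L", "S"), "ASD",
                 profiles$group)
comparisons <- list(
  compare_methylation(summ, pooled, "ASD", "control",
                      comparison = "ASD vs control"),
  compare_methylation(summ, profiles$group, "M", "control_M",
                      comparison = "subgroup M vs matched control"),
  compare_methylation(summ, profiles$group, "L", "control_L",
                      comparison = "subgroup L vs matched control"),
  compare_methylation(summ, profiles$group, "S", "control",
                      comparison = "subgroup S vs matched control")
)
cmp <- do.call(rbind, comparisons)
write.table(cmp, "results/methylation_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (one in comparisons) {
  hits <- one[one$adj_p < 0.05, ]
  message(sprintf("%s: %s", one$comparison[1],
                  if (nrow(hits) == 0) "no significant metric" else
                    paste(sprintf("%s adj p = %.3f (%.2f vs %.2f)",
                                  hits$metric, hits$adj_p, hits$mean_case,
                                  hits$mean_control), collapse = "; ")))
}
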