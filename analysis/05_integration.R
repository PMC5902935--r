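#!/usr/bin/env Rscript
# Stage 5: correlate AluS methylation patterns with AluS relative
# expression — across the whole cohort and within each phenotypic
# subgroup stratum (subgroup + its matched controls). Writes
# correlation.tsv and the scatter data for the subgroup-M uCmC panel.

suppressPackageStartupMessages(library(alupipe))

data_dir <- "results/data"
profiles <- read_band_profiles(file.path(data_dir, "bands.csv"))
summ <- compute_methylation(profiles)
ct <- read_ct_table(file.path(data_dir, "ct.csv"))
expr <- relative_expression(ct, control_label = "control")

strata <- list(
  all = unique(profiles$group),
  M = c("M", "control_M"),
  L = c("L", "control_L"),
  S = c("S", "control")
)
rows <- list()
for (nm in names(strata)) {
  ids <- summ$sample_id[profiles$group %in% strata[[nm]]]
  res <- correlate_methylation_expression(summ, expr, samples = ids)
  rows[[nm]] <- cbind(stratum = nm, res$table, stringsAsFactors = FALSE)
  if (nm == "M") {
    sc <- res$scatter[res$scatter$metric == "pct_uCmC", ]
    write.csv(sc, "results/scatter_subgroupM_uCmC.csv", row.names = FALSE,
              quote = FALSE)
  }
}
cors <- do.call(rbind, rows)
rownames(cors) <- NULL
write.table(cors, "results/correlation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

r_m <- cors$r[cors$stratum == "M" & cors$metric == "pct_uCmC"]
message(sprintf("subgroup M: uCmC vs expression r = %.3f (n = %d)",
                r_m, cors$n[cors$stratum == "M"][1]))
other <- cors[cors$stratum == "M" & cors$metric != "pct_uCmC", ]
message(sprintf("subgroup M other metrics: |r| max %.3f",
                max(abs(other$r))))
message(sprintf("full cohort uCmC r = %.3f",
                cors$r[cors$stratum == "all" & cors$metric == "pct_uCmC"]))
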