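# Builds a small end-to-end input bundle (two expression studies with a
# shared planted core, an annotation, a COBRA cohort and a Ct cohort)
# under `dir`, returning a ready pipeline configuration plus the scenario
# truth.
write_pipeline_inputs <- function(dir, seed = 401) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- generate_multistudy_scenario(n_studies = 2, n_genes = 600,
                                     core_size = 15, seed = seed)
  studies <- list()
  for (sid in names(sc$studies)) {
    mp <- file.path(dir, paste0(sid, "_matrix.tsv"))
    sp <- file.path(dir, paste0(sid, "_samples.tsv"))
    write_expression_study(sc$studies[[sid]], mp, sp)
    studies[[length(studies) + 1L]] <- list(study_id = sid, matrix = mp,
                                            samples = sp)
  }
  ann_path <- file.path(dir, "annotation.tsv")
  write_insertion_table(sc$annotation, ann_path)

  coh <- generate_cobra_cohort(default_cobra_mixtures()[c("control_M", "M")],
                               n_per_group = 8, seed = seed + 1)
  bands_path <- file.path(dir, "bands.csv")
  write_band_profiles(coh$profiles, bands_path)

  qc <- generate_ct_cohort(c(control_M = 0, M = 0.06), n_per_group = 8,
                           seed = seed + 2)
  ct_path <- file.path(dir, "ct.csv")
  write_ct_table(qc$ct, ct_path)

  list(
    annotation = ann_path,
    studies = studies,
    bands = bands_path,
    ct = ct_path,
    methylation_comparisons = list(c("M", "control_M")),
    expression_comparisons = list(c("M", "control_M")),
    expression_control_group = "control_M",
    correlation_strata = list(M = "M"),
    scenario = sc
  )
}
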