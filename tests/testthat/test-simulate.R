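test_that("every generator is a pure function of configuration and seed", {
  a1 <- generate_annotation(200, seed = 5)
  a2 <- generate_annotation(200, seed = 5)
  expect_identical(a1, a2)

  e1 <- generate_expression_study(n_genes = 300, seed = 6)
  e2 <- generate_expression_study(n_genes = 300, seed = 6)
  expect_identical(e1$study$matrix, e2$study$matrix)
  expect_identical(e1$truth, e2$truth)
  e3 <- generate_expression_study(n_genes = 300, seed = 7)
  expect_false(identical(e1$study$matrix, e3$study$matrix))

  c1 <- generate_cobra_cohort(default_cobra_mixtures()["control"],
                              n_per_group = 4, seed = 8)
  c2 <- generate_cobra_cohort(default_cobra_mixtures()["control"],
                              n_per_group = 4, seed = 8)
  expect_identical(c1, c2)

  q1 <- generate_ct_cohort(c(control = 0, case = 1), n_per_group = 4,
                           seed = 9)
  q2 <- generate_ct_cohort(c(control = 0, case = 1), n_per_group = 4,
                           seed = 9)
  expect_identical(q1, q2)
})

test_that("annotation defaults hit the expected per-type frequencies", {
  tab <- generate_annotation(20000, seed = 10)
  counts <- alu_type_counts(tab)
  for (tp in names(DEFAULT_TYPE_FREQUENCIES)) {
    expect_lt(abs(counts[[tp]] - 20000 * DEFAULT_TYPE_FREQUENCIES[[tp]]),
              0.01 * 20000)
  }
  # intronic dominates, promoter rarest (the insertion-type ordering)
  expect_gt(counts[["intronic"]], counts[["exonic"]])
  expect_gt(counts[["exonic"]], counts[["exonized"]])
  expect_gt(counts[["exonized"]], counts[["promoter"]])
  expect_error(generate_annotation(10, type_frequencies = c(exonic = 0)),
               "no gene received")
  one <- generate_annotation(50, type_frequencies = c(intronic = 1),
                             seed = 2)
  expect_equal(length(genes_with_type(one, "intronic")), 50L)
})

test_that("planted truth matches the generated study", {
  g <- generate_expression_study(n_genes = 500, frac_deg = 0.08,
                                 missing_rate = 0, seed = 11)
  truth <- g$truth
  m <- g$study$matrix
  expect_length(truth$deg_down, 0.04 * 500)
  expect_length(truth$deg_up, 0.04 * 500)
  # planted downs are lower in cases; nulls are not shifted
  case <- g$study$samples$group == "case"
  diff_means <- rowMeans(m[, case]) - rowMeans(m[, !case])
  expect_lt(max(diff_means[truth$deg_down]), 0)
  expect_gt(min(diff_means[truth$deg_up]), 0)
  nulls <- setdiff(rownames(m), c(truth$deg_down, truth$deg_up))
  expect_lt(abs(mean(diff_means[nulls])), 0.1)
  # Alu membership recorded in truth equals the annotation's gene set
  expect_setequal(truth$alu_genes, genes_with_type(g$annotation, "all"))
})

test_that("missingness interacts with the presence filter binomially", {
  n_genes <- 20000
  g <- generate_expression_study(n_genes = n_genes, n_case = 20,
                                 n_control = 20, frac_deg = 0,
                                 missing_rate = 0.5, seed = 12)
  kept <- nrow(filter_presence(g$study, 0.70)$matrix)
  # a gene survives iff >= 28 of its 40 entries are observed
  p_survive <- 1 - pbinom(ceiling(0.7 * 40) - 1, 40, 0.5)
  expect_lt(abs(kept - n_genes * p_survive),
            4 * sqrt(n_genes * p_survive * (1 - p_survive)) + 1)
})

test_that("multi-study scenarios share a core that every study downregulates", {
  sc <- generate_multistudy_scenario(n_studies = 3, n_genes = 800,
                                     core_size = 20, seed = 13)
  expect_length(sc$truth$core, 20L)
  alu <- genes_with_type(sc$annotation, "all")
  expect_true(all(sc$truth$core %in% alu))
  for (sid in names(sc$studies)) {
    expect_true(all(sc$truth$core %in% sc$truth$per_study[[sid]]$deg_down))
  }
})

test_that("noise-free COBRA cohorts reproduce the group truth exactly", {
  mixes <- default_cobra_mixtures()[c("control", "M")]
  coh <- generate_cobra_cohort(mixes, n_per_group = 3, cv = 0,
                               concentration = Inf, seed = 14)
  s <- compute_methylation(coh$profiles)
  for (g in names(mixes)) {
    truth <- unclass(mixes[[g]])
    rows <- s[coh$profiles$group == g, ]
    expect_equal(rows$pct_uCuC, rep(100 * truth[["p_uu"]], 3),
                 tolerance = 1e-9)
    expect_equal(rows$pct_uCmC, rep(100 * truth[["p_um"]], 3),
                 tolerance = 1e-9)
  }
})

test_that("Dirichlet jitter produces the targeted between-sample spread", {
  mix <- default_cobra_mixtures()["control_M"]
  conc <- 2000
  coh <- generate_cobra_cohort(mix, n_per_group = 300, cv = 0,
                               concentration = conc, seed = 15)
  s <- compute_methylation(coh$profiles)
  p_um <- unclass(mix$control_M)[["p_um"]]
  target_sd <- 100 * sqrt(p_um * (1 - p_um) / (conc + 1))
  expect_lt(abs(sd(s$pct_uCmC) - target_sd) / target_sd, 0.20)
})

test_that("Ct cohorts honour their noise parameters", {
  # no replicate noise: triplicates are identical
  g0 <- generate_ct_cohort(c(control = 0, case = 1), n_per_group = 3,
                           replicate_sd = 0, seed = 16)
  spread <- tapply(g0$ct$ct, paste(g0$ct$sample_id, g0$ct$assay),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # and per-sample dCt equals the generator's truth exactly
  d <- delta_ct(g0$ct)
  expect_equal(d$dct, unlist(g0$truth$true_dct)[d$sample_id],
               tolerance = 1e-12, ignore_attr = TRUE)

  # null fold change stays near 1
  g1 <- generate_ct_cohort(c(control = 0, case = 0), n_per_group = 10,
                           seed = 17)
  expect_lt(abs(fold_change(g1$ct, "case", "control")$log2_fc), 0.3)

  # per-sample log2 offsets shift that sample's true dCt one-for-one
  off <- c(case_01 = 2)
  g2 <- generate_ct_cohort(c(control = 0, case = 0), n_per_group = 3,
                           replicate_sd = 0, biological_sd = 0,
                           sample_log2fc_offsets = off, seed = 18)
  d2 <- delta_ct(g2$ct)
  expect_equal(d2$dct[d2$sample_id == "case_01"],
               d2$dct[d2$sample_id == "case_02"] - 2, tolerance = 1e-12)
})

test_that("truth objects survive JSON serialization", {
  g <- generate_expression_study(n_genes = 120, seed = 18)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(g$truth, path)
  back <- read_truth(path)
  expect_equal(back$deg_down, g$truth$deg_down)
  expect_equal(back$params$effect_size, g$truth$params$effect_size)
})
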