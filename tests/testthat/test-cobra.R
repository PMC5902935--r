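test_that("molar normalization is the plain intensity/length quotient", {
  prof <- c(b133 = 100, b90 = 0, b75 = 0, b58 = 0, b43 = 0, b32 = 0)
  q <- normalize_bands(prof)
  expect_equal(q[["A"]], 100 / 133)
  expect_equal(unname(q[c("B", "C", "D", "E", "F")]), rep(0, 5))

  equal <- setNames(rep(100 / 6, 6), names(BAND_LENGTHS))
  q2 <- normalize_bands(equal)
  expect_equal(unname(q2),
               (100 / 6) / c(133, 58, 75, 90, 43, 32), tolerance = 1e-12)

  set.seed(131)
  for (i in 1:20) {
    raw <- runif(6, 0, 50)
    names(raw) <- names(BAND_LENGTHS)
    shares <- 100 * raw / sum(raw)
    q3 <- normalize_bands(raw)
    expect_equal(unname(q3),
                 unname(shares[c("b133", "b58", "b75", "b90", "b43", "b32")] /
                          c(133, 58, 75, 90, 43, 32)),
                 tolerance = 1e-12)
  }
  expect_error(band_profile(c(b133 = -1, b90 = 1, b75 = 1, b58 = 1,
                              b43 = 1, b32 = 1)), "negative")
  expect_error(band_profile(setNames(rep(0, 6), names(BAND_LENGTHS))),
               "blank lane")
})

test_that("pure states produce the expected summaries", {
  # fully unmethylated: only the intact 133-bp amplicon
  uu <- compute_methylation(c(b133 = 100, b90 = 0, b75 = 0, b58 = 0,
                              b43 = 0, b32 = 0))
  expect_equal(uu[["pct_mC"]], 0)
  expect_equal(uu[["pct_uCuC"]], 100)
  expect_equal(uu[["pct_mCmC"]] + uu[["pct_uCmC"]] + uu[["pct_mCuC"]], 0)

  # fully methylated: equimolar 58/43/32 fragments, mass-proportional shares
  mm_mass <- c(b133 = 0, b90 = 0, b75 = 0, b58 = 58, b43 = 43, b32 = 32)
  mm <- compute_methylation(mm_mass)
  expect_equal(mm[["pct_mC"]], 100)
  expect_equal(mm[["pct_mCmC"]], 100)
  expect_equal(mm[["pct_uCuC"]], 0)

  # uniform mixture: patterns 25 each, half the loci methylated
  s <- compute_methylation(forward_profile(state_mixture(0.25, 0.25, 0.25,
                                                         0.25)))
  expect_equal(unname(s[c("pct_uCuC", "pct_mCuC", "pct_uCmC", "pct_mCmC")]),
               rep(25, 4), tolerance = 1e-9)
  expect_equal(s[["pct_mC"]], 50, tolerance = 1e-9)
})

test_that("forward profiles place mass on the state-diagnostic bands", {
  p_uu <- forward_profile(state_mixture(1, 0, 0, 0))
  expect_equal(p_uu[["b133"]], 100)
  # one mCuC molecule yields one 43-mer and one 90-mer; mass ~ length
  p_mu <- forward_profile(state_mixture(0, 1, 0, 0))
  expect_equal(p_mu[["b43"]] / p_mu[["b90"]], 43 / 90, tolerance = 1e-12)
  expect_equal(p_mu[["b43"]] + p_mu[["b90"]], 100)
  # molar mode weights fragments by count only
  p_mu_molar <- forward_profile(state_mixture(0, 1, 0, 0),
                                intensity_mode = "molar")
  expect_equal(p_mu_molar[["b43"]], p_mu_molar[["b90"]])
})

test_that("estimator inverts the forward model exactly", {
  set.seed(141)
  for (i in 1:200) {
    mix <- random_state_mixture()
    s <- compute_methylation(forward_profile(mix))
    expect_equal(s[["pct_uCuC"]], 100 * mix[["p_uu"]], tolerance = 1e-9)
    expect_equal(s[["pct_mCuC"]], 100 * mix[["p_mu"]], tolerance = 1e-9)
    expect_equal(s[["pct_uCmC"]], 100 * mix[["p_um"]], tolerance = 1e-9)
    expect_equal(s[["pct_mCmC"]], 100 * mix[["p_mm"]], tolerance = 1e-9)
    # methylated-locus fraction: each molecule carries two CpG loci
    expect_equal(s[["pct_mC"]],
                 100 * (mix[["p_mu"]] / 2 + mix[["p_um"]] / 2 + mix[["p_mm"]]),
                 tolerance = 1e-9)
    # closure and internal consistency on noise-free profiles
    expect_equal(s[["pct_uCuC"]] + s[["pct_mCuC"]] + s[["pct_uCmC"]] +
                   s[["pct_mCmC"]], 100, tolerance = 1e-9)
    expect_equal(s[["pct_mC"]],
                 (s[["pct_mCuC"]] + s[["pct_uCmC"]]) / 2 + s[["pct_mCmC"]],
                 tolerance = 1e-9)
  }
})

test_that("methylation increases when mm replaces uu, and scale cancels", {
  grid <- seq(0, 0.6, by = 0.1)
  mc <- vapply(grid, function(x) {
    compute_methylation(forward_profile(
      state_mixture(0.6 - x, 0.2, 0.2, x)))[["pct_mC"]]
  }, numeric(1))
  expect_true(all(diff(mc) > 0))

  prof <- forward_profile(state_mixture(0.3, 0.25, 0.25, 0.2))
  expect_equal(compute_methylation(prof * 7.3), compute_methylation(prof))
})

test_that("gel noise is seed-reproducible, mean-preserving, and off at cv 0", {
  prof <- forward_profile(state_mixture(0.34, 0.22, 0.19, 0.25))
  expect_equal(add_gel_noise(prof, cv = 0), prof)
  expect_equal(add_gel_noise(prof, cv = 0.05, seed = 99),
               add_gel_noise(prof, cv = 0.05, seed = 99))
  expect_false(isTRUE(all.equal(add_gel_noise(prof, cv = 0.05, seed = 99),
                                add_gel_noise(prof, cv = 0.05, seed = 100))))
  # Monte-Carlo bias check: mean estimated patterns within 1.5 points
  set.seed(151)
  mix <- state_mixture(0.34, 0.22, 0.19, 0.25)
  est <- t(replicate(200, {
    s <- compute_methylation(add_gel_noise(forward_profile(mix), cv = 0.05))
    s[c("pct_uCuC", "pct_mCuC", "pct_uCmC", "pct_mCmC")]
  }))
  expect_true(all(abs(colMeans(est) - 100 * unclass(mix)) < 1.5))
})

test_that("partial digestion biases the estimator toward hypomethylation", {
  mix <- state_mixture(0.2, 0.2, 0.2, 0.4)
  full <- compute_methylation(forward_profile(mix))
  partial <- compute_methylation(forward_profile(mix,
                                                 digestion_efficiency = 0.8))
  expect_lt(partial[["pct_mC"]], full[["pct_mC"]])
  expect_lt(partial[["pct_mCmC"]], full[["pct_mCmC"]])
})

test_that("data-frame lanes are summarised row-wise with ids carried through", {
  coh <- generate_cobra_cohort(default_cobra_mixtures()[c("control", "M")],
                               n_per_group = 3, seed = 8)
  s <- compute_methylation(coh$profiles)
  expect_s3_class(s, "methylation_summary")
  expect_equal(s$sample_id, coh$profiles$sample_id)
  expect_equal(s$group, coh$profiles$group)
  one <- compute_methylation(unlist(coh$profiles[1, names(BAND_LENGTHS)]))
  expect_equal(s$pct_mC[1], one[["pct_mC"]])
})

test_that("band CSV round-trips through the readers", {
  coh <- generate_cobra_cohort(default_cobra_mixtures()["control"],
                               n_per_group = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_band_profiles(coh$profiles, path)
  back <- read_band_profiles(path)
  expect_equal(back$sample_id, coh$profiles$sample_id)
  expect_equal(back$b133, coh$profiles$b133, tolerance = 1e-12)
  expect_error(read_band_profiles(withr::local_tempfile(lines = "x,y",
                                                        fileext = ".csv")),
               "missing column")
})
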