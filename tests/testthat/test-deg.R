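test_that("presence filter keeps exactly-70%-observed genes and drops below", {
  m <- matrix(rnorm(30), nrow = 3, ncol = 10,
              dimnames = list(c("G7", "G6", "G10"), sprintf("S%02d", 1:10)))
  m["G7", 1:3] <- NA   # 7/10 observed: kept at the inclusive boundary
  m["G6", 1:4] <- NA   # 6/10 observed: removed
  st <- filter_presence(make_study(m, n_case = 5), cutoff = 0.70)
  expect_setequal(rownames(st$matrix), c("G7", "G10"))
  expect_equal(rownames(st$matrix), c("G7", "G10")) # order preserved
  expect_error(filter_presence(make_study(m, 5), cutoff = 0), "\\(0, 1\\]")
  m2 <- m
  m2["G10", 1] <- NA # now every gene has a missing entry
  expect_warning(filter_presence(make_study(m2, 5), cutoff = 1 - 1e-9),
                 "removed every gene")
})

test_that("presence filter agrees with direct non-missing counting", {
  set.seed(61)
  rates <- c(0.0, 0.25, 0.35, 0.5)
  n_samp <- 40
  m <- matrix(rnorm(4 * 50 * n_samp), ncol = n_samp)
  rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%02d", seq_len(n_samp))
  rate_of_gene <- rep(rates, each = 50)
  for (i in seq_len(nrow(m))) {
    m[i, runif(n_samp) < rate_of_gene[i]] <- NA
  }
  st <- filter_presence(make_study(m, n_case = 20), cutoff = 0.70)
  kept_oracle <- rownames(m)[rowSums(!is.na(m)) >= 0.70 * n_samp]
  expect_equal(rownames(st$matrix), kept_oracle)
})

test_that("identical groups yield p = 1 and no DEGs; m = 1 keeps raw p", {
  m <- matrix(rep(c(5, 6, 7, 5, 6, 7), each = 4), nrow = 4, byrow = FALSE,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
  degs <- call_degs(make_study(m, n_case = 3))
  expect_true(all(degs$raw_p == 1))
  expect_false(any(degs$is_deg))

  # single tested gene: Bonferroni with m = 1 leaves p unchanged
  set.seed(3)
  m1 <- matrix(c(rnorm(4, 10), rnorm(4, 0)), nrow = 1,
               dimnames = list("G1", paste0("S", 1:8)))
  d1 <- call_degs(make_study(m1, n_case = 4))
  expect_equal(d1$adj_p, d1$raw_p)
  expect_true(d1$is_deg)
})

test_that("row t-statistics agree with stats::t.test under missingness", {
  set.seed(71)
  for (var_equal in c(TRUE, FALSE)) {
    m <- matrix(rnorm(50 * 16), nrow = 50,
                dimnames = list(sprintf("G%02d", 1:50), sprintf("S%02d", 1:16)))
    m[runif(length(m)) < 0.15] <- NA
    st <- make_study(m, n_case = 8)
    degs <- call_degs(st, var_equal = var_equal)
    for (i in which(degs$tested)) {
      x <- m[i, 1:8]; y <- m[i, 9:16]
      ref <- t.test(x[!is.na(x)], y[!is.na(y)], var.equal = var_equal)
      expect_equal(degs$raw_p[i], ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("genes with fewer than two values per group are excluded, not tested", {
  m <- matrix(rnorm(3 * 8), nrow = 3,
              dimnames = list(paste0("G", 1:3), paste0("S", 1:8)))
  m[2, 1:3] <- NA # one case value left
  expect_warning(degs <- call_degs(make_study(m, n_case = 4)),
                 "excluded from testing")
  expect_false(degs$tested[2])
  expect_true(is.na(degs$raw_p[2]))
  expect_true(is.na(degs$direction[2]))
  expect_equal(attr(degs, "n_tested"), 2L)
  # Bonferroni factor counts only tested genes
  expect_equal(degs$adj_p[1], min(1, degs$raw_p[1] * 2))
})

test_that("zero within-group variance with equal means gives p = 1", {
  m <- matrix(c(rep(4, 8), c(4, 4, 4, 4, 9, 9, 9, 9)), nrow = 2,
              byrow = TRUE, dimnames = list(c("FLAT", "SPLIT"),
                                            paste0("S", 1:8)))
  degs <- call_degs(make_study(m, n_case = 4))
  expect_equal(degs$raw_p[degs$gene == "FLAT"], 1)
  expect_lt(degs$raw_p[degs$gene == "SPLIT"], 1e-6)
})

test_that("planted shifts are recovered with high sensitivity and few false calls", {
  sens <- fpr <- numeric(0)
  for (s in 1:20) {
    set.seed(400 + s)
    n_null <- 500; n_shift <- 50; n <- 20
    m <- matrix(rnorm((n_null + n_shift) * 2 * n), ncol = 2 * n)
    rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
    colnames(m) <- sprintf("S%02d", seq_len(2 * n))
    shifted <- seq_len(n_shift) + n_null
    m[shifted, seq_len(n)] <- m[shifted, seq_len(n)] + 3 # 3 pooled-SD units
    degs <- call_degs(make_study(m, n_case = n))
    called <- degs$gene[degs$is_deg]
    sens <- c(sens, mean(rownames(m)[shifted] %in% called))
    fpr <- c(fpr, mean(rownames(m)[seq_len(n_null)] %in% called))
  }
  expect_gt(mean(sens), 0.9)
  expect_lte(max(fpr), 0.05)
})

test_that("Bonferroni calling controls the family-wise error under the null", {
  set.seed(81)
  any_deg <- logical(200)
  for (r in seq_along(any_deg)) {
    m <- matrix(rnorm(300 * 12), nrow = 300,
                dimnames = list(sprintf("G%03d", 1:300), sprintf("S%02d", 1:12)))
    any_deg[r] <- any(call_degs(make_study(m, n_case = 6))$is_deg)
  }
  # FWER <= alpha up to Monte-Carlo error (SE ~ 0.015 at 200 replicates)
  expect_lte(mean(any_deg), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("presence filtering never changes the raw p of a retained gene", {
  set.seed(91)
  m <- matrix(rnorm(100 * 20), nrow = 100,
              dimnames = list(sprintf("G%03d", 1:100), sprintf("S%02d", 1:20)))
  m[runif(length(m)) < 0.25] <- NA
  st <- make_study(m, n_case = 10)
  p_unfiltered <- call_degs(st)
  filt <- filter_presence(st, 0.70)
  p_filtered <- call_degs(filt)
  common <- intersect(p_filtered$gene, p_unfiltered$gene)
  expect_equal(p_filtered$raw_p[match(common, p_filtered$gene)],
               p_unfiltered$raw_p[match(common, p_unfiltered$gene)])
})

test_that("up and down directions partition the DEG set", {
  g <- generate_expression_study(n_genes = 600, seed = 5)
  degs <- call_degs(filter_presence(g$study))
  all_degs <- deg_genes(degs, "all")
  up <- deg_genes(degs, "up")
  down <- deg_genes(degs, "down")
  expect_length(intersect(up, down), 0)
  expect_setequal(c(up, down), all_degs)
})

test_that("probe collapse keeps the most significant probe per gene", {
  set.seed(101)
  m <- matrix(rnorm(4 * 12), nrow = 4,
              dimnames = list(c("GA|p1", "GA|p2", "GB|p1", "GC|p1"),
                              sprintf("S%02d", 1:12)))
  m["GA|p2", 1:6] <- m["GA|p2", 1:6] + 5 # clearly the better probe
  st <- collapse_probes(make_study(m, n_case = 6))
  expect_setequal(rownames(st$matrix), c("GA", "GB", "GC"))
  expect_equal(unname(st$matrix["GA", ]), unname(m["GA|p2", ]))
})
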