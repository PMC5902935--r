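#' @title Synthetic-data generators with planted ground truth
#' @name simulate
#' @description Seed-reproducible generators for every input the workflow
#'   consumes: Alu insertion annotations, missingness-laden expression
#'   matrices with downregulation planted preferentially in Alu-inserted
#'   genes, COBRA gel profiles forward-simulated from true four-state
#'   methylation mixtures, and qPCR Ct tables generated from true log2
#'   fold changes. Every generator is a pure function of (configuration,
#'   seed), and the returned truth object is sufficient to score every
#'   downstream stage.
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Default per-type insertion frequencies
#'
#' Membership probabilities among Alu-inserted genes, matching the
#' intronic >> exonic > exonized > promoter ordering of the TranspoGene
#' hg18 gene lists (intronic insertions dominate: roughly 98% of
#' Alu-inserted genes carry one; exonic ~12%, exonized ~6%, promoter ~4%).
#' @export
DEFAULT_TYPE_FREQUENCIES <- c(exonic = 0.12, exonized = 0.06,
                              intronic = 0.95, promoter = 0.04)

#' Generate a synthetic Alu insertion annotation
#'
#' Each candidate gene independently carries each insertion type with the
#' given frequency; genes that end up with no type are omitted from the
#' table (the table lists inserted genes only).
#'
#' @param n_genes Number of candidate genes.
#' @param type_frequencies Named per-type membership probabilities.
#' @param seed Integer seed.
#' @param gene_names Optional character vector of candidate gene symbols
#'   (length `n_genes`); defaults to `GENE00001` style names.
#' @return An [alu_insertion_table()].
#' @export
generate_annotation <- function(n_genes,
                                type_frequencies = DEFAULT_TYPE_FREQUENCIES,
                                seed = 1L, gene_names = NULL) {
  stopifnot(all(type_frequencies >= 0), all(type_frequencies <= 1))
  if (!all(names(type_frequencies) %in% ALU_INSERTION_TYPES)) {
    stop("type_frequencies must be named by insertion type")
  }
  if (is.null(gene_names)) {
    gene_names <- sprintf("GENE%05d", seq_len(n_genes))
  }
  stopifnot(length(gene_names) == n_genes)
  rows <- withr::with_seed(seed, {
    do.call(rbind, lapply(names(type_frequencies), function(tp) {
      member <- stats::runif(n_genes) < type_frequencies[[tp]]
      if (!any(member)) return(NULL)
      data.frame(gene = gene_names[member], insertion_type = tp,
                 stringsAsFactors = FALSE)
    }))
  })
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("no gene received any insertion type (all frequencies 0?)")
  }
  alu_insertion_table(rows)
}

#' Generate a synthetic expression study with planted DEGs
#'
#' Baseline intensities are i.i.d. normal around per-gene means
#' (`N(8, 1)` gene means, unit residual SD, so `effect_size` is in
#' within-group SD units). A planted fraction of genes is shifted in the
#' case group: downregulated genes are drawn preferentially from
#' Alu-inserted genes with odds multiplier `alu_down_enrichment`
#' (`1` = no association, the null for enrichment tests); upregulated
#' genes are drawn uniformly from the remainder. Missingness is completely
#' at random per entry.
#'
#' @param n_genes,n_case,n_control Dimensions of the study.
#' @param frac_deg Fraction of genes planted as DEGs (half down, half up).
#' @param alu_down_enrichment Odds multiplier for an Alu-inserted gene to
#'   be chosen as a downregulated DEG. Default 1 (null).
#' @param missing_rate Per-entry missingness probability.
#' @param effect_size Planted shift in residual-SD units.
#' @param alu_fraction Fraction of the gene universe that is Alu-inserted
#'   (used only when `annotation` is not supplied). Default 0.6.
#' @param annotation Optional [alu_insertion_table()] over the study's
#'   gene names; generated internally when `NULL`.
#' @param core_down_genes Optional genes forced into the planted
#'   downregulated set (used for multi-study cores).
#' @param study_id Study label.
#' @param seed Integer seed.
#' @return List with `study` (an [expression_study()]), `annotation`, and
#'   `truth` (planted DEG sets with directions, Alu membership, parameters,
#'   seed).
#' @export
generate_expression_study <- function(n_genes = 2000, n_case = 20,
                                      n_control = 20, frac_deg = 0.05,
                                      alu_down_enrichment = 1,
                                      missing_rate = 0.1, effect_size = 3,
                                      alu_fraction = 0.6, annotation = NULL,
                                      core_down_genes = NULL,
                                      study_id = "SIM1", seed = 1L) {
  stopifnot(frac_deg >= 0, frac_deg < 1, missing_rate >= 0, missing_rate < 1,
            alu_down_enrichment > 0)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  if (is.null(annotation)) {
    n_alu <- round(alu_fraction * n_genes)
    alu_candidates <- withr::with_seed(seed + 1000000L,
                                       sample(genes, n_alu))
    annotation <- generate_annotation(n_alu, seed = seed + 2000000L,
                                      gene_names = alu_candidates)
  }
  alu_genes <- genes_with_type(annotation, "all")
  is_alu <- genes %in% alu_genes
  core_down_genes <- intersect(core_down_genes %||% character(0), genes)

  out <- withr::with_seed(seed, {
    n_down <- max(round(frac_deg * n_genes / 2), length(core_down_genes))
    n_up <- round(frac_deg * n_genes / 2)
    pool <- setdiff(genes, core_down_genes)
    w <- ifelse(pool %in% alu_genes, alu_down_enrichment, 1)
    extra_down <- if (n_down > length(core_down_genes)) {
      sample(pool, n_down - length(core_down_genes), prob = w)
    } else character(0)
    down <- c(core_down_genes, extra_down)
    up <- sample(setdiff(genes, down), n_up)

    mu <- stats::rnorm(n_genes, mean = 8, sd = 1)
    n_samp <- n_case + n_control
    m <- matrix(stats::rnorm(n_genes * n_samp, mean = mu, sd = 1),
                nrow = n_genes, ncol = n_samp)
    case_cols <- seq_len(n_case)
    m[genes %in% down, case_cols] <- m[genes %in% down, case_cols] -
      effect_size
    m[genes %in% up, case_cols] <- m[genes %in% up, case_cols] + effect_size
    if (missing_rate > 0) {
      m[stats::runif(length(m)) < missing_rate] <- NA_real_
    }
    rownames(m) <- genes
    colnames(m) <- sprintf("%s_S%03d", study_id, seq_len(n_samp))
    samples <- data.frame(
      sample_id = colnames(m),
      group = rep(c("case", "control"), c(n_case, n_control)),
      subgroup = "none", stringsAsFactors = FALSE
    )
    list(study = expression_study(m, samples, study_id = study_id),
         down = sort(down), up = sort(up))
  })

  truth <- list(study_id = study_id, deg_down = out$down, deg_up = out$up,
                core_down = sort(core_down_genes),
                alu_genes = alu_genes,
                params = list(n_genes = n_genes, n_case = n_case,
                              n_control = n_control, frac_deg = frac_deg,
                              alu_down_enrichment = alu_down_enrichment,
                              missing_rate = missing_rate,
                              effect_size = effect_size),
                seed = seed)
  list(study = out$study, annotation = annotation, truth = truth)
}

#' Generate a multi-study scenario with a shared downregulated core
#'
#' All studies share one gene universe and one Alu annotation; a planted
#' core of Alu-inserted genes is downregulated in every study, while the
#' remaining planted DEGs are study-private. Feeding the studies through
#' DEG calling, enrichment and the reproducible-overlap step should
#' recover the core at `min_support = 2`.
#'
#' @param n_studies Number of studies. Default 4.
#' @param core_size Size of the shared downregulated Alu core. Default 50.
#' @param seed Integer seed; study `i` uses `seed + i`.
#' @inheritParams generate_expression_study
#' @param ... Passed to [generate_expression_study()].
#' @return List with `studies` (named list of [expression_study()]),
#'   `annotation`, and `truth` (core genes, per-study planted sets).
#' @export
generate_multistudy_scenario <- function(n_studies = 4, n_genes = 5000,
                                         core_size = 50,
                                         alu_down_enrichment = 3,
                                         alu_fraction = 0.6, seed = 1L,
                                         ...) {
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  n_alu <- round(alu_fraction * n_genes)
  alu_candidates <- withr::with_seed(seed + 1000000L, sample(genes, n_alu))
  annotation <- generate_annotation(n_alu, seed = seed + 2000000L,
                                    gene_names = alu_candidates)
  core <- withr::with_seed(seed + 3000000L,
                           sample(genes_with_type(annotation, "all"),
                                  core_size))
  studies <- list()
  truths <- list()
  for (i in seq_len(n_studies)) {
    sid <- sprintf("SIM%d", i)
    g <- generate_expression_study(n_genes = n_genes,
                                   alu_down_enrichment = alu_down_enrichment,
                                   annotation = annotation,
                                   core_down_genes = core,
                                   study_id = sid, seed = seed + i, ...)
    studies[[sid]] <- g$study
    truths[[sid]] <- g$truth
  }
  list(studies = studies, annotation = annotation,
       truth = list(core = sort(core), per_study = truths, seed = seed))
}

#' Default COBRA group mixtures
#'
#' Four-state mixtures emulating a reported LCL cohort: controls around
#' 33.8% uCuC / 18.7% uCmC / 21.8% mCuC / 25.7% mCmC, a mild-phenotype
#' (M) subgroup with the partially methylated uCmC pattern elevated to
#' about 20.1%, a language-impaired (L) subgroup with a higher
#' hypomethylated fraction, and a savant (S) subgroup with a reduced mCuC
#' pattern.
#'
#' @return Named list of [state_mixture()] objects (`control`,
#'   `control_M`, `M`, `control_L`, `L`, `S`).
#' @export
default_cobra_mixtures <- function() {
  m <- function(uu, um, mu, mm) {
    p <- c(uu, mu, um, mm) / sum(c(uu, mu, um, mm))
    state_mixture(p[1], p[2], p[3], p[4])
  }
  list(
    control   = m(33.83, 18.71, 21.76, 25.70),
    control_M = m(33.62, 18.76, 22.06, 25.57),
    M         = m(31.77, 20.06, 22.99, 25.17),
    control_L = m(33.77, 19.10, 22.25, 24.88),
    L         = m(36.38, 19.32, 20.93, 23.37),
    S         = m(34.64, 17.88, 20.43, 27.06)
  )
}

#' Generate a COBRA band-intensity cohort
#'
#' Per sample, the group's true mixture is jittered by a Dirichlet
#' perturbation (concentration parameter `concentration`; `Inf` disables
#' jitter), forward-simulated through the digestion/gel model, and
#' quantification noise is added. The default concentration of 2000 gives
#' per-sample pattern SDs of roughly 0.8-1.1 percentage points, matching
#' observed between-sample variability in LCL cohorts.
#'
#' @param mixtures_by_group Named list of [state_mixture()]s, one per
#'   group.
#' @param n_per_group Samples per group; scalar or named vector.
#' @param cv Gel quantification noise CV. Default 0.03.
#' @param concentration Dirichlet concentration of the biological jitter.
#'   Default 2000; `Inf` = no jitter.
#' @param seed Integer seed.
#' @return List with `profiles` (data frame: `sample_id`, `group`,
#'   `subgroup`, six band columns) and `truth` (group mixtures, per-sample
#'   true mixtures, parameters, seed).
#' @export
generate_cobra_cohort <- function(mixtures_by_group, n_per_group = 10,
                                  cv = 0.03, concentration = 2000,
                                  seed = 1L) {
  stopifnot(length(mixtures_by_group) >= 1, !is.null(names(mixtures_by_group)))
  groups <- names(mixtures_by_group)
  if (length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(n_per_group, length(groups)), groups)
  }
  stopifnot(all(groups %in% names(n_per_group)))
  withr::with_seed(seed, {
    rows <- list()
    sample_truth <- list()
    k <- 0L
    for (g in groups) {
      p0 <- unclass(mixtures_by_group[[g]])
      for (j in seq_len(n_per_group[[g]])) {
        k <- k + 1L
        p <- if (is.finite(concentration)) {
          rdirichlet1(concentration * p0)
        } else {
          p0
        }
        mix <- state_mixture(p[[1]], p[[2]], p[[3]], p[[4]])
        prof <- forward_profile(mix)
        if (cv > 0) prof <- add_gel_noise(prof, cv)
        sid <- sprintf("%s_%02d", g, j)
        rows[[k]] <- data.frame(sample_id = sid, group = g,
                                subgroup = if (g %in% c("L", "M", "S")) g
                                           else "none",
                                t(prof), stringsAsFactors = FALSE)
        sample_truth[[sid]] <- unclass(mix)
      }
    }
    profiles <- do.call(rbind, rows)
    rownames(profiles) <- NULL
    list(profiles = profiles,
         truth = list(group_mixtures = lapply(mixtures_by_group, unclass),
                      sample_mixtures = sample_truth,
                      params = list(n_per_group = as.list(n_per_group),
                                    cv = cv, concentration = concentration),
                      seed = seed))
  })
}

#' Generate a qPCR Ct cohort from true log2 fold changes
#'
#' Per sample: a reference-gene mean Ct is drawn from `N(18, 0.3)`; the
#' sample's true dCt is `baseline_dct - true_log2fc(group) + N(0,
#' biological_sd)`; replicate Ct values for both assays add independent
#' `N(0, replicate_sd)` noise. With `replicate_sd = 0` the per-sample dCt
#' is exact. The control group (label `"control"`) should carry true
#' log2FC 0.
#'
#' @param true_log2fc_by_group Named numeric vector of true log2 fold
#'   changes, e.g. `c(control = 0, case = 0.81)`.
#' @param n_per_group Samples per group; scalar or named vector.
#' @param replicate_sd Technical SD of a single replicate Ct. Default
#'   0.15.
#' @param biological_sd Between-sample SD of true dCt within a group, in
#'   cycles (= log2 units). Default 0.25.
#' @param n_replicates Replicates per assay per sample. Default 3
#'   (triplicate).
#' @param baseline_dct Control-group mean dCt. Default 5.
#' @param sample_log2fc_offsets Optional named numeric vector of per-sample
#'   additions to the group's true log2FC, keyed by the generated sample id
#'   (`"<group>_<nn>"`). Used to couple a sample's expression to another
#'   per-sample quantity, e.g. its methylation pattern.
#' @param seed Integer seed.
#' @return List with `ct` (a [ct_table()]) and `truth` (true log2FC per
#'   group, per-sample true dCt, parameters, seed).
#' @export
generate_ct_cohort <- function(true_log2fc_by_group, n_per_group = 10,
                               replicate_sd = 0.15, biological_sd = 0.25,
                               n_replicates = 3, baseline_dct = 5,
                               sample_log2fc_offsets = NULL,
                               seed = 1L) {
  stopifnot(replicate_sd >= 0, biological_sd >= 0, n_replicates >= 1,
            !is.null(names(true_log2fc_by_group)))
  groups <- names(true_log2fc_by_group)
  if (length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(n_per_group, length(groups)), groups)
  }
  withr::with_seed(seed, {
    rows <- list()
    true_dct <- list()
    k <- 0L
    for (g in groups) {
      for (j in seq_len(n_per_group[[g]])) {
        k <- k + 1L
        sid <- sprintf("%s_%02d", g, j)
        ref_mean <- stats::rnorm(1, 18, 0.3)
        offset <- if (!is.null(sample_log2fc_offsets) &&
                      sid %in% names(sample_log2fc_offsets)) {
          sample_log2fc_offsets[[sid]]
        } else 0
        dct_i <- baseline_dct - true_log2fc_by_group[[g]] - offset +
          stats::rnorm(1, 0, biological_sd)
        tgt_mean <- ref_mean + dct_i
        true_dct[[sid]] <- dct_i
        for (assay in c("target", "reference")) {
          mu <- if (assay == "target") tgt_mean else ref_mean
          cts <- mu + stats::rnorm(n_replicates, 0, replicate_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, assay = assay,
            replicate = seq_len(n_replicates), ct = cts, group = g,
            subgroup = if (g %in% c("L", "M", "S")) g else "none",
            stringsAsFactors = FALSE
          )
        }
      }
    }
    ct <- ct_table(do.call(rbind, rows))
    list(ct = ct,
         truth = list(true_log2fc = as.list(true_log2fc_by_group),
                      true_dct = true_dct,
                      params = list(n_per_group = as.list(n_per_group),
                                    replicate_sd = replicate_sd,
                                    biological_sd = biological_sd,
                                    n_replicates = n_replicates,
                                    baseline_dct = baseline_dct),
                      seed = seed))
  })
}

#' Couple relative expression to a methylation metric
#'
#' Generates per-sample relative expression with a planted population
#' correlation `rho` against one methylation metric: the metric is
#' standardized and expression is `mean_expr + sd_expr * (rho * z +
#' sqrt(1 - rho^2) * noise)`, floored just above zero.
#'
#' @param summaries A `methylation_summary` data frame.
#' @param metric Metric column coupled to expression. Default
#'   `"pct_uCmC"`.
#' @param rho Target correlation. Default 0.5.
#' @param mean_expr,sd_expr Location and scale of the expression values.
#' @param seed Integer seed.
#' @return Data frame with `sample_id` and `rel_expr`.
#' @export
couple_expression_to_methylation <- function(summaries,
                                             metric = "pct_uCmC",
                                             rho = 0.5, mean_expr = 1,
                                             sd_expr = 0.4, seed = 1L) {
  stopifnot(metric %in% names(summaries), abs(rho) <= 1)
  v <- summaries[[metric]]
  z <- (v - mean(v)) / stats::sd(v)
  withr::with_seed(seed, {
    eps <- stats::rnorm(length(z))
    rel <- mean_expr + sd_expr * (rho * z + sqrt(1 - rho^2) * eps)
    data.frame(sample_id = summaries$sample_id,
               rel_expr = pmax(rel, 1e-3), stringsAsFactors = FALSE)
  })
}

#' Serialize / load a simulation truth object
#'
#' @param truth Truth list from a generator.
#' @param path JSON path.
#' @return `path` invisibly; `read_truth` returns the list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
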