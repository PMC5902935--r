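#' @title Workflow driver
#' @name pipeline
#' @description Ties the stages into one deterministic run: DEG calling ->
#'   Alu enrichment -> cross-study overlap on expression inputs, and COBRA
#'   methylation -> qPCR fold changes -> group comparison / correlation on
#'   wet-lab-style inputs, whichever inputs the configuration provides.
#'   Every output table is plain TSV with a header comment carrying the
#'   package version and a configuration hash, so re-running the same
#'   configuration reproduces byte-identical outputs.
NULL

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

write_output_table <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with any
#' of these sections:
#' * `annotation`: path to the Alu insertion TSV (required with
#'   `studies`);
#' * `studies`: list of `list(study_id=, matrix=, samples=)` paths;
#' * `bands`: path to the COBRA band-intensity CSV;
#' * `ct`: path to the qPCR Ct CSV;
#' * `methylation_comparisons` / `expression_comparisons`: lists of
#'   `c(case_label, control_label)` pairs evaluated on the band / Ct
#'   group columns;
#' * `correlation_strata`: named list of group-label vectors; within each
#'   stratum, methylation metrics are correlated with `2^-ddCt`
#'   expression (both `bands` and `ct` required);
#' * scalars `alpha` (default 0.05), `cutoff` (0.70), `min_support` (2),
#'   `overlap_insertion_type` (`"all"`), `overlap_direction` (`"down"`),
#'   `expression_control_group` (`"control"`), `seed` (1), `out_dir`.
#'
#' @param config Named list or YAML path.
#' @return The validated configuration list, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || length(config) == 0L) {
    stop("empty configuration: nothing to run")
  }
  config$alpha <- config$alpha %||% 0.05
  config$cutoff <- config$cutoff %||% 0.70
  config$min_support <- config$min_support %||% 2L
  config$overlap_insertion_type <- config$overlap_insertion_type %||% "all"
  config$overlap_direction <- config$overlap_direction %||% "down"
  config$expression_control_group <- config$expression_control_group %||%
    "control"
  config$seed <- config$seed %||% 1L
  if (length(config$studies) == 0L) config$studies <- NULL
  if (is.null(config$studies) && is.null(config$bands) &&
      is.null(config$ct)) {
    stop("configuration provides no inputs (studies, bands or ct)")
  }
  if (!is.null(config$studies) && is.null(config$annotation)) {
    stop("'annotation' is required when 'studies' are given")
  }
  for (p in c(config$annotation, config$bands, config$ct,
              unlist(lapply(config$studies, function(s) c(s$matrix,
                                                          s$samples))))) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  config
}

#' Run the configured stages of the workflow
#'
#' Executes DEG calling, per-study Alu enrichment and the significance-
#' gated cross-study overlap when expression studies are configured, and
#' COBRA methylation summaries, qPCR fold changes, group comparisons and
#' methylation-expression correlation when band/Ct inputs are configured.
#' Progress is logged with per-stage record counts (genes filtered, DEGs,
#' significant strata, samples). Deterministic given the configuration.
#'
#' @param config Named list or YAML path; see [validate_config()].
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return Invisibly, a named list of the tables written (also serialized
#'   as TSV under `out_dir`, together with `config.yaml`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  header <- sprintf("# alupipe %s config=%s",
                    as.character(utils::packageVersion("alupipe")), hash)
  log_msg <- function(...) message("[alupipe] ", sprintf(...))
  outputs <- list()

  if (!is.null(config$studies)) {
    annotation <- load_insertion_table(config$annotation)
    log_msg("annotation: %d Alu-inserted genes",
            length(genes_with_type(annotation, "all")))
    deg_results <- list()
    enrichments <- list()
    for (s in config$studies) {
      study <- read_expression_study(s$matrix, s$samples,
                                     study_id = s$study_id)
      n_total <- nrow(study$matrix)
      study <- filter_presence(study, cutoff = config$cutoff)
      degs <- call_degs(study, alpha = config$alpha)
      log_msg("%s: %d/%d genes pass the %.0f%% presence filter, %d DEGs",
              s$study_id, nrow(study$matrix), n_total,
              100 * config$cutoff, sum(degs$is_deg))
      deg_results[[s$study_id]] <- degs
      enrichments[[s$study_id]] <-
        run_enrichment(degs, annotation, alpha = config$alpha)
      write_output_table(as.data.frame(degs),
                         file.path(out_dir,
                                   sprintf("degs_%s.tsv", s$study_id)),
                         header)
    }
    enr_all <- do.call(rbind, enrichments)
    rownames(enr_all) <- NULL
    log_msg("enrichment: %d/%d strata significant",
            sum(enr_all$significant), nrow(enr_all))
    outputs$enrichment <- enr_all
    write_output_table(enr_all, file.path(out_dir, "enrichment.tsv"), header)

    if (length(deg_results) >= 2L) {
      sets <- significant_alu_deg_sets(
        deg_results, enrichments, annotation,
        insertion_type = config$overlap_insertion_type,
        direction = config$overlap_direction)
      if (length(sets) >= 2L) {
        ov <- reproducible_overlap(sets, min_support = config$min_support)
        log_msg("overlap: %d genes supported by >= %d studies",
                length(ov$genes), config$min_support)
        outputs$overlap <- ov$support
        write_output_table(ov$support, file.path(out_dir, "overlap.tsv"),
                           header)
      } else {
        log_msg("overlap skipped: fewer than 2 studies passed gating")
      }
    }
    outputs$degs <- deg_results
  }

  summaries <- NULL
  if (!is.null(config$bands)) {
    profiles <- read_band_profiles(config$bands)
    summaries <- compute_methylation(profiles)
    log_msg("COBRA: %d lanes quantified", nrow(summaries))
    outputs$methylation <- summaries
    write_output_table(as.data.frame(summaries),
                       file.path(out_dir, "methylation.tsv"), header)
    if (!is.null(config$methylation_comparisons)) {
      cmp <- do.call(rbind, lapply(config$methylation_comparisons,
                                   function(pair) {
        compare_methylation(summaries, profiles$group,
                            case_label = pair[[1L]],
                            control_label = pair[[2L]])
      }))
      rownames(cmp) <- NULL
      log_msg("methylation comparisons: %d/%d metric tests significant",
              sum(cmp$adj_p < config$alpha), nrow(cmp))
      outputs$methylation_comparisons <- cmp
      write_output_table(cmp,
                         file.path(out_dir, "methylation_comparisons.tsv"),
                         header)
    }
  }

  expr <- NULL
  if (!is.null(config$ct)) {
    ct <- read_ct_table(config$ct)
    expr <- relative_expression(ct,
                                control_label = config$expression_control_group)
    if (!is.null(config$expression_comparisons)) {
      fc <- run_fold_changes(ct, config$expression_comparisons)
      log_msg("qPCR: %d comparisons, %d significant after BH",
              nrow(fc), sum(fc$adj_p < config$alpha))
      outputs$fold_changes <- fc
      write_output_table(fc, file.path(out_dir, "qpcr.tsv"), header)
    }
    outputs$relative_expression <- expr
    write_output_table(expr, file.path(out_dir, "relative_expression.tsv"),
                       header)
  }

  if (!is.null(summaries) && !is.null(expr) &&
      !is.null(config$correlation_strata)) {
    groups <- read_band_profiles(config$bands)$group
    cors <- do.call(rbind, lapply(names(config$correlation_strata),
                                  function(nm) {
      ids <- summaries$sample_id[groups %in%
                                   config$correlation_strata[[nm]]]
      res <- correlate_methylation_expression(summaries, expr,
                                              samples = ids)
      cbind(stratum = nm, res$table, stringsAsFactors = FALSE)
    }))
    rownames(cors) <- NULL
    log_msg("correlation: %d stratum x metric coefficients", nrow(cors))
    outputs$correlation <- cors
    write_output_table(cors, file.path(out_dir, "correlation.tsv"), header)
  }

  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(outputs)
}
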