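#' @title Group comparisons and methylation-expression correlation
#' @name integration
#' @description Compares COBRA methylation summaries between groups
#'   (unpaired two-tailed t-tests, BH-adjusted across the five metrics of
#'   one comparison) and correlates methylation patterns with AluS relative
#'   expression within phenotypic strata.
NULL

METHYLATION_METRICS <- c("pct_mC", "pct_mCmC", "pct_uCmC", "pct_mCuC",
                         "pct_uCuC")

# stats::t.test refuses essentially-constant data; degenerate groups with
# equal means carry no evidence (p = 1), unequal constant groups are an
# extreme (p ~ 0)
two_sample_t_p <- function(x, y, var_equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Compare methylation summaries between two groups
#'
#' For each of the five metrics (methylation level and four patterns), an
#' unpaired two-tailed t-test between the groups; BH adjustment is applied
#' across the five metrics of this one comparison (the per-comparison
#' multiplicity family). Samples with an undefined value for a metric are
#' dropped for that metric with a warning.
#'
#' @param summaries A `methylation_summary` data frame ([compute_methylation()])
#'   with a `sample_id` column.
#' @param groups Either a character vector of group labels aligned with the
#'   rows of `summaries`, or a data frame with `sample_id` and `group`.
#' @param case_label,control_label The two labels compared.
#' @param comparison Label stored in the result.
#' @param var_equal Pooled-variance t-test by default.
#' @return Data frame of class `subgroup_comparison` with one row per
#'   metric: means and SDs per group, `n_case`, `n_control`, `raw_p`,
#'   `adj_p`.
#' @export
compare_methylation <- function(summaries, groups,
                                case_label = "case",
                                control_label = "control",
                                comparison = paste(case_label, "vs",
                                                   control_label),
                                var_equal = TRUE) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    groups <- groups$group[match(summaries$sample_id, groups$sample_id)]
  }
  if (length(groups) != nrow(summaries)) {
    stop("group assignment does not match the summaries")
  }
  sel_case <- groups == case_label
  sel_ctrl <- groups == control_label
  if (any(sel_case & sel_ctrl)) stop("groups must be disjoint")
  if (sum(sel_case) < 2L || sum(sel_ctrl) < 2L) {
    stop("need at least 2 samples per group")
  }
  rows <- lapply(METHYLATION_METRICS, function(metric) {
    v <- summaries[[metric]]
    if (anyNA(v[sel_case | sel_ctrl])) {
      warning("dropping sample(s) with undefined ", metric)
    }
    x <- v[sel_case]; x <- x[is.finite(x)]
    y <- v[sel_ctrl]; y <- y[is.finite(y)]
    data.frame(comparison = comparison, metric = metric,
               mean_case = mean(x), sd_case = stats::sd(x),
               mean_control = mean(y), sd_control = stats::sd(y),
               n_case = length(x), n_control = length(y),
               raw_p = two_sample_t_p(x, y, var_equal = var_equal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$raw_p)
  rownames(out) <- NULL
  class(out) <- c("subgroup_comparison", "data.frame")
  out
}

#' Correlate methylation patterns with AluS expression in a stratum
#'
#' Pearson correlation (optionally Spearman, since gel-derived percentages
#' may be non-normal) between each methylation metric and per-sample
#' relative expression, over the samples of one stratum. The scatter data
#' used for each coefficient are returned for export/plotting.
#'
#' @param summaries A `methylation_summary` data frame with `sample_id`.
#' @param expression Data frame with `sample_id` and `rel_expr` (per-sample
#'   relative expression, e.g. `2^-ddCt`).
#' @param samples Optional character vector of sample ids defining the
#'   stratum; default all matched samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List of class `correlation_result`: `table` (one row per
#'   metric: `metric`, `r`, `n`) and `scatter` (long data frame
#'   `sample_id`, `metric`, `methylation`, `rel_expr`).
#' @export
correlate_methylation_expression <- function(summaries, expression,
                                             samples = NULL,
                                             method = c("pearson",
                                                        "spearman")) {
  method <- match.arg(method)
  stopifnot(all(c("sample_id", "rel_expr") %in% names(expression)))
  ids <- intersect(summaries$sample_id, expression$sample_id)
  if (!is.null(samples)) ids <- intersect(ids, samples)
  if (length(ids) < 3L) stop("need at least 3 matched samples in the stratum")
  s <- summaries[match(ids, summaries$sample_id), , drop = FALSE]
  e <- expression$rel_expr[match(ids, expression$sample_id)]
  rows <- lapply(METHYLATION_METRICS, function(metric) {
    v <- s[[metric]]
    ok <- is.finite(v) & is.finite(e)
    r <- if (sum(ok) < 3L) {
      NA_real_
    } else if (method == "pearson") {
      pearson_r(v[ok], e[ok])
    } else {
      stats::cor(v[ok], e[ok], method = "spearman")
    }
    data.frame(metric = metric, r = r, n = sum(ok), stringsAsFactors = FALSE)
  })
  scatter <- do.call(rbind, lapply(METHYLATION_METRICS, function(metric) {
    data.frame(sample_id = ids, metric = metric, methylation = s[[metric]],
               rel_expr = e, stringsAsFactors = FALSE)
  }))
  structure(list(table = do.call(rbind, rows), scatter = scatter,
                 method = method, samples = ids),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Methylation-expression correlation (%s, n = %d):\n",
              x$method, length(x$samples)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
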