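#' @title AluS expression by the 2^-ddCt method
#' @name qpcr
#' @description Relative quantification of AluS transcript levels from
#'   qPCR Ct tables: replicate Ct values for the AluS target and the GAPDH
#'   reference are averaged per sample, normalized to the reference (dCt),
#'   then to the control group's mean dCt (ddCt); relative expression is
#'   `2^-ddCt` and the group fold change is `2^(-mean ddCt of the case
#'   group)`.
NULL

#' Construct / validate a Ct table
#'
#' @param df Data frame with columns `sample_id`, `assay`
#'   (`"target"`/`"reference"`), `replicate`, `ct`, `group`, and optionally
#'   `subgroup`.
#' @return The validated data frame (class `ct_table`).
#' @export
ct_table <- function(df) {
  need <- c("sample_id", "assay", "replicate", "ct", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"subgroup" %in% names(df)) df$subgroup <- "none"
  df$assay <- tolower(as.character(df$assay))
  bad <- setdiff(unique(df$assay), c("target", "reference"))
  if (length(bad)) stop("unknown assay label(s): ", paste(bad, collapse = ", "))
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("Ct values must be positive and finite")
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Read a Ct table from CSV
#'
#' @param path CSV with columns `sample_id`, `assay`, `replicate`, `ct`,
#'   `group`, `subgroup`.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path) {
  ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a Ct table to CSV
#' @param ct A [ct_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-sample dCt: target normalized to the reference gene
#'
#' `dCt = mean(replicate Ct, target) - mean(replicate Ct, reference)`.
#' Samples missing either assay are excluded with a warning.
#'
#' @param ct A [ct_table()].
#' @return Data frame with one row per sample: `sample_id`, `group`,
#'   `subgroup`, `ct_target`, `ct_reference`, `dct`.
#' @export
delta_ct <- function(ct) {
  ct <- ct_table(ct)
  agg <- stats::aggregate(ct ~ sample_id + assay, data = ct, FUN = mean)
  wide <- stats::reshape(agg, idvar = "sample_id", timevar = "assay",
                         direction = "wide")
  names(wide) <- sub("^ct\\.", "ct_", names(wide))
  if (!"ct_target" %in% names(wide)) wide$ct_target <- NA_real_
  if (!"ct_reference" %in% names(wide)) wide$ct_reference <- NA_real_
  meta <- unique(ct[, c("sample_id", "group", "subgroup")])
  out <- merge(meta, wide, by = "sample_id", sort = TRUE)
  drop <- !is.finite(out$ct_target) | !is.finite(out$ct_reference)
  if (any(drop)) {
    warning("excluding sample(s) missing an assay: ",
            paste(out$sample_id[drop], collapse = ", "))
    out <- out[!drop, , drop = FALSE]
  }
  out$dct <- out$ct_target - out$ct_reference
  rownames(out) <- NULL
  out
}

#' Group fold change by the 2^-ddCt method
#'
#' Per-sample `ddCt = dCt - mean(dCt of the control group)` and relative
#' expression `2^-ddCt`; the group fold change is `2^(-mean ddCt of the
#' case group)` -- the geometric mean of per-sample relative expression --
#' with `log2_fc = -mean(ddCt case)`. The group difference p-value comes
#' from a two-tailed t-test on the (approximately normal) dCt values, not
#' on exponentiated fold changes.
#'
#' @param ct A [ct_table()].
#' @param case_label,control_label Group labels compared.
#' @param fc_method `"geometric"` (default; consistent with `2^-mean ddCt`)
#'   or `"arithmetic"` (ratio of arithmetic means of per-sample relative
#'   expression).
#' @param var_equal Passed to [stats::t.test()]; pooled variance by
#'   default.
#' @return An object of class `fold_change_result`: a list with
#'   `comparison`, `fold_change`, `log2_fc`, `raw_p`, `n_case`,
#'   `n_control`, and `samples` (per-sample `dct`, `ddct`, `rel_expr`).
#' @export
fold_change <- function(ct, case_label = "case", control_label = "control",
                        fc_method = c("geometric", "arithmetic"),
                        var_equal = TRUE) {
  fc_method <- match.arg(fc_method)
  d <- delta_ct(ct)
  d <- d[d$group %in% c(case_label, control_label), , drop = FALSE]
  n_case <- sum(d$group == case_label)
  n_control <- sum(d$group == control_label)
  if (n_case < 2L || n_control < 2L) {
    stop("need at least 2 samples per group (",
         case_label, ": ", n_case, ", ", control_label, ": ", n_control, ")")
  }
  d$ddct <- d$dct - mean(d$dct[d$group == control_label])
  d$rel_expr <- 2^(-d$ddct)
  log2_fc <- -mean(d$ddct[d$group == case_label])
  fc <- if (fc_method == "geometric") {
    2^log2_fc
  } else {
    mean(d$rel_expr[d$group == case_label]) /
      mean(d$rel_expr[d$group == control_label])
  }
  if (fc_method == "arithmetic") log2_fc <- log2(fc)
  p <- two_sample_t_p(d$dct[d$group == case_label],
                      d$dct[d$group == control_label],
                      var_equal = var_equal)
  structure(list(comparison = paste(case_label, "vs", control_label),
                 fold_change = fc, log2_fc = log2_fc, raw_p = p,
                 n_case = n_case, n_control = n_control, samples = d),
            class = "fold_change_result")
}

#' Per-sample relative expression against a control group
#'
#' `2^-ddCt` per sample, with `ddCt = dCt - mean(dCt of the control
#' group)`; control samples average to relative expression 1 on the log
#' scale.
#'
#' @param ct A [ct_table()].
#' @param control_label Group whose mean dCt anchors the normalization.
#' @return Data frame with `sample_id`, `group`, `subgroup`, `dct`,
#'   `ddct`, `rel_expr`.
#' @export
relative_expression <- function(ct, control_label = "control") {
  d <- delta_ct(ct)
  if (!any(d$group == control_label)) {
    stop("no samples in control group '", control_label, "'")
  }
  d$ddct <- d$dct - mean(d$dct[d$group == control_label])
  d$rel_expr <- 2^(-d$ddct)
  d[, c("sample_id", "group", "subgroup", "dct", "ddct", "rel_expr")]
}

#' Run several fold-change comparisons with BH adjustment
#'
#' @param ct A [ct_table()].
#' @param comparisons Named list of `c(case_label, control_label)` pairs.
#' @param ... Passed to [fold_change()].
#' @return Data frame with one row per comparison: `comparison`,
#'   `fold_change`, `log2_fc`, `raw_p`, `adj_p` (BH across the comparisons
#'   run together), `n_case`, `n_control`.
#' @export
run_fold_changes <- function(ct, comparisons, ...) {
  if (!length(comparisons)) stop("no comparisons given")
  res <- lapply(comparisons, function(cmp) {
    fold_change(ct, case_label = cmp[[1L]], control_label = cmp[[2L]], ...)
  })
  out <- data.frame(
    comparison = vapply(res, `[[`, character(1), "comparison"),
    fold_change = vapply(res, `[[`, numeric(1), "fold_change"),
    log2_fc = vapply(res, `[[`, numeric(1), "log2_fc"),
    raw_p = vapply(res, `[[`, numeric(1), "raw_p"),
    n_case = vapply(res, `[[`, numeric(1), "n_case"),
    n_control = vapply(res, `[[`, numeric(1), "n_control"),
    stringsAsFactors = FALSE
  )
  out$adj_p <- bh_adjust(out$raw_p)
  out <- out[, c("comparison", "fold_change", "log2_fc", "raw_p", "adj_p",
                 "n_case", "n_control")]
  rownames(out) <- NULL
  out
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("%s: FC = %.3f, log2FC = %.3f, p = %.4g (n = %d vs %d)\n",
              x$comparison, x$fold_change, x$log2_fc, x$raw_p,
              x$n_case, x$n_control))
  invisible(x)
}
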