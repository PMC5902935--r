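#' @title Differential expression on blood transcriptome matrices
#' @name deg
#' @description Presence filtering (70% cutoff by default) and
#'   differentially-expressed-gene calling with two-tailed two-sample
#'   t-tests and Bonferroni adjustment, with up/down direction labels.
NULL

#' Construct an expression study
#'
#' @param matrix Numeric genes x samples matrix with gene symbols as row
#'   names and sample ids as column names; missing intensities are `NA`.
#' @param samples Data frame with columns `sample_id`, `group` (values
#'   `"case"`/`"control"`) and optionally `subgroup` (`"L"`, `"M"`, `"S"` or
#'   `"none"`).
#' @param study_id Study label carried through result tables.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(matrix, samples, study_id = "study") {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("'matrix' must be a numeric matrix")
  }
  if (is.null(rownames(matrix))) stop("matrix must have gene row names")
  if (anyDuplicated(rownames(matrix))) stop("gene identifiers must be unique")
  if (is.null(colnames(matrix))) stop("matrix must have sample column names")
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("'samples' must have columns sample_id and group")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"subgroup" %in% names(samples)) samples$subgroup <- "none"
  if (!setequal(colnames(matrix), samples$sample_id) ||
      ncol(matrix) != nrow(samples)) {
    stop("matrix columns and sample sheet do not match")
  }
  samples <- samples[match(colnames(matrix), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  bad <- setdiff(unique(samples$group), c("case", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (min(table(factor(samples$group, c("case", "control")))) < 2L) {
    warning("fewer than 2 samples in a compared group")
  }
  structure(list(matrix = matrix, samples = samples, study_id = study_id),
            class = "expression_study")
}

#' Read an expression study from TSV files
#'
#' The matrix TSV has gene symbols in the first column and one column per
#' sample, with the literal string `NA` for missing intensities. The sample
#' sheet TSV has columns `sample_id`, `group`, and optionally `subgroup`.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @param study_id Study label.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(matrix_path, samples_path,
                                  study_id = basename(matrix_path)) {
  mt <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(mt) < 2L) stop("matrix file needs a gene column plus samples: ",
                          matrix_path)
  genes <- toupper(as.character(mt[[1L]]))
  m <- as.matrix(mt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  ss <- utils::read.delim(samples_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  expression_study(m, ss, study_id = study_id)
}

#' Write an expression study to TSV files
#'
#' @param study An `expression_study`.
#' @param matrix_path,samples_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_study <- function(study, matrix_path, samples_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Presence filter: drop genes missing in too many samples
#'
#' Retains genes whose non-missing fraction across all samples (both groups
#' jointly) is at least `cutoff`; the default 0.70 removes transcripts with
#' intensities missing in more than 30% of samples. The boundary is
#' inclusive: a gene observed in exactly 70% of samples is kept. Gene order
#' is preserved.
#'
#' @param study An `expression_study`.
#' @param cutoff Minimum non-missing fraction, in `(0, 1]`. Default 0.70.
#' @return The filtered `expression_study`.
#' @export
filter_presence <- function(study, cutoff = 0.70) {
  stopifnot(inherits(study, "expression_study"))
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]")
  frac <- rowMeans(!is.na(study$matrix))
  keep <- frac >= cutoff
  if (!any(keep)) warning("presence filter removed every gene")
  study$matrix <- study$matrix[keep, , drop = FALSE]
  study
}

# Vectorized per-row two-sample t-test with pairwise NA omission.
# Cross-checked against stats::t.test in the test suite.
row_t_test <- function(X, case_cols, control_cols, var_equal = TRUE) {
  X1 <- X[, case_cols, drop = FALSE]
  X2 <- X[, control_cols, drop = FALSE]
  n1 <- rowSums(!is.na(X1))
  n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE)
  m2 <- rowMeans(X2, na.rm = TRUE)
  v1 <- rowSums((X1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((X2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  ok <- n1 >= 2 & n2 >= 2
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate: no within-group variance anywhere
  zero_se <- ok & !is.na(se) & se == 0
  p[zero_se & (m1 == m2)] <- 1
  p[zero_se & (m1 != m2)] <- 0
  p[!ok] <- NA_real_
  list(p = p, mean_case = m1, mean_control = m2,
       n_case = n1, n_control = n2, tested = ok)
}

#' Call differentially expressed genes
#'
#' Per-gene two-tailed two-sample t-test (Student pooled-variance by
#' default, Welch optionally) on non-missing values, Bonferroni adjustment
#' over the number of genes actually tested, and a direction label from the
#' sign of `mean(case) - mean(control)`. Genes with fewer than two
#' non-missing values in either group are excluded from testing and flagged
#' (`tested = FALSE`); they do not count toward the Bonferroni factor.
#' Missing values are omitted pairwise, never imputed.
#'
#' @param study An `expression_study`, already presence-filtered.
#' @param alpha Significance level on the adjusted p-value. Default 0.05.
#' @param var_equal Use the pooled-variance Student t-test (default `TRUE`);
#'   `FALSE` switches to Welch.
#' @return An object of class `deg_result`: a data frame with columns
#'   `gene`, `mean_case`, `mean_control`, `direction` (`"up"`/`"down"`),
#'   `raw_p`, `adj_p`, `is_deg`, `tested`, plus attributes `study_id`,
#'   `n_tested`, `alpha` and `universe` (the tested gene set).
#' @export
call_degs <- function(study, alpha = 0.05, var_equal = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  g <- study$samples$group
  res <- row_t_test(study$matrix,
                    case_cols = which(g == "case"),
                    control_cols = which(g == "control"),
                    var_equal = var_equal)
  out <- data.frame(
    gene = rownames(study$matrix),
    mean_case = res$mean_case,
    mean_control = res$mean_control,
    direction = ifelse(res$mean_case - res$mean_control > 0, "up", "down"),
    raw_p = res$p,
    adj_p = NA_real_,
    is_deg = FALSE,
    tested = res$tested,
    stringsAsFactors = FALSE
  )
  if (any(!res$tested)) {
    warning(sum(!res$tested),
            " gene(s) with <2 values in a group excluded from testing")
    out$direction[!res$tested] <- NA_character_
  }
  m <- sum(res$tested)
  if (m > 0L) {
    out$adj_p[res$tested] <- bonferroni_adjust(out$raw_p[res$tested])
    out$is_deg <- !is.na(out$adj_p) & out$adj_p < alpha
  }
  rownames(out) <- NULL
  structure(out,
            study_id = study$study_id, n_tested = m, alpha = alpha,
            universe = out$gene[out$tested],
            class = c("deg_result", "data.frame"))
}

#' Gene sets from a DEG result
#'
#' @param deg_result A `deg_result`.
#' @param direction `"all"`, `"up"` or `"down"`.
#' @return Character vector of DEG gene symbols in that direction.
#' @export
deg_genes <- function(deg_result, direction = "all") {
  stopifnot(inherits(deg_result, "deg_result"))
  direction <- match.arg(direction, c("all", "up", "down"))
  sel <- deg_result$is_deg
  if (direction != "all") sel <- sel & deg_result$direction == direction
  sort(deg_result$gene[sel %in% TRUE])
}

#' Collapse probe-level rows to one row per gene
#'
#' Optional pre-processing for probe-level matrices: keeps, per gene, the
#' probe with the smallest raw p-value in a preliminary t-test. Off the
#' main path; input to [call_degs()] is assumed gene-level.
#'
#' @param study An `expression_study` whose row names are
#'   `"GENE|probe_id"` pairs (pipe-separated).
#' @param var_equal Passed to the preliminary test.
#' @return An `expression_study` with one row per gene.
#' @export
collapse_probes <- function(study, var_equal = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  ids <- rownames(study$matrix)
  gene <- toupper(sub("\\|.*$", "", ids))
  if (!anyDuplicated(gene)) {
    rownames(study$matrix) <- gene
    return(study)
  }
  g <- study$samples$group
  res <- row_t_test(study$matrix, which(g == "case"), which(g == "control"),
                    var_equal = var_equal)
  p <- res$p
  p[is.na(p)] <- Inf
  ord <- order(gene, p)
  keep <- ord[!duplicated(gene[ord])]
  keep <- sort(keep) # preserve original row order
  study$matrix <- study$matrix[keep, , drop = FALSE]
  rownames(study$matrix) <- gene[keep]
  study
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("DEG result for %s: %d genes tested, %d DEGs (%d up, %d down) at adj_p < %g\n",
              attr(x, "study_id"), attr(x, "n_tested"),
              sum(x$is_deg), length(deg_genes(x, "up")),
              length(deg_genes(x, "down")), attr(x, "alpha")))
  invisible(x)
}
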