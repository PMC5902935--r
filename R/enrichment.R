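#' @title DEG / Alu-insertion enrichment and cross-study overlap
#' @name enrichment
#' @description Tests whether DEG lists are associated with Alu-inserted
#'   genes via 2x2 crosstabs and Fisher's exact test, stratified by
#'   insertion type and regulation direction, with BH adjustment across the
#'   strata of one study; and intersects per-study significant gene lists
#'   into a reproducible (multi-study) gene set.
NULL

#' Build the DEG/Alu 2x2 crosstab
#'
#' Classifies the gene universe into DEGs with Alu insertion (`a`), DEGs
#' without (`b`), non-DEGs with (`c`) and non-DEGs without (`d`). The Alu
#' set is intersected with the universe before counting, so membership is
#' conditioned on testability.
#'
#' @param degs Character vector of DEG symbols; must be a subset of
#'   `universe`.
#' @param universe Character vector: the tested (post-filter) gene set.
#' @param alu_genes Character vector of Alu-inserted gene symbols.
#' @return Named integer vector `c(a, b, c, d)` summing to
#'   `length(unique(universe))`.
#' @export
build_crosstab <- function(degs, universe, alu_genes) {
  degs <- unique(as.character(degs))
  universe <- unique(as.character(universe))
  alu_genes <- unique(as.character(alu_genes))
  extra <- setdiff(degs, universe)
  if (length(extra)) {
    stop("DEGs not in universe: ",
         paste(utils::head(extra, 5L), collapse = ", "),
         if (length(extra) > 5L) sprintf(" (and %d more)", length(extra) - 5L))
  }
  alu <- intersect(alu_genes, universe)
  a <- length(intersect(degs, alu))
  b <- length(degs) - a
  c_ <- length(alu) - a
  d <- length(universe) - a - b - c_
  c(a = a, b = b, c = c_, d = d)
}

default_enrichment_strata <- function() {
  expand.grid(insertion_type = c("all", "intronic", "exonized", "exonic",
                                 "promoter"),
              direction = c("all", "up", "down"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run Alu-insertion enrichment over strata of one study
#'
#' For each (insertion type, direction) stratum the DEGs of that stratum
#' are crosstabbed against the Alu-inserted genes of that type within the
#' study's tested universe and tested with the two-sided Fisher exact test.
#' BH adjustment is applied across the strata of this one study (the
#' per-study multiplicity family). A stratum with no DEGs has a zero margin,
#' `p = 1`, and is flagged `empty`.
#'
#' @param deg_result A [call_degs()] result.
#' @param annotation An [alu_insertion_table()].
#' @param universe Tested gene set; defaults to the `deg_result` universe.
#' @param strata Data frame with columns `insertion_type` and `direction`;
#'   defaults to all 5 types x all/up/down = 15 strata.
#' @param alpha Significance threshold on the adjusted p-value. Default
#'   0.05.
#' @return A data frame of class `enrichment_result` with one row per
#'   stratum: `study_id`, `insertion_type`, `direction`, cells `a`-`d`,
#'   `n_deg`, `n_overlap` (= `a`), `raw_p`, `adj_p`, `significant`,
#'   `empty`.
#' @export
run_enrichment <- function(deg_result, annotation,
                           universe = attr(deg_result, "universe"),
                           strata = default_enrichment_strata(),
                           alpha = 0.05) {
  stopifnot(inherits(deg_result, "deg_result"),
            inherits(annotation, "alu_insertion_table"))
  if (is.null(strata) || nrow(strata) == 0L) stop("strata must be non-empty")
  universe <- unique(as.character(universe))
  rows <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    tp <- strata$insertion_type[i]
    dir <- strata$direction[i]
    degs <- deg_genes(deg_result, dir)
    degs <- intersect(degs, universe)
    alu <- genes_with_type(annotation, tp)
    ct <- build_crosstab(degs, universe, alu)
    p <- fisher_exact_two_sided(ct["a"], ct["b"], ct["c"], ct["d"])
    rows[[i]] <- data.frame(
      study_id = attr(deg_result, "study_id"),
      insertion_type = tp, direction = dir,
      a = ct[["a"]], b = ct[["b"]], c = ct[["c"]], d = ct[["d"]],
      n_deg = length(degs), n_overlap = ct[["a"]],
      raw_p = p, empty = length(degs) == 0L,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$raw_p)
  out$significant <- out$adj_p < alpha & !out$empty
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Per-study significant Alu-inserted DEG sets
#'
#' The cross-study reproducibility step intersects, per study, the DEGs of
#' one direction that carry an Alu insertion of one type -- but only for
#' studies whose corresponding enrichment stratum was significant
#' (significance gating). Defaults follow the downregulated, all-insertion
#' choice.
#'
#' @param deg_results Named list of `deg_result` objects (names = study
#'   ids).
#' @param enrichments Named list of matching [run_enrichment()] results.
#' @param annotation An [alu_insertion_table()].
#' @param insertion_type,direction The stratum used for gating and set
#'   construction. Defaults `"all"`, `"down"`.
#' @return Named list of gene sets, one per study that passed gating.
#' @export
significant_alu_deg_sets <- function(deg_results, enrichments, annotation,
                                     insertion_type = "all",
                                     direction = "down") {
  stopifnot(length(deg_results) == length(enrichments),
            !is.null(names(deg_results)))
  alu <- genes_with_type(annotation, insertion_type)
  sets <- list()
  for (sid in names(deg_results)) {
    enr <- enrichments[[sid]]
    row <- enr[enr$insertion_type == insertion_type &
                 enr$direction == direction, , drop = FALSE]
    if (nrow(row) != 1L) stop("stratum not found for study ", sid)
    if (!isTRUE(row$significant)) next
    sets[[sid]] <- intersect(deg_genes(deg_results[[sid]], direction), alu)
  }
  sets
}

#' Cross-study reproducible gene set
#'
#' Genes supported by at least `min_support` of the per-study gene sets,
#' with per-gene study provenance.
#'
#' @param per_study_sets Named list mapping study id to a character vector
#'   of gene symbols.
#' @param min_support Minimum number of supporting studies. Default 2.
#' @return An object of class `reproducible_gene_set`: a list with
#'   `genes` (character), `support` (data frame `gene`,
#'   `supporting_studies`, `support_count`) and `min_support`.
#' @export
reproducible_overlap <- function(per_study_sets, min_support = 2L) {
  if (length(per_study_sets) < 2L) stop("need at least 2 studies")
  if (is.null(names(per_study_sets)) || any(names(per_study_sets) == "")) {
    stop("per_study_sets must be named by study id")
  }
  if (min_support > length(per_study_sets)) {
    warning("min_support exceeds the number of studies; empty set")
  }
  long <- data.frame(
    study = rep(names(per_study_sets), lengths(per_study_sets)),
    gene = unlist(lapply(per_study_sets, function(g) unique(as.character(g))),
                  use.names = FALSE),
    stringsAsFactors = FALSE
  )
  support <- if (nrow(long)) {
    agg <- stats::aggregate(study ~ gene, data = long, FUN = function(s) {
      paste(sort(unique(s)), collapse = ",")
    })
    cnt <- stats::aggregate(study ~ gene, data = long,
                            FUN = function(s) length(unique(s)))
    data.frame(gene = agg$gene, supporting_studies = agg$study,
               support_count = cnt$study, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), supporting_studies = character(0),
               support_count = integer(0), stringsAsFactors = FALSE)
  }
  support <- support[order(-support$support_count, support$gene), ,
                     drop = FALSE]
  rownames(support) <- NULL
  keep <- support[support$support_count >= min_support, , drop = FALSE]
  structure(list(genes = sort(keep$gene), support = support,
                 min_support = as.integer(min_support)),
            class = "reproducible_gene_set")
}

#' @export
print.reproducible_gene_set <- function(x, ...) {
  cat(sprintf("Reproducible gene set: %d genes in >= %d studies (of %d candidates)\n",
              length(x$genes), x$min_support, nrow(x$support)))
  invisible(x)
}
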