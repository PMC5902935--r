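#' @title Alu insertion annotation
#' @name annotation
#' @description Load, validate and query gene lists annotated with Alu
#'   insertion types (TranspoGene-style: exonic, exonized, intronic,
#'   promoter). A single gene may carry several insertion types, so the
#'   number of distinct genes is at most the sum of the per-type counts.
NULL

#' The four recognised Alu insertion types
#' @export
ALU_INSERTION_TYPES <- c("exonic", "exonized", "intronic", "promoter")

#' Construct an Alu insertion table from a (gene, insertion_type) data frame
#'
#' Gene symbols are uppercased, types lowercased and validated, duplicate
#' (gene, type) rows collapsed. Gene identity is the uppercased symbol
#' string; no alias resolution is attempted.
#'
#' @param df Data frame with character columns `gene` and `insertion_type`
#'   (one row per gene-type pair).
#' @return An object of class `alu_insertion_table`: a canonicalised long
#'   data frame with columns `gene` and `insertion_type`.
#' @export
alu_insertion_table <- function(df) {
  if (!is.data.frame(df) || !all(c("gene", "insertion_type") %in% names(df))) {
    stop("expected a data frame with columns 'gene' and 'insertion_type'")
  }
  if (nrow(df) == 0L) stop("insertion table is empty")
  gene <- toupper(trimws(as.character(df$gene)))
  type <- tolower(trimws(as.character(df$insertion_type)))
  bad <- which(!type %in% ALU_INSERTION_TYPES)
  if (length(bad)) {
    stop(sprintf("row %d: unknown insertion type '%s' (expected one of %s)",
                 bad[1L], type[bad[1L]],
                 paste(ALU_INSERTION_TYPES, collapse = ", ")))
  }
  if (any(gene == "")) stop("empty gene symbol")
  out <- unique(data.frame(gene = gene, insertion_type = type,
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene, out$insertion_type), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alu_insertion_table", "data.frame")
  out
}

#' Load an Alu insertion table from a TSV file
#'
#' Expected format: tab-separated with header `gene<TAB>insertion_type`,
#' one row per (gene, type) pair. Types are case-insensitive; duplicate
#' rows are collapsed.
#'
#' @param path Path to the TSV file.
#' @return An [alu_insertion_table()].
#' @export
load_insertion_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("insertion table file is empty: ", path)
  alu_insertion_table(df)
}

#' Write an Alu insertion table to TSV
#'
#' Inverse of [load_insertion_table()]; re-loading the written file yields
#' an identical table.
#'
#' @param table An `alu_insertion_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_insertion_table <- function(table, path) {
  stopifnot(inherits(table, "alu_insertion_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genes carrying a given insertion type
#'
#' `"all"` returns every gene in the table (the union over the four types,
#' not a separate input list, so the all-type count is at most the sum of
#' the per-type counts).
#'
#' @param table An `alu_insertion_table`.
#' @param type One of `"all"`, `"exonic"`, `"exonized"`, `"intronic"`,
#'   `"promoter"`.
#' @return A character vector of gene symbols (sorted, unique).
#' @export
genes_with_type <- function(table, type = "all") {
  stopifnot(inherits(table, "alu_insertion_table"))
  type <- tolower(type)
  if (!type %in% c("all", ALU_INSERTION_TYPES)) {
    stop("invalid insertion type: '", type, "'")
  }
  if (type == "all") {
    sort(unique(table$gene))
  } else {
    sort(unique(table$gene[table$insertion_type == type]))
  }
}

#' Per-type and total gene counts of an insertion table
#'
#' @param table An `alu_insertion_table`.
#' @return Named integer vector with entries `all` and one per insertion
#'   type.
#' @export
alu_type_counts <- function(table) {
  counts <- vapply(c("all", ALU_INSERTION_TYPES),
                   function(tp) length(genes_with_type(table, tp)),
                   integer(1))
  counts
}

#' @export
print.alu_insertion_table <- function(x, ...) {
  counts <- alu_type_counts(x)
  cat("Alu insertion table:", counts[["all"]], "genes\n")
  for (tp in ALU_INSERTION_TYPES) {
    cat(sprintf("  %-9s %d\n", tp, counts[[tp]]))
  }
  invisible(x)
}
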