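#' Normalize gene symbols
#'
#' Uppercases and trims surrounding whitespace. No alias or ortholog mapping
#' is attempted: the published gene lists are symbol-level, so identity of
#' symbols (case-insensitively) is the only equivalence applied. The
#' operation is idempotent.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' normalize_gene_symbols(c(" Il5ra", "RNASE2 "))
normalize_gene_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct an expression matrix
#'
#' A thin container for a genes x samples intensity matrix together with a
#' declared scale. The scale is never auto-detected: callers must state
#' whether values are linear intensities or log2 intensities, and all
#' fold-change computations convert accordingly.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `eos_expr` with elements `values` and `scale`.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  rownames(values) <- normalize_gene_symbols(rownames(values))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids after symbol normalization; ",
         "use read_expression_matrix() or collapse_duplicate_genes() first")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("all expression values must be finite")
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale values must be non-negative")
  }
  structure(list(values = values, scale = scale), class = "eos_expr")
}

#' @export
print.eos_expr <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.eos_expr <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `eos_expr` object.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Convert an expression matrix to linear scale
#'
#' @param x An `eos_expr` object.
#' @return An `eos_expr` on linear scale (`2^value` applied if needed).
#' @export
as_linear <- function(x) {
  stopifnot(inherits(x, "eos_expr"))
  if (x$scale == "linear") return(x)
  expression_matrix(2^x$values, scale = "linear")
}

#' Collapse duplicate gene rows
#'
#' After symbol normalization several input rows (e.g. alternate-case
#' symbols or multiple probes annotated to one gene) can map to one gene.
#' They are collapsed to a single row, by default taking the per-sample
#' maximum — i.e. keeping the most responsive probe per gene, which is
#' conservative for fold-change selection because it never splits signal
#' across rows.
#'
#' @param values Numeric matrix whose rownames are already normalized.
#' @param collapse `"max"` (default) or `"mean"`.
#' @return Matrix with unique rownames; emits a message per collapsed symbol.
#' @export
collapse_duplicate_genes <- function(values, collapse = c("max", "mean")) {
  collapse <- match.arg(collapse)
  ids <- rownames(values)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) == 0) return(values)
  fun <- if (collapse == "max") max else mean
  keep <- !duplicated(ids)
  out <- values[keep, , drop = FALSE]
  for (g in dup) {
    rows <- values[ids == g, , drop = FALSE]
    out[g, ] <- apply(rows, 2, fun)
  }
  message(sprintf("collapsed %d duplicate gene row(s) (%s): %s",
                  sum(duplicated(ids)), collapse,
                  paste(dup, collapse = ", ")))
  out
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids, a first column of gene identifiers,
#' and numeric intensities in the body. Gene symbols are normalized
#' (uppercase, trimmed) and duplicate rows collapsed per `collapse`.
#'
#' @param path Path to a TSV file (`gene_id<TAB>sample1<TAB>...`).
#' @param scale Declared scale of the stored values: `"linear"` or `"log2"`.
#' @param collapse Duplicate-row policy, `"max"` (default) or `"mean"`.
#' @return An `eos_expr` object.
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2"),
                                   collapse = c("max", "mean")) {
  scale <- match.arg(scale)
  collapse <- match.arg(collapse)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no genes: file has an empty data section")
  if (ncol(raw) < 2) stop("no samples: file needs at least one sample column")
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample_id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  genes_raw <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(body)))
  )
  num <- matrix(num, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(NULL, samples))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 genes_raw[bad[1, 1]], samples[bad[1, 2]]))
  }
  if (any(is.na(num))) stop("missing values are not supported")
  if (scale == "linear" && any(num < 0)) {
    i <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative linear value at gene '%s', sample '%s'",
                 genes_raw[i[1]], samples[i[2]]))
  }
  rownames(num) <- normalize_gene_symbols(genes_raw)
  num <- collapse_duplicate_genes(num, collapse)
  message(sprintf("read expression matrix: %d genes x %d samples from %s",
                  nrow(num), ncol(num), path))
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Output contract: tab separators, '.' decimal separator, UTF-8, LF line
#' endings, full double precision (values survive a read/write round trip
#' to at least 6 significant figures).
#'
#' @param x An `eos_expr` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "eos_expr"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x$values)), collapse = "\t"),
             con, sep = "\n")
  body <- apply(x$values, 1, function(row) {
    paste(format(row, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t")
  })
  writeLines(paste(rownames(x$values), body, sep = "\t"), con, sep = "\n")
  invisible(path)
}
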