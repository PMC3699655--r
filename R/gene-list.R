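#' Construct a named gene list
#'
#' An ordered set of normalized gene symbols. Duplicates (after
#' normalization) are dropped, keeping first occurrence, and the number
#' dropped is recorded and messaged.
#'
#' @param symbols Character vector of gene symbols.
#' @param name Short name for the list.
#' @param provenance Free-text note on where the list came from.
#' @return An object of class `eos_genelist` with elements `name`,
#'   `symbols`, `provenance`, `n_dropped`.
#' @export
gene_list <- function(symbols, name = "gene_list", provenance = "") {
  norm <- normalize_gene_symbols(symbols)
  norm <- norm[nzchar(norm)]
  dropped <- sum(duplicated(norm))
  if (dropped > 0) {
    message(sprintf("gene list '%s': dropped %d duplicate symbol(s)",
                    name, dropped))
  }
  structure(list(name = name, symbols = norm[!duplicated(norm)],
                 provenance = provenance, n_dropped = dropped),
            class = "eos_genelist")
}

#' @export
print.eos_genelist <- function(x, ...) {
  cat(sprintf("Gene list '%s': %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' @export
length.eos_genelist <- function(x) length(x$symbols)

# Coerce gene lists / character vectors to a plain symbol vector.
as_symbols <- function(x) {
  if (inherits(x, "eos_genelist")) x$symbols
  else normalize_gene_symbols(as.character(x))
}

#' Read a gene list from plain text
#'
#' One symbol per line; blank lines and lines starting with `#` are
#' ignored. With `raw = TRUE` the verbatim (trimmed, un-normalized,
#' un-deduplicated) entries are returned — the mode used to count raw
#' entries of published tables that contain printed duplicates.
#'
#' @param path Path to the text file.
#' @param name Name for the resulting list (default: file name).
#' @param raw If `TRUE`, return the raw character vector of entries.
#' @return An `eos_genelist`, or a character vector when `raw = TRUE`.
#' @export
read_gene_list <- function(path, name = NULL, raw = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty gene list file: ", path)
  if (raw) return(lines)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_list(lines, name = name, provenance = path)
}

#' Write a gene list as plain text
#'
#' Round-trips preserve symbol order.
#'
#' @param x An `eos_genelist` or character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_list <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as_symbols(x), con, sep = "\n")
  invisible(path)
}

#' Paths to the packaged published gene tables
#'
#' Two plain-text transcriptions ship with the package: the 365 raw entries
#' of the sputum eosinophil-associated gene table (printed duplicates
#' retained) and the 57-gene three-way intersection table.
#'
#' @param which `"table1_sputum"` or `"table2_intersection"`.
#' @return Path to the packaged fixture file.
#' @export
eos_table_path <- function(which = c("table1_sputum", "table2_intersection")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".txt"), package = "eosid")
  if (!nzchar(path)) stop("packaged fixture not found: ", which)
  path
}
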