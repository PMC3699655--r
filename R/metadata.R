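COMPARTMENTS <- c("BAL", "sputum", "purified_EOS")
VISITS <- c("V1", "V2", "V3", "V4")
CELL_CLASSES <- c("eosinophil", "macrophage", "lymphocyte", "neutrophil",
                  "epithelial")

#' Validate per-sample study metadata
#'
#' Sample metadata drives every contrast pairing: `subject_id` pairs visits
#' within a subject, `compartment` separates the BAL and sputum arms (and
#' purified-EOS samples), `visit` encodes the timeline (V1 pre-challenge,
#' V2 48 h post-challenge, V3/V4 the same pair after mepolizumab), and
#' `mepolizumab` flags samples collected after anti-IL-5 dosing.
#'
#' @param meta Data frame with columns `sample_id`, `subject_id`,
#'   `compartment`, `visit`, `mepolizumab`.
#' @return The validated data frame (with `mepolizumab` coerced to logical).
#' @export
validate_sample_info <- function(meta) {
  req <- c("sample_id", "subject_id", "compartment", "visit", "mepolizumab")
  miss <- setdiff(req, colnames(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(meta$compartment %in% COMPARTMENTS)) {
    stop("compartment must be one of: ", paste(COMPARTMENTS, collapse = ", "))
  }
  if (!all(meta$visit %in% VISITS)) {
    stop("visit must be one of: ", paste(VISITS, collapse = ", "))
  }
  if (is.character(meta$mepolizumab)) {
    meta$mepolizumab <- toupper(meta$mepolizumab) %in% c("TRUE", "T", "1", "YES")
  }
  meta$mepolizumab <- as.logical(meta$mepolizumab)
  key <- paste(meta$subject_id, meta$compartment, meta$visit)
  if (anyDuplicated(key)) {
    stop("(subject_id, compartment, visit) must be unique; duplicated: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  sput <- meta$compartment == "sputum"
  if (any(sput & !meta$visit %in% c("V1", "V2"))) {
    stop("sputum samples only have visits V1/V2")
  }
  bal_pre <- meta$compartment == "BAL" & meta$visit %in% c("V1", "V2")
  if (any(bal_pre & meta$mepolizumab)) {
    stop("mepolizumab must be FALSE for BAL V1/V2 samples")
  }
  meta
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `compartment`,
#'   `visit`, `mepolizumab`.
#' @return Validated metadata data frame.
#' @export
read_sample_info <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
  validate_sample_info(meta)
}

#' Write sample metadata as TSV
#' @param meta Validated metadata data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_info <- function(meta, path) {
  write_tsv_lf(validate_sample_info(meta), path)
}

#' Validate a cell-differential count table
#'
#' Counts per cytospin cell class; class counts must sum to the total
#' number of cells counted, so derived percentages sum to 100.
#'
#' @param diffs Data frame with columns `sample_id`, one column per class in
#'   `eosinophil, macrophage, lymphocyte, neutrophil, epithelial`, and
#'   `total_counted`.
#' @return The validated data frame.
#' @export
validate_cell_differentials <- function(diffs) {
  req <- c("sample_id", CELL_CLASSES, "total_counted")
  miss <- setdiff(req, colnames(diffs))
  if (length(miss)) stop("differentials missing columns: ",
                         paste(miss, collapse = ", "))
  counts <- as.matrix(diffs[, CELL_CLASSES])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if (any(diffs$total_counted < 0)) stop("total_counted must be non-negative")
  if (!all(rowSums(counts) == diffs$total_counted)) {
    stop("class counts must sum to total_counted")
  }
  as.data.frame(diffs, stringsAsFactors = FALSE)
}

#' Percentages from a cell-differential table
#'
#' @param diffs Validated differential table.
#' @return Data frame of per-class percentages (rows matching `diffs`).
#' @export
cell_percentages <- function(diffs) {
  diffs <- validate_cell_differentials(diffs)
  pct <- 100 * as.matrix(diffs[, CELL_CLASSES]) /
    ifelse(diffs$total_counted > 0, diffs$total_counted, 1)
  data.frame(sample_id = diffs$sample_id, pct, stringsAsFactors = FALSE)
}

# TSV writer honouring the output contract: tab-separated, '.' decimal,
# UTF-8, LF endings regardless of platform.
write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    rows <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                  scientific = FALSE)
      else as.character(col)
    }), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}
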