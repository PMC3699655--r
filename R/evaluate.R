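#' Percentage with half-away-from-zero rounding
#'
#' `100 * part / whole`, rounded half away from zero to the requested
#' number of decimals — the rounding convention used for printed
#' percentages (so 99 of 299 prints as 33.1 and 168 of 365 as 46).
#'
#' @param part,whole Counts; `whole` must be positive, `part` non-negative.
#' @param decimals Decimal places to round to (default 1).
#' @return Rounded percentage.
#' @export
percent_of <- function(part, whole, decimals = 1) {
  if (whole <= 0) stop("whole must be positive")
  if (part < 0) stop("part must be non-negative")
  x <- 100 * part / whole
  scale <- 10^decimals
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Score a selection result against simulated ground truth
#'
#' EOS-program genes (`eos_specific` and `eos_activated` classes) are the
#' positive class; the pipeline's final intersection is the prediction.
#' Sensitivity is the fraction of positive genes selected; the false
#' discovery rate is the fraction of selected genes outside the positive
#' class (defined as 0 with a warning when nothing is selected).
#'
#' @param selection An `eos_selection` result.
#' @param truth An `eos_truth` object covering the same gene universe.
#' @return List of class `eos_recovery`: `sensitivity`, `fdr`, `n_selected`,
#'   `confusion` (per-class selected/not-selected counts).
#' @export
evaluate_recovery <- function(selection, truth) {
  stopifnot(inherits(selection, "eos_selection"))
  genes <- truth$genes
  universe <- genes$gene
  branch_union <- unique(unlist(selection$branches))
  outside <- setdiff(branch_union, universe)
  if (length(outside)) {
    stop("selection contains gene(s) outside the truth universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  selected <- selection$intersection
  positive <- genes$gene[genes$class %in% c("eos_specific", "eos_activated")]
  tp <- length(intersect(selected, positive))
  sensitivity <- if (length(positive)) tp / length(positive) else NA_real_
  if (length(selected) == 0) {
    warning("empty final intersection; FDR defined as 0")
    fdr <- 0
  } else {
    fdr <- (length(selected) - tp) / length(selected)
  }
  confusion <- table(
    class = factor(genes$class, levels = GENE_CLASSES),
    selected = factor(genes$gene %in% selected, levels = c(TRUE, FALSE))
  )
  structure(list(sensitivity = sensitivity, fdr = fdr,
                 n_selected = length(selected), confusion = confusion),
            class = "eos_recovery")
}

#' @export
print.eos_recovery <- function(x, ...) {
  cat(sprintf("Recovery: sensitivity %.3f, FDR %.3f (%d genes selected)\n",
              x$sensitivity, x$fdr, x$n_selected))
  invisible(x)
}

#' Summarize an eosinophil-percentage contrast between two groups
#'
#' Reports per-group mean and standard error, and the percent reduction
#' from group A to group B by two conventions: the reduction of the group
#' means, `100 * (mean_a - mean_b) / mean_a`, and the mean of per-subject
#' reductions (when `paired = TRUE` and groups align subject-wise). The two
#' differ in general and both are reported.
#'
#' @param a,b Numeric vectors (e.g. EOS percentages per subject), group A
#'   the larger/reference condition.
#' @param paired If `TRUE` (default when lengths match), per-subject
#'   reductions are also computed.
#' @return List of class `eos_diffsummary`: `mean_a`, `sem_a`, `n_a`,
#'   `mean_b`, `sem_b`, `n_b`, `reduction_of_means`,
#'   `mean_of_subject_reductions` (NA when unpaired).
#' @export
summarize_differentials <- function(a, b, paired = length(a) == length(b)) {
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  if (mean(a) == 0) stop("group A mean is zero; reduction undefined")
  red_means <- 100 * (mean(a) - mean(b)) / mean(a)
  red_subj <- NA_real_
  if (paired) {
    if (any(a == 0)) stop("per-subject reduction undefined for zero baseline")
    red_subj <- mean(100 * (a - b) / a)
  }
  structure(list(mean_a = mean(a), sem_a = sem(a), n_a = length(a),
                 mean_b = mean(b), sem_b = sem(b), n_b = length(b),
                 reduction_of_means = red_means,
                 mean_of_subject_reductions = red_subj),
            class = "eos_diffsummary")
}

#' @export
print.eos_diffsummary <- function(x, ...) {
  cat(sprintf("%.1f +/- %.1f (n=%d) vs %.1f +/- %.1f (n=%d): %.1f%% reduction of means\n",
              x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
              x$reduction_of_means))
  invisible(x)
}

#' Verify the packaged published gene tables
#'
#' Checks the internal consistency of the two packaged table
#' transcriptions: the sputum table holds 365 raw entries (printed
#' duplicates included), the intersection table holds 57 genes, every
#' intersection gene is contained in the sputum table, and all four EOS
#' marker genes appear in the intersection table.
#'
#' @return List of class `eos_table_report` with the observed counts, the
#'   recorded expectations, and an overall `ok` flag.
#' @export
verify_paper_tables <- function() {
  t1_raw <- read_gene_list(eos_table_path("table1_sputum"), raw = TRUE)
  t1 <- suppressMessages(read_gene_list(eos_table_path("table1_sputum")))
  t2 <- read_gene_list(eos_table_path("table2_intersection"))
  overlap <- intersect(t2$symbols, t1$symbols)
  markers_in_t2 <- EOS_MARKER_GENES %in% t2$symbols
  expected <- list(table1_raw = 365L, table2 = 57L, overlap = 57L,
                   markers = 4L)
  observed <- list(table1_raw = length(t1_raw), table2 = length(t2$symbols),
                   overlap = length(overlap), markers = sum(markers_in_t2))
  structure(list(observed = observed, expected = expected,
                 table1_unique = length(t1$symbols),
                 ok = identical(lapply(observed, as.integer), expected)),
            class = "eos_table_report")
}

#' @export
print.eos_table_report <- function(x, ...) {
  cat("Packaged table verification:\n")
  for (k in names(x$observed)) {
    cat(sprintf("  %-11s observed %3d, expected %3d\n", k,
                x$observed[[k]], x$expected[[k]]))
  }
  cat(if (x$ok) "  all checks passed\n" else "  CHECKS FAILED\n")
  invisible(x)
}

#' Write selection results to a report directory
#'
#' Writes the three branch gene lists and the final intersection as plain
#' text, the seven Venn region counts as JSON, and the thresholds used.
#' Output is deterministic: identical input produces byte-identical files.
#'
#' @param result An `eos_selection`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, out_dir) {
  stopifnot(inherits(result, "eos_selection"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(
    bal_up = file.path(out_dir, "bal_up.txt"),
    mepo_down = file.path(out_dir, "mepo_down.txt"),
    sputum_assoc = file.path(out_dir, "sputum_assoc.txt"),
    intersection = file.path(out_dir, "intersection.txt")
  )
  write_gene_list(result$branches$bal_up, paths["bal_up"])
  write_gene_list(result$branches$mepo_down, paths["mepo_down"])
  write_gene_list(result$branches$sputum_assoc, paths["sputum_assoc"])
  write_gene_list(result$intersection, paths["intersection"])
  venn_path <- file.path(out_dir, "venn.json")
  jsonlite::write_json(as.list(venn_counts(result)), venn_path,
                       auto_unbox = TRUE, pretty = TRUE)
  params_path <- file.path(out_dir, "params.json")
  th <- result$thresholds
  params <- list(
    thresholds = if (is.null(th)) NULL else unclass(th),
    gated_subjects = result$gated_subjects
  )
  jsonlite::write_json(params, params_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(c(paths, venn = venn_path, params = params_path))
}
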