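#' Fold-change thresholds for the three selection branches
#'
#' Defaults follow the published analysis: >2-fold up-regulation in BAL
#' after segmental challenge, >1.5-fold decrease after mepolizumab (1.5
#' rather than 2 because mepolizumab halved, not abolished, the BAL EOS
#' percentage), >2-fold marker-gene increase to gate sputum subjects, and
#' >1.5-fold up-regulation for the sputum-associated list. All comparisons
#' are strict (`>`) by default; `mode = "gte"` switches to `>=`.
#'
#' @param bal_up_fc BAL V2/V1 up-regulation threshold (default 2).
#' @param mepo_down_fc Mepolizumab decrease threshold (default 1.5),
#'   applied to both decrease criteria.
#' @param sputum_marker_fc Marker-gene gating threshold (default 2).
#' @param sputum_up_fc Sputum up-regulation threshold (default 1.5).
#' @param mode `"strict"` (`>`) or `"gte"` (`>=`).
#' @param mepo_combine How the two mepolizumab decrease criteria combine:
#'   `"and"` (default; both must indicate a decrease) or `"or"`.
#' @param min_markers Number of the four marker genes that must pass the
#'   gate (default 4, i.e. all; lower values are for sensitivity analysis).
#' @return An object of class `eos_thresholds`.
#' @export
selection_thresholds <- function(bal_up_fc = 2, mepo_down_fc = 1.5,
                                 sputum_marker_fc = 2, sputum_up_fc = 1.5,
                                 mode = c("strict", "gte"),
                                 mepo_combine = c("and", "or"),
                                 min_markers = 4L) {
  mode <- match.arg(mode)
  mepo_combine <- match.arg(mepo_combine)
  for (v in c(bal_up_fc, mepo_down_fc, sputum_marker_fc, sputum_up_fc)) {
    if (!is.finite(v) || v <= 1) stop("all fold-change thresholds must be > 1")
  }
  structure(list(bal_up_fc = bal_up_fc, mepo_down_fc = mepo_down_fc,
                 sputum_marker_fc = sputum_marker_fc,
                 sputum_up_fc = sputum_up_fc, mode = mode,
                 mepo_combine = mepo_combine,
                 min_markers = as.integer(min_markers)),
            class = "eos_thresholds")
}

exceeds <- function(x, threshold, mode) {
  if (mode == "strict") x > threshold else x >= threshold
}

# Linear-scale values with near-zero denominators floored at
# 1e-6 * median positive value, so fold changes stay finite. Floored
# events are messaged.
floor_linear <- function(values, context = "denominator") {
  pos <- values[values > 0]
  eps <- if (length(pos)) 1e-6 * stats::median(pos) else 1e-6
  n_floored <- sum(values < eps)
  if (n_floored > 0) {
    message(sprintf("floored %d near-zero %s value(s) at %.3g",
                    n_floored, context, eps))
  }
  pmax(values, eps)
}

# Internal: per-subject matrix of values for one (compartment, visit),
# columns named by subject id. Errors if a required subject lacks the visit.
visit_values <- function(x, meta, compartment, visit, subjects) {
  sel <- meta$compartment == compartment & meta$visit == visit
  m <- meta[sel, , drop = FALSE]
  missing <- setdiff(subjects, m$subject_id)
  if (length(missing)) {
    stop(sprintf("missing %s %s sample for subject(s): %s",
                 compartment, visit, paste(missing, collapse = ", ")))
  }
  m <- m[match(subjects, m$subject_id), , drop = FALSE]
  absent <- setdiff(m$sample_id, colnames(x$values))
  if (length(absent)) {
    stop("metadata sample(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  }
  v <- x$values[, m$sample_id, drop = FALSE]
  colnames(v) <- subjects
  v
}

#' Per-subject fold changes between two visits
#'
#' Computes linear-scale expression ratios (numerator visit over
#' denominator visit) per gene and subject. Log2 input is exponentiated
#' first, so `FC = 2^(log2 num - log2 den)`; near-zero linear denominators
#' are floored (see [selection_thresholds()] documentation for the branch
#' rules these records feed).
#'
#' @param x An `eos_expr` expression matrix.
#' @param meta Validated sample metadata covering the matrix columns used.
#' @param contrast Character pair `c(numerator_visit, denominator_visit)`,
#'   e.g. `c("V2", "V1")`.
#' @param compartment Compartment to restrict to (default `"BAL"`).
#' @param subjects Subjects to include (default: all subjects with the
#'   numerator visit in this compartment).
#' @param per_subject If `FALSE`, a single pooled record per gene is
#'   returned, the ratio of geometric means across subjects.
#' @return Data frame with columns `gene`, `subject_id`, `contrast`,
#'   `fold_change`.
#' @export
compute_fold_change <- function(x, meta, contrast, compartment = "BAL",
                                subjects = NULL, per_subject = TRUE) {
  stopifnot(inherits(x, "eos_expr"), length(contrast) == 2)
  if (!all(contrast %in% VISITS)) {
    stop("unknown contrast: ", paste(contrast, collapse = "/"))
  }
  meta <- validate_sample_info(meta)
  if (is.null(subjects)) {
    subjects <- sort(unique(
      meta$subject_id[meta$compartment == compartment &
                        meta$visit == contrast[1]]))
  }
  if (length(subjects) == 0) stop("no subjects in scope for contrast")
  lin <- as_linear(x)
  num <- visit_values(lin, meta, compartment, contrast[1], subjects)
  den <- visit_values(lin, meta, compartment, contrast[2], subjects)
  den <- floor_linear(den)
  fc <- num / den
  label <- sprintf("%s %s-vs-%s", compartment, contrast[1], contrast[2])
  if (!per_subject) {
    gm <- function(m) exp(rowMeans(log(floor_linear(m, "pooled"))))
    return(data.frame(gene = rownames(fc), subject_id = "(pooled)",
                      contrast = label,
                      fold_change = gm(num) / gm(den),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  data.frame(
    gene = rep(rownames(fc), times = ncol(fc)),
    subject_id = rep(colnames(fc), each = nrow(fc)),
    contrast = label,
    fold_change = as.vector(fc),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Branch 1: genes up-regulated in BAL after segmental allergen challenge
#'
#' Selects genes whose BAL V2-vs-V1 fold change exceeds the threshold in
#' every subject analyzed (the published two-subject "both subjects" rule
#' generalized to all-of-n).
#'
#' @param fc_records Fold-change records from [compute_fold_change()] for
#'   the BAL V2-vs-V1 contrast.
#' @param thresholds An [selection_thresholds()] object.
#' @return An `eos_genelist` of selected genes (alphabetical).
#' @export
select_bal_upregulated <- function(fc_records, thresholds = selection_thresholds()) {
  if (is.null(fc_records) || nrow(fc_records) == 0) {
    stop("empty fold-change record set")
  }
  pass <- exceeds(fc_records$fold_change, thresholds$bal_up_fc, thresholds$mode)
  sel <- tapply(pass, fc_records$gene, all)
  gene_list(sort(names(sel)[sel]), name = "bal_up",
            provenance = sprintf("BAL V2/V1 FC %s %g in all subjects",
                                 if (thresholds$mode == "strict") ">" else ">=",
                                 thresholds$bal_up_fc))
}

#' Branch 2: genes decreased after eosinophil depletion by mepolizumab
#'
#' For every subject, two decrease criteria are evaluated on linear-scale
#' expression: (i) the direct fold change `expr(V2) / expr(V4)` and
#' (ii) the challenge fold change before mepolizumab divided by the
#' challenge fold change after, `[V2/V1] / [V4/V3]`. A candidate gene is
#' selected when the combined rule (both by default) exceeds the
#' mepolizumab threshold in every subject.
#'
#' @param x BAL `eos_expr` matrix containing visits V1-V4 for each subject.
#' @param meta Validated sample metadata.
#' @param candidate_genes Genes to test (typically the
#'   [select_bal_upregulated()] output); `eos_genelist` or character.
#' @param thresholds An [selection_thresholds()] object.
#' @param subjects Subjects to evaluate (default: all BAL subjects with a
#'   V4 sample).
#' @return An `eos_genelist`, a subset of `candidate_genes`.
#' @export
select_mepolizumab_decreased <- function(x, meta, candidate_genes,
                                         thresholds = selection_thresholds(),
                                         subjects = NULL) {
  stopifnot(inherits(x, "eos_expr"))
  meta <- validate_sample_info(meta)
  genes <- as_symbols(candidate_genes)
  absent <- setdiff(genes, gene_ids(x))
  if (length(absent)) {
    stop("candidate gene(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  }
  if (is.null(subjects)) {
    subjects <- sort(unique(
      meta$subject_id[meta$compartment == "BAL" & meta$visit == "V4"]))
  }
  lin <- as_linear(x)
  lin$values <- lin$values[genes, , drop = FALSE]
  v <- lapply(setNames(VISITS, VISITS), function(vis) {
    visit_values(lin, meta, "BAL", vis, subjects)
  })
  direct <- v$V2 / floor_linear(v$V4)
  ratio <- (v$V2 / floor_linear(v$V1)) / floor_linear(v$V4 / floor_linear(v$V3))
  pd <- exceeds(direct, thresholds$mepo_down_fc, thresholds$mode)
  pr <- exceeds(ratio, thresholds$mepo_down_fc, thresholds$mode)
  pass <- if (thresholds$mepo_combine == "and") pd & pr else pd | pr
  sel <- rownames(pass)[rowSums(pass) == ncol(pass)]
  gene_list(sort(sel), name = "mepo_down",
            provenance = sprintf(
              "V2/V4 and (V2/V1)/(V4/V3) %s %g in all subjects (%s rule)",
              if (thresholds$mode == "strict") ">" else ">=",
              thresholds$mepo_down_fc, thresholds$mepo_combine))
}

#' Gate sputum subjects on eosinophil marker genes
#'
#' A sputum subject is retained when all four EOS marker genes (IL5RA,
#' RNASE2, RNASE3, SIGLEC8) are up-regulated by more than the marker
#' threshold after whole-lung allergen challenge (V2 vs V1). A relaxed
#' `min_markers` setting in the thresholds is available for sensitivity
#' analysis only.
#'
#' @param fc_records Sputum V2-vs-V1 fold-change records.
#' @param marker_genes Marker symbols (default [EOS_MARKER_GENES]).
#' @param thresholds An [selection_thresholds()] object.
#' @return Character vector of gated subject ids (sorted).
#' @export
gate_sputum_subjects <- function(fc_records,
                                 marker_genes = EOS_MARKER_GENES,
                                 thresholds = selection_thresholds()) {
  marker_genes <- normalize_gene_symbols(marker_genes)
  absent <- setdiff(marker_genes, unique(fc_records$gene))
  if (length(absent)) {
    stop("marker gene(s) missing from matrix: ", paste(absent, collapse = ", "))
  }
  rec <- fc_records[fc_records$gene %in% marker_genes, , drop = FALSE]
  pass <- exceeds(rec$fold_change, thresholds$sputum_marker_fc, thresholds$mode)
  n_pass <- tapply(pass, rec$subject_id, sum)
  sort(names(n_pass)[n_pass >= thresholds$min_markers])
}

#' Branch 3: sputum eosinophil-associated genes in gated subjects
#'
#' Genes whose sputum V2-vs-V1 fold change exceeds the sputum threshold in
#' every marker-gated subject.
#'
#' @param fc_records Sputum V2-vs-V1 fold-change records.
#' @param gated_subjects Subject ids from [gate_sputum_subjects()].
#' @param thresholds An [selection_thresholds()] object.
#' @return An `eos_genelist` of selected genes (alphabetical).
#' @export
select_sputum_associated <- function(fc_records, gated_subjects,
                                     thresholds = selection_thresholds()) {
  if (length(gated_subjects) == 0) stop("no subjects passed marker gating")
  rec <- fc_records[fc_records$subject_id %in% gated_subjects, , drop = FALSE]
  missing <- setdiff(gated_subjects, unique(rec$subject_id))
  if (length(missing)) {
    stop("no fold-change records for gated subject(s): ",
         paste(missing, collapse = ", "))
  }
  pass <- exceeds(rec$fold_change, thresholds$sputum_up_fc, thresholds$mode)
  sel <- tapply(pass, rec$gene, all)
  gene_list(sort(names(sel)[sel]), name = "sputum_assoc",
            provenance = sprintf(
              "sputum V2/V1 FC %s %g in all %d gated subjects",
              if (thresholds$mode == "strict") ">" else ">=",
              thresholds$sputum_up_fc, length(gated_subjects)))
}

#' Three-way intersection of the selection branches
#'
#' Computes all seven disjoint Venn regions over the union of the three
#' branch gene sets, plus the final intersection — the genes attributed to
#' airway eosinophils. The Venn is computed over branch outputs, not over
#' platform universes, mirroring the published list-level intersection.
#'
#' @param bal_up,mepo_down,sputum_assoc Branch outputs (`eos_genelist` or
#'   character vectors).
#' @param thresholds Optional thresholds object echoed into the result.
#' @param gated_subjects Optional gated sputum subject ids, echoed.
#' @return An object of class `eos_selection` with elements `branches`
#'   (three sorted symbol vectors), `regions` (seven disjoint sets keyed
#'   `bal_only`, `sputum_only`, `mepo_only`, `bal_sputum`, `bal_mepo`,
#'   `sputum_mepo`, `all_three`), `intersection`, `thresholds`,
#'   `gated_subjects`.
#' @export
intersect_branches <- function(bal_up, mepo_down, sputum_assoc,
                               thresholds = NULL, gated_subjects = NULL) {
  b <- sort(unique(as_symbols(bal_up)))
  m <- sort(unique(as_symbols(mepo_down)))
  s <- sort(unique(as_symbols(sputum_assoc)))
  regions <- list(
    bal_only    = setdiff(b, union(m, s)),
    sputum_only = setdiff(s, union(b, m)),
    mepo_only   = setdiff(m, union(b, s)),
    bal_sputum  = setdiff(intersect(b, s), m),
    bal_mepo    = setdiff(intersect(b, m), s),
    sputum_mepo = setdiff(intersect(s, m), b),
    all_three   = intersect(intersect(b, m), s)
  )
  structure(list(branches = list(bal_up = b, mepo_down = m, sputum_assoc = s),
                 regions = regions,
                 intersection = regions$all_three,
                 thresholds = thresholds,
                 gated_subjects = gated_subjects),
            class = "eos_selection")
}

#' @export
print.eos_selection <- function(x, ...) {
  cat("Three-branch gene selection\n")
  cat(sprintf("  BAL up-regulated:      %4d\n", length(x$branches$bal_up)))
  cat(sprintf("  mepolizumab-decreased: %4d\n", length(x$branches$mepo_down)))
  cat(sprintf("  sputum-associated:     %4d\n", length(x$branches$sputum_assoc)))
  cat(sprintf("  final intersection:    %4d\n", length(x$intersection)))
  if (!is.null(x$gated_subjects)) {
    cat("  gated sputum subjects: ",
        paste(x$gated_subjects, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Venn region counts of a selection result
#' @param x An `eos_selection`.
#' @return Named integer vector over the seven regions.
#' @export
venn_counts <- function(x) {
  stopifnot(inherits(x, "eos_selection"))
  vapply(x$regions, length, integer(1))
}

#' Run the full three-branch selection pipeline
#'
#' Convenience wrapper: computes BAL V2/V1 fold changes, the BAL
#' up-regulated branch, the mepolizumab-decreased branch on those
#' candidates, the marker-gated sputum branch, and their intersection.
#'
#' @param bal BAL `eos_expr` matrix (visits V1-V4 per subject).
#' @param sputum Sputum `eos_expr` matrix (visits V1-V2 per subject).
#' @param meta Validated metadata covering both matrices.
#' @param thresholds An [selection_thresholds()] object.
#' @param marker_genes Marker genes for sputum gating.
#' @return An `eos_selection` (see [intersect_branches()]).
#' @export
run_selection <- function(bal, sputum, meta,
                          thresholds = selection_thresholds(),
                          marker_genes = EOS_MARKER_GENES) {
  meta <- validate_sample_info(meta)
  bal_fc <- compute_fold_change(bal, meta, c("V2", "V1"), "BAL")
  bal_up <- select_bal_upregulated(bal_fc, thresholds)
  mepo <- select_mepolizumab_decreased(bal, meta, bal_up, thresholds)
  sput_fc <- compute_fold_change(sputum, meta, c("V2", "V1"), "sputum")
  gated <- gate_sputum_subjects(sput_fc, marker_genes, thresholds)
  sput <- select_sputum_associated(sput_fc, gated, thresholds)
  intersect_branches(bal_up, mepo, sput, thresholds = thresholds,
                     gated_subjects = gated)
}
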