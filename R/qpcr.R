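#' Read a qPCR Ct table
#'
#' @param path CSV with columns `sample_id`, `gene`, `replicate`, `ct`.
#' @return Validated data frame of wells.
#' @export
read_qpcr <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_qpcr_wells(wells)
}

#' Validate a table of qPCR wells
#' @param wells Data frame with columns `sample_id`, `gene`, `replicate`,
#'   `ct`; Ct values must be finite and positive.
#' @return The validated data frame (gene symbols normalized).
#' @export
validate_qpcr_wells <- function(wells) {
  req <- c("sample_id", "gene", "replicate", "ct")
  miss <- setdiff(req, colnames(wells))
  if (length(miss)) stop("qPCR table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(wells$ct)) || any(wells$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  wells$gene <- normalize_gene_symbols(wells$gene)
  as.data.frame(wells, stringsAsFactors = FALSE)
}

#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Ordinary least-squares fit of mean Ct against log10 relative template
#' quantity over a dilution series. Efficiency is derived from the slope
#' by the standard convention `E = 10^(-1/slope) - 1` (a slope of -3.3219
#' cycles per decade corresponds to perfect doubling, 100 percent).
#'
#' @param points Data frame with columns `log10_quantity` and `ct`
#'   (replicates allowed; at least 3 distinct dilution points, ideally
#'   spanning at least 2 decades).
#' @param gene Optional gene label.
#' @param acceptance_band Efficiency band (percent) outside which the curve
#'   is flagged; default `c(91, 96)`, the range observed for the study's
#'   primer sets.
#' @return Object of class `eos_stdcurve`: `gene`, `slope` (cycles per
#'   decade), `intercept`, `efficiency` (percent), `r_squared`,
#'   `in_band` (logical), `points`.
#' @export
fit_standard_curve <- function(points, gene = NA_character_,
                               acceptance_band = c(91, 96)) {
  req <- c("log10_quantity", "ct")
  if (!all(req %in% colnames(points))) {
    stop("points must have columns log10_quantity and ct")
  }
  if (length(unique(points$log10_quantity)) < 3) {
    stop("standard curve needs at least 3 dilution points")
  }
  span <- diff(range(points$log10_quantity))
  if (span < 2) {
    warning(sprintf("dilution series spans only %.2f log10 units (< 2)", span))
  }
  fit <- stats::lm(ct ~ log10_quantity, data = points)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("invalid dilution series: slope must be negative")
  }
  efficiency <- (10^(-1 / slope) - 1) * 100
  in_band <- efficiency >= acceptance_band[1] & efficiency <= acceptance_band[2]
  if (!in_band) {
    warning(sprintf("efficiency %.1f%% outside acceptance band [%g%%, %g%%]",
                    efficiency, acceptance_band[1], acceptance_band[2]))
  }
  structure(list(gene = gene, slope = slope,
                 intercept = unname(coef(fit)[1]),
                 efficiency = efficiency,
                 # exact dilution points make summary.lm grumble; r^2 is
                 # reported descriptively only
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 in_band = in_band, points = points),
            class = "eos_stdcurve")
}

#' @export
print.eos_stdcurve <- function(x, ...) {
  cat(sprintf("Standard curve%s: slope %.4f cycles/log10, efficiency %.1f%%%s\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$slope, x$efficiency,
              if (x$in_band) "" else " (outside acceptance band)"))
  invisible(x)
}

#' Relative quantification by the comparative threshold-cycle method
#'
#' Replicate Cts are averaged per (sample, gene); the delta Ct is the mean
#' target Ct minus the mean reference-gene Ct within each sample; the
#' delta-delta Ct subtracts the calibrator sample's delta Ct; and the fold
#' change is `2^-ddCt`. Base 2 is used regardless of measured primer
#' efficiency (no Pfaffl-type correction), matching the conventional
#' reporting of the method; the resulting bias at efficiency below 100
#' percent is documented, not corrected.
#'
#' @param wells Data frame of wells (see [validate_qpcr_wells()]).
#' @param reference_gene Reference gene symbol, measured in every sample.
#' @param calibrator_sample Sample id against which fold changes are
#'   expressed (fold change exactly 1 there).
#' @return Data frame of class `eos_qpcr_result` addition: columns
#'   `sample_id`, `gene`, `mean_ct`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
delta_delta_ct <- function(wells, reference_gene, calibrator_sample) {
  wells <- validate_qpcr_wells(wells)
  reference_gene <- normalize_gene_symbols(reference_gene)
  if (!calibrator_sample %in% wells$sample_id) {
    stop("calibrator sample not present: ", calibrator_sample)
  }
  agg <- stats::aggregate(ct ~ sample_id + gene, data = wells, FUN = mean)
  names(agg)[names(agg) == "ct"] <- "mean_ct"
  ref <- agg[agg$gene == reference_gene, c("sample_id", "mean_ct")]
  missing_ref <- setdiff(unique(agg$sample_id), ref$sample_id)
  if (length(missing_ref)) {
    stop("reference gene missing in sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  agg$delta_ct <- agg$mean_ct - ref$mean_ct[match(agg$sample_id, ref$sample_id)]
  cal <- agg[agg$sample_id == calibrator_sample, c("gene", "delta_ct")]
  missing_cal <- setdiff(unique(agg$gene), cal$gene)
  if (length(missing_cal)) {
    stop("gene(s) not measured in calibrator sample: ",
         paste(missing_cal, collapse = ", "))
  }
  agg$delta_delta_ct <- agg$delta_ct - cal$delta_ct[match(agg$gene, cal$gene)]
  agg$fold_change <- 2^(-agg$delta_delta_ct)
  agg <- agg[order(agg$gene, agg$sample_id), ]
  rownames(agg) <- NULL
  agg
}

#' Per-subject calibrated fold changes for a qPCR plate
#'
#' Convenience wrapper applying [delta_delta_ct()] separately per subject,
#' each calibrated on that subject's own sample at `calibrator_visit`
#' (default V1, i.e. fold change relative to the subject's pre-challenge
#' BAL cells).
#'
#' @param wells qPCR well table.
#' @param meta Validated sample metadata covering the plate's samples.
#' @param reference_gene Reference gene symbol.
#' @param calibrator_visit Visit of the per-subject calibrator (default
#'   `"V1"`).
#' @param calibrator_compartment Compartment of the calibrator (default
#'   `"BAL"`).
#' @return Row-bound [delta_delta_ct()] results with a `subject_id` column.
#' @export
qpcr_relative_expression <- function(wells, meta, reference_gene,
                                     calibrator_visit = "V1",
                                     calibrator_compartment = "BAL") {
  meta <- validate_sample_info(meta)
  wells <- validate_qpcr_wells(wells)
  subj <- meta$subject_id[match(wells$sample_id, meta$sample_id)]
  if (any(is.na(subj))) {
    stop("plate sample(s) missing from metadata: ",
         paste(unique(wells$sample_id[is.na(subj)]), collapse = ", "))
  }
  res <- lapply(split(seq_len(nrow(wells)), subj), function(i) {
    sw <- wells[i, , drop = FALSE]
    sid <- subj[i][1]
    cal <- meta$sample_id[meta$subject_id == sid &
                            meta$visit == calibrator_visit &
                            meta$compartment == calibrator_compartment]
    if (length(cal) != 1) {
      stop("no unique calibrator sample for subject ", sid)
    }
    out <- delta_delta_ct(sw, reference_gene, cal)
    out$subject_id <- sid
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Paired t-test on log-transformed fold changes
#'
#' Two-sided Student's paired t-test on natural-log-transformed values
#' (any log base gives identical t and p). Degenerate all-zero paired
#' differences return `t = 0, p = 1` with a warning rather than `NaN`.
#' Significance tiers match conventional figure markers: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001, `ns` otherwise.
#'
#' @param a,b Equal-length paired vectors of positive fold changes
#'   (length at least 2).
#' @return List with `t`, `p_value`, `df`, `tier`.
#' @export
paired_log_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("paired test needs n >= 2")
  if (any(a <= 0) || any(b <= 0)) stop("fold changes must be positive")
  d <- log(a) - log(b)
  # numerically zero variance (constant ratio) would poison t.test with NaN
  if (sd(d) < 1e-12 * max(1, abs(mean(d)))) {
    if (all(abs(d) < 1e-12)) {
      warning("all paired differences are zero; returning t = 0, p = 1")
      return(list(t = 0, p_value = 1, df = length(d) - 1, tier = "ns"))
    }
    warning("zero-variance non-zero differences; p-value degenerate at 0")
    return(list(t = sign(d[1]) * Inf, p_value = 0, df = length(d) - 1,
                tier = "***"))
  }
  ht <- stats::t.test(log(a), log(b), paired = TRUE)
  p <- ht$p.value
  tier <- if (p < 0.001) "***" else if (p < 0.01) "**"
          else if (p < 0.05) "*" else "ns"
  list(t = unname(ht$statistic), p_value = p,
       df = unname(ht$parameter), tier = tier)
}

#' Summary statistics of a group of fold changes
#'
#' Median, 25th/75th percentiles (linear-interpolation convention,
#' `quantile` type 7) and arithmetic mean — the statistics shown in
#' box-plot style summaries of qPCR fold changes.
#'
#' @param values Numeric vector (at least 1 value).
#' @return List with `median`, `q25`, `q75`, `mean`, `n`.
#' @export
summarize_fold_changes <- function(values) {
  if (length(values) == 0) stop("empty group")
  qs <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = qs[2], q25 = qs[1], q75 = qs[3],
       mean = mean(values), n = length(values))
}
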