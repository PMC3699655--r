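# Shared fixtures and independent brute-force oracles. The oracles
# re-derive every selection branch as explicit loops / set comprehensions,
# deliberately sharing no code with the package implementation.

# Seed used for frozen regression values on simulated data.
PINNED_SEED <- 20130702

# Build a linear expression matrix + metadata for a BAL-style design:
# `values` is a list: values[[subject]][[visit]] = named gene vector.
make_bal_matrix <- function(values_by_subject) {
  cols <- list()
  meta <- NULL
  for (subj in names(values_by_subject)) {
    for (vis in names(values_by_subject[[subj]])) {
      id <- paste0(subj, "_", vis)
      cols[[id]] <- values_by_subject[[subj]][[vis]]
      meta <- rbind(meta, data.frame(
        sample_id = id, subject_id = subj, compartment = "BAL",
        visit = vis, mepolizumab = vis %in% c("V3", "V4"),
        stringsAsFactors = FALSE))
    }
  }
  m <- do.call(cbind, cols)
  list(expr = expression_matrix(m, "linear"), meta = meta)
}

# Random linear BAL study: n_genes x n_subjects, all four visits.
random_bal_study <- function(n_genes, n_subjects) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  subjects <- sprintf("SU%02d", seq_len(n_subjects))
  vals <- lapply(setNames(subjects, subjects), function(s) {
    lapply(setNames(VISITS_ALL, VISITS_ALL), function(v) {
      setNames(exp(rnorm(n_genes, 5, 1.5)), genes)
    })
  })
  make_bal_matrix(vals)
}
VISITS_ALL <- c("V1", "V2", "V3", "V4")

# Random sputum study (V1/V2 only) including the four marker genes.
random_sputum_study <- function(n_genes, n_subjects) {
  genes <- unique(c(EOS_MARKER_GENES, sprintf("G%03d", seq_len(n_genes))))
  subjects <- sprintf("SP%02d", seq_len(n_subjects))
  cols <- list()
  meta <- NULL
  for (s in subjects) {
    for (v in c("V1", "V2")) {
      id <- paste0(s, "_", v)
      cols[[id]] <- setNames(exp(rnorm(length(genes), 5, 1.5)), genes)
      meta <- rbind(meta, data.frame(
        sample_id = id, subject_id = s, compartment = "sputum",
        visit = v, mepolizumab = FALSE, stringsAsFactors = FALSE))
    }
  }
  list(expr = expression_matrix(do.call(cbind, cols), "linear"), meta = meta)
}

# --- independent oracles -------------------------------------------------

value_of <- function(study, gene, subject, visit) {
  study$expr$values[gene, paste0(subject, "_", visit)]
}

oracle_bal_up <- function(study, threshold) {
  genes <- rownames(study$expr$values)
  subjects <- unique(study$meta$subject_id)
  keep <- character(0)
  for (g in genes) {
    ok <- TRUE
    for (s in subjects) {
      fc <- value_of(study, g, s, "V2") / value_of(study, g, s, "V1")
      if (!(fc > threshold)) ok <- FALSE
    }
    if (ok) keep <- c(keep, g)
  }
  sort(keep)
}

oracle_mepo <- function(study, candidates, threshold) {
  subjects <- unique(study$meta$subject_id)
  keep <- character(0)
  for (g in candidates) {
    ok <- TRUE
    for (s in subjects) {
      v1 <- value_of(study, g, s, "V1"); v2 <- value_of(study, g, s, "V2")
      v3 <- value_of(study, g, s, "V3"); v4 <- value_of(study, g, s, "V4")
      direct <- v2 / v4
      ratio <- (v2 / v1) / (v4 / v3)
      if (!(direct > threshold && ratio > threshold)) ok <- FALSE
    }
    if (ok) keep <- c(keep, g)
  }
  sort(keep)
}

oracle_gate <- function(study, markers, threshold) {
  subjects <- unique(study$meta$subject_id)
  gated <- character(0)
  for (s in subjects) {
    ok <- TRUE
    for (g in markers) {
      fc <- value_of(study, g, s, "V2") / value_of(study, g, s, "V1")
      if (!(fc > threshold)) ok <- FALSE
    }
    if (ok) gated <- c(gated, s)
  }
  sort(gated)
}

oracle_sputum_assoc <- function(study, gated, threshold) {
  genes <- rownames(study$expr$values)
  keep <- character(0)
  for (g in genes) {
    ok <- TRUE
    for (s in gated) {
      fc <- value_of(study, g, s, "V2") / value_of(study, g, s, "V1")
      if (!(fc > threshold)) ok <- FALSE
    }
    if (ok) keep <- c(keep, g)
  }
  sort(keep)
}

# Deterministic study conditions: no measurement noise, no between-subject
# EOS-fraction spread.
deterministic_config <- function(...) {
  fr <- default_fractions()
  fr$sd <- 0
  sim_config(sigma = 0, fractions = fr, ...)
}
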