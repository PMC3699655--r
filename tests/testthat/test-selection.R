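test_that("fold changes handle linear input, log2 input, and identity", {
  study <- make_bal_matrix(list(
    S1 = list(V1 = c(G1 = 100, G2 = 64), V2 = c(G1 = 250, G2 = 64))))
  fc <- compute_fold_change(study$expr, study$meta, c("V2", "V1"))
  expect_equal(fc$fold_change[fc$gene == "G1"], 2.5)
  expect_equal(fc$fold_change[fc$gene == "G2"], 1)  # sample vs itself-alike

  xlog <- expression_matrix(log2(study$expr$values), "log2")
  fclog <- compute_fold_change(xlog, study$meta, c("V2", "V1"))
  expect_equal(fclog$fold_change, fc$fold_change, tolerance = 1e-12)
  # log2 V1=6, V2=8 -> FC 4
  xl <- expression_matrix(
    matrix(c(6, 8), 1, 2, dimnames = list("G", c("S1_V1", "S1_V2"))), "log2")
  expect_equal(compute_fold_change(xl, study$meta[1:2, ],
                                   c("V2", "V1"))$fold_change, 4)

  expect_error(compute_fold_change(study$expr, study$meta, c("V9", "V1")),
               "unknown contrast")
  # a subject lacking the denominator visit is named in the error
  study2 <- make_bal_matrix(list(
    S1 = list(V1 = c(G1 = 1), V2 = c(G1 = 2)),
    S2 = list(V2 = c(G1 = 3))))
  expect_error(compute_fold_change(study2$expr, study2$meta, c("V2", "V1")),
               "V1 sample for subject\\(s\\): S2")
})

test_that("BAL branch requires the threshold in every subject, strictly", {
  study <- make_bal_matrix(list(
    S1 = list(V1 = c(A = 10, B = 10, C = 10), V2 = c(A = 30, B = 20, C = 25)),
    S2 = list(V1 = c(A = 10, B = 10, C = 10), V2 = c(A = 21, B = 50, C = 19))))
  fc <- compute_fold_change(study$expr, study$meta, c("V2", "V1"))
  sel <- suppressMessages(select_bal_upregulated(fc))
  # A: FC 3 and 2.1 -> in; B: FC exactly 2.0 in S1 -> out (strict >); C: 1.9 out
  expect_identical(sel$symbols, "A")
  gte <- suppressMessages(
    select_bal_upregulated(fc, selection_thresholds(mode = "gte")))
  expect_identical(gte$symbols, c("A", "B"))
  expect_error(select_bal_upregulated(fc[0, ]), "empty")
})

test_that("mepolizumab branch applies both decrease criteria per subject", {
  # hand-evaluated: V1=10,V2=100,V3=10,V4=40 -> direct 2.5, ratio 2.5 -> in
  # gene with direct 2.0 but fold-change ratio 1.2 -> out under AND
  study <- make_bal_matrix(list(
    S1 = list(V1 = c(IN = 10, OUT = 50),
              V2 = c(IN = 100, OUT = 100),
              V3 = c(IN = 10, OUT = 30),
              V4 = c(IN = 40, OUT = 50))))
  # OUT: direct = 100/50 = 2 > 1.5 but ratio = (100/50)/(50/30) = 1.2
  th <- selection_thresholds()
  sel <- suppressMessages(
    select_mepolizumab_decreased(study$expr, study$meta, c("IN", "OUT"), th))
  expect_identical(sel$symbols, "IN")
  or_mode <- suppressMessages(select_mepolizumab_decreased(
    study$expr, study$meta, c("IN", "OUT"),
    selection_thresholds(mepo_combine = "or")))
  expect_identical(or_mode$symbols, c("IN", "OUT"))
  expect_error(
    select_mepolizumab_decreased(study$expr, study$meta, c("IN", "NOPE"), th),
    "NOPE")
})

test_that("sputum gating demands all four markers above threshold", {
  mk <- function(fcs) c(setNames(fcs, EOS_MARKER_GENES), OTHER = 1)
  base <- mk(c(1, 1, 1, 1)) * 0 + 10
  study_cols <- list(
    P1 = list(V1 = base, V2 = base * mk(c(3, 3, 3, 3))),    # gated
    P2 = list(V1 = base, V2 = base * mk(c(3, 3, 3, 1.9))),  # 3 of 4
    P3 = list(V1 = base, V2 = base * mk(c(2, 2, 2, 2))))    # exactly 2.0
  cols <- list(); meta <- NULL
  for (s in names(study_cols)) for (v in c("V1", "V2")) {
    id <- paste0(s, "_", v)
    cols[[id]] <- study_cols[[s]][[v]]
    meta <- rbind(meta, data.frame(sample_id = id, subject_id = s,
                                   compartment = "sputum", visit = v,
                                   mepolizumab = FALSE))
  }
  x <- expression_matrix(do.call(cbind, cols), "linear")
  fc <- compute_fold_change(x, meta, c("V2", "V1"), "sputum")
  expect_identical(gate_sputum_subjects(fc), "P1")
  # relaxed any-3 mode for sensitivity analysis
  expect_identical(
    gate_sputum_subjects(fc, thresholds = selection_thresholds(min_markers = 3)),
    c("P1", "P2"))
  expect_error(gate_sputum_subjects(fc[fc$gene != "IL5RA", ]),
               "marker gene")
  sel <- suppressMessages(select_sputum_associated(fc, "P1"))
  expect_identical(sel$symbols, sort(EOS_MARKER_GENES))
  expect_error(select_sputum_associated(fc, character(0)),
               "no subjects passed marker gating")
})

test_that("every branch matches its brute-force oracle on random studies", {
  set.seed(4711)
  th <- selection_thresholds()
  for (trial in 1:100) {
    n_genes <- sample(5:50, 1)
    n_subj <- sample(1:6, 1)
    bal <- random_bal_study(n_genes, n_subj)
    fc <- compute_fold_change(bal$expr, bal$meta, c("V2", "V1"))
    got_bal <- suppressMessages(select_bal_upregulated(fc, th))$symbols
    expect_identical(got_bal, oracle_bal_up(bal, 2))
    cand <- rownames(bal$expr$values)
    got_mepo <- suppressMessages(
      select_mepolizumab_decreased(bal$expr, bal$meta, cand, th))$symbols
    expect_identical(got_mepo, oracle_mepo(bal, cand, 1.5))

    sput <- random_sputum_study(sample(5:40, 1), sample(2:6, 1))
    sfc <- compute_fold_change(sput$expr, sput$meta, c("V2", "V1"), "sputum")
    gated <- gate_sputum_subjects(sfc)
    expect_identical(gated, oracle_gate(sput, EOS_MARKER_GENES, 2))
    if (length(gated) > 0) {
      got_sput <- suppressMessages(
        select_sputum_associated(sfc, gated, th))$symbols
      expect_identical(got_sput, oracle_sputum_assoc(sput, gated, 1.5))
    }
  }
})

test_that("raising a threshold never grows the corresponding branch", {
  set.seed(88)
  bal <- random_bal_study(40, 3)
  fc <- compute_fold_change(bal$expr, bal$meta, c("V2", "V1"))
  prev <- NULL
  for (cut in c(1.2, 1.5, 2, 3, 5)) {
    cur <- suppressMessages(
      select_bal_upregulated(fc, selection_thresholds(bal_up_fc = cut)))$symbols
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("selection is invariant to gene and subject ordering", {
  set.seed(21)
  bal <- random_bal_study(30, 4)
  fc <- compute_fold_change(bal$expr, bal$meta, c("V2", "V1"))
  ref <- suppressMessages(select_bal_upregulated(fc))$symbols

  perm <- sample(nrow(bal$expr$values))
  shuffled <- expression_matrix(bal$expr$values[perm, , drop = FALSE],
                                "linear")
  meta_perm <- bal$meta[sample(nrow(bal$meta)), ]
  fc2 <- compute_fold_change(shuffled, meta_perm, c("V2", "V1"))
  expect_identical(suppressMessages(select_bal_upregulated(fc2))$symbols, ref)

  cand <- rownames(bal$expr$values)
  m1 <- suppressMessages(
    select_mepolizumab_decreased(bal$expr, bal$meta, cand))$symbols
  m2 <- suppressMessages(
    select_mepolizumab_decreased(shuffled, meta_perm, sample(cand)))$symbols
  expect_identical(m1, m2)
})

test_that("fold changes chain multiplicatively across visits", {
  sim <- suppressMessages(simulate_study(deterministic_config(seed = 9)))
  bal_meta <- sim$meta[sim$meta$compartment == "BAL", ]
  f21 <- compute_fold_change(sim$bal, bal_meta, c("V2", "V1"))
  f32 <- compute_fold_change(sim$bal, bal_meta, c("V3", "V2"))
  f31 <- compute_fold_change(sim$bal, bal_meta, c("V3", "V1"))
  key <- function(d) paste(d$gene, d$subject_id)
  m <- match(key(f31), key(f21))
  m2 <- match(key(f31), key(f32))
  expect_equal(f21$fold_change[m] * f32$fold_change[m2], f31$fold_change,
               tolerance = 1e-9)
})

test_that("Venn regions partition the branch union and respect set algebra", {
  res <- intersect_branches(c("A", "B"), c("B"), c("B", "C"))
  expect_equal(unname(venn_counts(res)["all_three"]), 1)
  expect_identical(res$intersection, "B")
  expect_identical(res$regions$bal_only, "A")
  expect_identical(res$regions$sputum_only, "C")

  # pairwise-disjoint inputs: all overlap regions empty
  dis <- intersect_branches(c("A"), c("B"), c("C"))
  expect_equal(sum(venn_counts(dis)[c("bal_sputum", "bal_mepo",
                                      "sputum_mepo", "all_three")]), 0)

  # nested inputs: intersection equals the innermost set
  nest <- intersect_branches(c("A"), c("A", "B"), c("A", "B", "C"))
  expect_identical(nest$intersection, "A")

  # partition invariants on random sets
  set.seed(12)
  for (i in 1:20) {
    u <- sprintf("G%02d", 1:20)
    r <- intersect_branches(sample(u, sample(0:15, 1)),
                            sample(u, sample(0:15, 1)),
                            sample(u, sample(0:15, 1)))
    all_regions <- unlist(r$regions)
    expect_equal(length(all_regions), length(unique(all_regions)))
    expect_setequal(all_regions, unique(unlist(r$branches)))
    expect_identical(r$regions$all_three, r$intersection)
  }
})

test_that("deterministic-limit pipeline recovers the EOS program exactly", {
  sim <- suppressMessages(simulate_study(deterministic_config(seed = 1)))
  sel <- suppressMessages(run_selection(sim$bal, sim$sputum, sim$meta))
  cls <- sim$truth$genes
  positive <- cls$gene[cls$class %in% c("eos_specific", "eos_activated")]
  noneos <- cls$gene[cls$class == "noneos_challenge_induced"]
  expect_setequal(sel$intersection, positive)
  # challenge-induced non-EOS genes reach BAL and sputum branches ...
  expect_true(all(noneos %in% sel$branches$bal_up))
  expect_true(all(noneos %in% sel$branches$sputum_assoc))
  # ... but are excluded by the mepolizumab branch
  expect_length(intersect(noneos, sel$branches$mepo_down), 0)
})
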