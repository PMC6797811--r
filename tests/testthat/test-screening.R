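test_that("disease-based assignment follows the single-condition rule", {
  d <- assign_pattern_ds1(subject("a", "hypertension"))
  expect_identical(d$outcome, "kept")
  expect_identical(d$pattern, "Hn")

  expect_identical(assign_pattern_ds1(subject("b"))$pattern, "H1")
  expect_identical(
    assign_pattern_ds1(subject("c", c("hypertension", "atherosclerosis")))$pattern,
    "HCA")

  d2 <- assign_pattern_ds1(subject("d", c("type 2 diabetes", "hypertension")))
  expect_identical(d2$outcome, "excluded")
  expect_identical(d2$reason, "comorbid_combination")

  d3 <- assign_pattern_ds1(subject("e", "diabetic foot"))
  expect_identical(d3$outcome, "excluded")
  expect_identical(d3$reason, "disease_not_in_vocabulary")

  for (dis in c("atherosclerosis", "hyperlipidaemia", "type 2 diabetes"))
    expect_identical(assign_pattern_ds1(subject("f", dis))$outcome, "kept")
})

test_that("parameter-based assignment counts out-of-range parameters", {
  # one parameter out -> its pattern
  d <- assign_pattern_ds2(subject("a", systolic = 150, diastolic = 85))
  expect_identical(d$pattern, "BP")
  # diastolic alone can trip the blood-pressure rule (OR semantics)
  expect_identical(assign_pattern_ds2(subject("b", diastolic = 95))$pattern,
                   "BP")
  expect_identical(assign_pattern_ds2(subject("c", cavi = 9.5))$pattern,
                   "CAVI")
  expect_identical(assign_pattern_ds2(subject("d", bapwv = 1500))$pattern,
                   "baPWV")
  expect_identical(assign_pattern_ds2(subject("e", viscosity = 5.5))$pattern,
                   "BV")
  # all within range -> healthy control
  expect_identical(assign_pattern_ds2(subject("f"))$pattern, "H2")
  # two or more out -> excluded
  d2 <- assign_pattern_ds2(subject("g", cavi = 9.5, bapwv = 1500))
  expect_identical(d2$outcome, "excluded")
  # thresholds are exclusive bounds
  expect_identical(
    assign_pattern_ds2(subject("h", systolic = 140, cavi = 9, bapwv = 1400,
                               viscosity = 5))$pattern, "H2")
  expect_error(assign_pattern_ds2(subject("i", cavi = NA)), "incomplete")
})

test_that("cohort screening partitions subjects and drops small classes", {
  expect_identical(nrow(screen_cohort(list(), 1)$decisions), 0L)

  cohort <- c(lapply(1:25, function(i) subject(paste0("hn", i), "hypertension")),
              lapply(1:10, function(i) subject(paste0("at", i), "atherosclerosis")))
  sc <- screen_cohort(cohort, criteria = 1)
  expect_identical(nrow(sc$decisions), 35L)
  expect_identical(unname(sc$kept_counts["Hn"]), 25L)
  expect_false("At" %in% names(sc$kept_counts))
  at_rows <- sc$decisions[grepl("^at", sc$decisions$subject_id), ]
  expect_true(all(at_rows$outcome == "excluded"))
  expect_true(all(at_rows$reason == "class_too_small"))
  # partition: every subject decided exactly once
  expect_identical(sum(sc$decisions$outcome == "kept") +
                     sum(sc$decisions$outcome == "excluded"), 35L)
})

test_that("tightening a threshold never increases a pattern's kept count", {
  set.seed(31)
  cohort <- generate_cohort(class_mix = c(H2 = 30, BP = 30, CAVI = 30,
                                          baPWV = 30, BV = 30))
  base_kept <- screen_cohort(cohort, 2)$kept_counts[["CAVI"]]
  for (cv in c(8.5, 9.5, 10.5)) {
    kept <- screen_cohort(cohort, 2,
                          screening_thresholds(cavi = cv))$kept_counts
    k <- if ("CAVI" %in% names(kept)) kept[["CAVI"]] else 0L
    if (cv <= 9.0) expect_gte(k, base_kept) else expect_lte(k, base_kept)
  }
})

test_that("no kept subject violates exclusivity", {
  set.seed(32)
  cohort <- generate_cohort(
    class_mix = c(H1 = 22, Hn = 22, At = 22, HCA = 22, H2 = 22, BP = 22),
    comorbidity_mix = list("Td+Hn" = 4, "diabetic foot" = 3))
  thr <- screening_thresholds()
  sc1 <- screen_cohort(cohort, 1, thr)
  kept1 <- sc1$decisions[sc1$decisions$outcome == "kept", ]
  for (i in seq_len(nrow(kept1))) {
    s <- cohort[[which(vapply(cohort, `[[`, "", "subject_id") ==
                         kept1$subject_id[i])]]
    if (kept1$pattern[i] != "HCA") expect_lte(length(s$diseases), 1)
  }
  sc2 <- screen_cohort(cohort, 2, thr)
  kept2 <- sc2$decisions[sc2$decisions$outcome == "kept", ]
  for (i in seq_len(nrow(kept2))) {
    s <- cohort[[which(vapply(cohort, `[[`, "", "subject_id") ==
                         kept2$subject_id[i])]]
    n_out <- (s$systolic > thr$bp_systolic || s$diastolic > thr$bp_diastolic) +
      (s$cavi > thr$cavi) + (s$bapwv > thr$bapwv) +
      (s$viscosity > thr$viscosity)
    expect_lte(n_out, 1)
  }
})

test_that("the quality gate excludes subjects with unusable records", {
  good <- subject("ok", "hypertension")
  set.seed(33)
  good$record <- generate_record(default_class_specs(1)$Hn, 3)
  bad <- subject("flat", "hypertension")
  bad$record <- structure(list(samples = rep(1, 300), fs = 100,
                               subject_id = "flat"),
                          class = "pulse_record")
  cohort <- c(lapply(1:21, function(i) {
    s <- subject(paste0("hn", i), "hypertension")
    s$record <- good$record
    s
  }), list(bad))
  sc <- screen_cohort(cohort, 1, quality_gate = TRUE)
  flat_row <- sc$decisions[sc$decisions$subject_id == "flat", ]
  expect_identical(flat_row$outcome, "excluded")
  expect_identical(flat_row$reason, "abnormal_pulse_wave")
  expect_identical(unname(sc$kept_counts[["Hn"]]), 21L)
})
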