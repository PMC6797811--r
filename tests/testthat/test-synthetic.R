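test_that("generate_cycle evaluates the Gaussian component model", {
  # zero-amplitude spec -> flat zero
  z <- pulse_class_spec("z", list(pulse_component(0, 0.5, 0.1)),
                        jitter = c(amplitude = 0, center = 0, width = 0))
  expect_equal(generate_cycle(z, 64), rep(0, 64))

  # argmax of a single bump lands on its center (dense-grid oracle:
  # the component peaks at t = center, grid t_i = (i-1)/n)
  y <- generate_cycle(bump_spec(1, 0.2, 0.05), 200)
  expect_lte(abs((which.max(y) - 1) - 40), 1)

  # deterministic under a fixed seed
  sp <- default_class_specs(1)$Hn
  set.seed(7); a <- generate_cycle(sp, 120)
  set.seed(7); b <- generate_cycle(sp, 120)
  expect_identical(a, b)

  expect_error(generate_cycle(sp, 8), "n_points")
})

test_that("generate_record concatenates cycles with exact bookkeeping", {
  sp <- default_class_specs(1)$H1
  set.seed(1)
  rec <- generate_record(sp, 1, noise_sd = 0)
  expect_identical(rec$true_boundaries, 1L)
  expect_identical(rec$samples, rec$clean)

  set.seed(2)
  rec10 <- generate_record(sp, 10)
  expect_length(rec10$true_boundaries, 10)
  # boundaries are the cumulative cycle starts; total length is the sum of
  # per-cycle lengths
  lens <- diff(c(rec10$true_boundaries, length(rec10$samples) + 1L))
  expect_identical(sum(lens), length(rec10$samples))
  expect_true(all(diff(rec10$true_boundaries) > 0))

  expect_error(generate_record(sp, 0), "n_cycles")
})

test_that("requested signal-to-noise ratio is achieved within 1 dB", {
  sp <- default_class_specs(1)$Hn
  for (snr in c(10, 20)) {
    set.seed(snr)
    rec <- generate_record(sp, 20, noise_sd = noise_sd_for_snr(snr))
    expect_lt(abs(empirical_snr_db(rec) - snr), 1)
  }
})

test_that("each true cycle contains exactly one percussion maximum, early", {
  set.seed(11)
  for (sp in default_class_specs(1)) {
    rec <- generate_record(sp, 8)
    ends <- c(rec$true_boundaries[-1] - 1L, length(rec$samples))
    for (i in seq_along(rec$true_boundaries)) {
      seg <- rec$clean[rec$true_boundaries[i]:ends[i]]
      n <- length(seg)
      # one dominant local maximum (the percussion peak) ...
      loc <- which(seg[2:(n - 1)] > seg[1:(n - 2)] &
                     seg[2:(n - 1)] >= seg[3:n]) + 1L
      expect_identical(sum(seg[loc] > 0.97 * max(seg)), 1L)
      # ... located in the systolic (early) part of the cycle
      expect_lt(which.max(seg) / n, 0.5)
    }
  }
})

test_that("disease-based class specs are mutually separated under jitter", {
  set.seed(23)
  specs <- default_class_specs(1)
  n <- 20
  cycles <- lapply(specs, function(sp)
    t(vapply(seq_len(n), function(i) generate_cycle(sp, 200), numeric(200))))
  means <- lapply(cycles, colMeans)
  within <- vapply(names(specs), function(nm)
    mean(rowMeans(sweep(cycles[[nm]], 2, means[[nm]])^2)), 0)
  for (a in names(specs)) for (b in names(specs)) {
    if (a == b) next
    between <- mean((means[[a]] - means[[b]])^2)
    expect_gt(between, max(within[a], within[b]))
  }
  # jitter 0 reproduces the fixed class-mean curve
  sp0 <- specs$Td
  expect_identical(generate_cycle(sp0, 200, jitter = FALSE),
                   generate_cycle(sp0, 200, jitter = FALSE))
})

test_that("generate_cohort emits consistent subjects and comorbid cases", {
  expect_length(generate_cohort(), 0)

  set.seed(5)
  cohort <- generate_cohort(class_mix = c(Hn = 25))
  expect_length(cohort, 25)
  for (s in cohort) expect_identical(s$diseases, "hypertension")

  set.seed(6)
  com <- generate_cohort(
    comorbidity_mix = list("Td+Hn" = 4, "Td+At" = 3, "Td+HF" = 5,
                           "diabetic foot" = 8))
  expect_length(com, 20)
  nsets <- table(vapply(com, function(s)
    paste(sort(s$diseases), collapse = "+"), ""))
  expect_identical(unname(nsets[["hypertension+type 2 diabetes"]]), 4L)
  expect_identical(unname(nsets[["atherosclerosis+type 2 diabetes"]]), 3L)
  expect_identical(unname(nsets[["heart failure+type 2 diabetes"]]), 5L)
  expect_identical(unname(nsets[["diabetic foot"]]), 8L)

  # parameters match the intended pattern: BP subjects have only blood
  # pressure out of range
  set.seed(7)
  bp <- generate_cohort(class_mix = c(BP = 10))
  thr <- screening_thresholds()
  for (s in bp) {
    expect_true(s$systolic > thr$bp_systolic || s$diastolic > thr$bp_diastolic)
    expect_lte(s$cavi, thr$cavi)
    expect_lte(s$bapwv, thr$bapwv)
    expect_lte(s$viscosity, thr$viscosity)
  }

  # identical seeds give identical cohorts
  set.seed(9); c1 <- generate_cohort(class_mix = c(H1 = 3, Td = 2))
  set.seed(9); c2 <- generate_cohort(class_mix = c(H1 = 3, Td = 2))
  expect_identical(c1, c2)
})
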