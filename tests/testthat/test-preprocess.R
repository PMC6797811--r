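test_that("the db4 transform reconstructs perfectly and denoise is sound", {
  set.seed(1)
  x <- rnorm(256)
  w <- pulsecnn:::.dwt(x, 4)
  expect_equal(pulsecnn:::.idwt(w), x, tolerance = 1e-10)
  # filters are orthonormal
  expect_equal(sum(pulsecnn:::.db4_h^2), 1, tolerance = 1e-12)
  expect_equal(sum(pulsecnn:::.db4_h), sqrt(2), tolerance = 1e-12)

  # constant signal passes through unchanged (no detail energy)
  const <- list(samples = rep(3.5, 128), fs = 100)
  expect_equal(denoise(const)$samples, rep(3.5, 128), tolerance = 1e-9)

  expect_error(denoise(list(samples = rnorm(8), fs = 100), level = 6),
               "too deep")
})

test_that("denoising preserves clean signals and strictly reduces noise", {
  sp <- default_class_specs(1)$Hn
  set.seed(2)
  clean_rec <- generate_record(sp, 10, noise_sd = 0)
  den <- denoise(clean_rec)
  expect_length(den$samples, length(clean_rec$samples))
  rmse <- sqrt(mean((den$samples - clean_rec$samples)^2))
  expect_lt(rmse, 0.02 * diff(range(clean_rec$samples)))

  set.seed(3)
  noisy <- generate_record(sp, 10, noise_sd = noise_sd_for_snr(10))
  den10 <- denoise(noisy)
  expect_lt(sqrt(mean((den10$samples - noisy$clean)^2)),
            sqrt(mean((noisy$samples - noisy$clean)^2)))

  # near-idempotent: a second pass changes far less than the first
  den2 <- denoise(den10)
  d1 <- sqrt(mean((den10$samples - noisy$samples)^2))
  d2 <- sqrt(mean((den2$samples - den10$samples)^2))
  expect_lt(d2, 0.1 * d1)
})

test_that("segmentation recovers generator cycle boundaries", {
  sp <- default_class_specs(1)$H1
  set.seed(4)
  rec <- generate_record(sp, 10, noise_sd = noise_sd_for_snr(20),
                         wander_amplitude = 0.05)
  cycles <- segment_cycles(denoise(rec))
  expect_length(cycles, 10)
  feet <- attr(cycles, "feet")
  err <- vapply(rec$true_boundaries, function(b) min(abs(feet - b)), 0)
  expect_true(all(err <= 3))

  # single clean cycle -> one cycle
  set.seed(5)
  one <- generate_record(sp, 1, noise_sd = 0)
  expect_length(segment_cycles(one), 1)

  # flat signal -> empty with a warning, not an error
  flat <- list(samples = rep(1, 200), fs = 100, subject_id = "f")
  expect_warning(out <- segment_cycles(flat), "no detectable cycles")
  expect_length(out, 0)
})

test_that("resampling is linear, endpoint-exact and identity at 200", {
  ramp <- 0:49
  r <- resample_cycle(ramp, 200)
  expect_length(r, 200)
  expect_identical(r[1], 0)
  expect_identical(r[200], 49)
  # linear interpolation is exact on a line
  expect_equal(r, seq(0, 49, length.out = 200), tolerance = 1e-12)

  x200 <- sin(seq(0, 2 * pi, length.out = 200))
  expect_equal(resample_cycle(x200, 200), x200, tolerance = 1e-12)

  set.seed(6)
  cy <- pulse_cycle(rnorm(77), fs = 100)
  expect_length(resample_cycle(cy), 200)
  expect_error(resample_cycle(c(1)), "at least 2")
})

test_that("amplitude normalization maps any non-constant cycle onto 0-200", {
  v <- c(1, 2, 3, rep(2, 197))
  nv <- normalize_amplitude(v)
  expect_equal(min(nv), 0)
  expect_equal(max(nv), 200)
  expect_equal(unclass(nv)[2], 100)
  # idempotent
  expect_equal(unclass(normalize_amplitude(nv)), unclass(nv))
  expect_error(normalize_amplitude(rep(1, 200)), "degenerate")
})

test_that("rasterization follows the row convention and is invertible", {
  set.seed(7)
  v <- normalize_amplitude(generate_cycle(default_class_specs(1)$Ha, 200))
  img <- rasterize(v)
  expect_identical(dim(img), c(200L, 200L))
  expect_true(all(img %in% c(0L, 255L)))
  # exactly one contiguous foreground run per column
  for (x in seq(1, 200, by = 7)) {
    fg <- which(img[, x] > 0)
    expect_identical(fg, fg[1]:fg[length(fg)])
  }
  # amplitude v maps to 0-based row 199 - round(v) from the top (y up)
  expect_identical(which(img[, 1] > 0),
                   as.integer(200 - pmin(199, floor(unclass(v)[1] + 0.5))))

  # quantization-bound round trip
  expect_lte(max(abs(image_to_values(img) - unclass(v))), 1)

  # alternating extremes force full-height connecting runs
  alt <- structure(rep(c(0, 200), 100), class = "normalized_cycle")
  img2 <- rasterize(alt)
  expect_true(all(colSums(img2[, -1] > 0) == 200))
  expect_lte(max(abs(image_to_values(img2) - rep(c(0, 199), 100))), 1)

  expect_error(rasterize(structure(rep(-1, 200), class = "normalized_cycle")),
               "\\[0, 200\\]")
})

test_that("preprocess_record yields one 200-point cycle and image per beat", {
  set.seed(8)
  for (sp in default_class_specs(1)[c("H1", "At")]) {
    rec <- generate_record(sp, 6, noise_sd = noise_sd_for_snr(20),
                           wander_amplitude = 0.05)
    pp <- preprocess_record(rec)
    expect_gt(length(pp$images), 0)
    expect_length(pp$normalized, length(pp$images))
    for (i in seq_along(pp$images)) {
      expect_length(pp$normalized[[i]], 200)
      expect_equal(min(pp$normalized[[i]]), 0)
      expect_equal(max(pp$normalized[[i]]), 200)
      expect_identical(dim(pp$images[[i]]), c(200L, 200L))
    }
  }
})

test_that("pulse images and records survive file round trips", {
  img <- toy_image(1)
  f <- tempfile(fileext = ".png")
  write_pulse_png(img, f)
  expect_identical(unclass(read_pulse_png(f))[, ], unclass(img)[, ])

  set.seed(9)
  rec <- generate_record(default_class_specs(1)$Td, 3)
  f2 <- tempfile(fileext = ".csv")
  write_record_csv(rec, f2)
  back <- read_record_csv(f2, subject_id = "S1")
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)
  expect_equal(back$fs, rec$fs, tolerance = 1e-6)
})
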