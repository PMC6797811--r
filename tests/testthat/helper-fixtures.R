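# Shared fixtures, all generated in code.

# Single-component spec with no jitter: closed-form Gaussian bump.
bump_spec <- function(amplitude = 1, center = 0.2, width = 0.05) {
  pulse_class_spec("bump",
                   list(pulse_component(amplitude, center, width)),
                   jitter = c(amplitude = 0, center = 0, width = 0))
}

# A cohort entry with just the fields screening needs.
subject <- function(id, diseases = character(0), systolic = 120,
                    diastolic = 75, cavi = 7.5, bapwv = 1200,
                    viscosity = 4.2) {
  list(subject_id = id, diseases = diseases, systolic = systolic,
       diastolic = diastolic, cavi = cavi, bapwv = bapwv,
       viscosity = viscosity)
}

# n fake image entries for dataset-builder tests (images need not be
# 200 x 200 until they are persisted).
fake_entries <- function(pattern, n, img = matrix(0L, 2, 2)) {
  lapply(seq_len(n), function(i)
    list(image = img, subject_id = paste0(pattern, "s", (i - 1) %/% 10 + 1),
         cycle_index = i))
}

# Deterministic 200 x 200 test image from a smooth normalized cycle.
toy_image <- function(seed = 1) {
  set.seed(seed)
  v <- normalize_amplitude(generate_cycle(bump_spec(center = runif(1, 0.2, 0.6)), 200))
  rasterize(v)
}

# Small labelled image set for CNN unit tests: class 1 curves sit in the
# lower half of the frame, class 2 in the upper half (disjoint regions).
separable_images <- function(n_per_class = 15, size = 40, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(0, c(n, size, size))
  y <- integer(n)
  for (i in seq_len(n)) {
    cls <- (i - 1) %/% n_per_class + 1
    row0 <- if (cls == 1) size - 6 else 4
    rows <- pmin(size - 1, pmax(2, row0 + round(2 * sin(seq_len(size) / 4) +
                                                  rnorm(size, 0, 0.4))))
    for (j in seq_len(size)) x[i, rows[j], j] <- 1
    y[i] <- cls
  }
  list(x = x, y = y)
}

tiny_arch <- function(n_classes = 2, input_size = 40)
  cnn_architecture(n_classes, channels = c(2, 3, 4), kernel = 3,
                   pools = c(2, 2, 2), fc_hidden = 8, dropout = 0.25,
                   input_size = input_size)
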