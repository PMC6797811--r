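#' @useDynLib pulsecnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm runif sd median mad var
#' @importFrom utils read.csv write.csv head tail
NULL

# Disease vocabulary for the disease-based classification criterion and the
# abbreviations used in comorbidity labels.
.disease_vocab <- c("hypertension", "atherosclerosis", "hyperlipidaemia",
                    "type 2 diabetes")

.disease_abbrev <- c(Hn = "hypertension", At = "atherosclerosis",
                     Ha = "hyperlipidaemia", Td = "type 2 diabetes",
                     HF = "heart failure")

#' Describe one sub-wave of a pulse cycle
#'
#' A pulse cycle is modelled as a superposition of bell-shaped (Gaussian)
#' components: the percussion wave (main systolic peak), the tidal wave
#' (late-systolic reflection) and the dicrotic wave (diastolic rebound).
#'
#' @param amplitude Relative height, >= 0 (percussion is conventionally 1).
#' @param center Peak location as a fraction of the cycle duration, in (0, 1).
#' @param width Gaussian standard deviation as a fraction of the cycle
#'   duration, in (0, 0.5).
#' @return A `pulse_component` list.
#' @export
pulse_component <- function(amplitude, center, width) {
  stopifnot(is.numeric(amplitude), amplitude >= 0,
            is.numeric(center), center > 0, center < 1,
            is.numeric(width), width > 0, width < 0.5)
  structure(list(amplitude = amplitude, center = center, width = width),
            class = "pulse_component")
}

#' Define a pulse-wave pattern class
#'
#' @param label Pattern name (e.g. "Hn", "H1", "BP").
#' @param components Named list of [pulse_component()]s, ordered
#'   percussion, tidal, dicrotic. The percussion amplitude must be the
#'   largest.
#' @param jitter Named numeric vector `c(amplitude=, center=, width=)` of
#'   relative standard deviations applied multiplicatively per draw.
#' @param cycle_s Named numeric vector `c(mean=, sd=)`: cycle duration in
#'   seconds.
#' @return A `pulse_class_spec` list.
#' @export
pulse_class_spec <- function(label, components,
                             jitter = c(amplitude = 0.05, center = 0.05,
                                        width = 0.05),
                             cycle_s = c(mean = 0.8, sd = 0.08)) {
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "pulse_component")))
  amps <- vapply(components, `[[`, 0, "amplitude")
  if (amps[[1]] < max(amps))
    stop("percussion (first component) amplitude must be the maximum")
  jitter <- jitter[c("amplitude", "center", "width")]
  stopifnot(!anyNA(jitter), all(jitter >= 0),
            cycle_s[["mean"]] > 0, cycle_s[["sd"]] >= 0)
  structure(list(label = label, components = components,
                 jitter = jitter, cycle_s = cycle_s),
            class = "pulse_class_spec")
}

.spec3 <- function(label, p, t, d, jitter, cycle_sd = 0.08) {
  pulse_class_spec(
    label,
    components = list(percussion = pulse_component(p[1], p[2], p[3]),
                      tidal      = pulse_component(t[1], t[2], t[3]),
                      dicrotic   = pulse_component(d[1], d[2], d[3])),
    jitter = c(amplitude = jitter, center = jitter, width = jitter))
}

#' Default pattern class specifications
#'
#' Qualitative, documented morphologies for the six disease-based patterns
#' (dataset 1: H1, Hn, At, Ha, Td, HCA) and the five parameter-based
#' patterns (dataset 2: H2, BP, CAVI, baPWV, BV). Dataset-1 classes differ
#' in overall waveform (distinct tidal/dicrotic placement and amplitude);
#' dataset-2 classes deliberately share a common morphology and differ only
#' in small local features under larger jitter, so single-parameter classes
#' interfere with each other.
#'
#' @param dataset 1, 2 or "all".
#' @return Named list of [pulse_class_spec()]s.
#' @export
default_class_specs <- function(dataset = "all") {
  j1 <- 0.05
  ds1 <- list(
    H1  = .spec3("H1",  c(1.00, 0.15, 0.050), c(0.45, 0.36, 0.070),
                 c(0.28, 0.66, 0.060), j1),
    Hn  = .spec3("Hn",  c(1.00, 0.16, 0.050), c(0.82, 0.33, 0.080),
                 c(0.14, 0.62, 0.060), j1),
    At  = .spec3("At",  c(1.00, 0.20, 0.090), c(0.68, 0.30, 0.110),
                 c(0.07, 0.68, 0.070), j1),
    Ha  = .spec3("Ha",  c(1.00, 0.17, 0.060), c(0.34, 0.41, 0.090),
                 c(0.32, 0.73, 0.070), j1),
    Td  = .spec3("Td",  c(1.00, 0.13, 0.045), c(0.56, 0.29, 0.060),
                 c(0.20, 0.56, 0.050), j1),
    HCA = .spec3("HCA", c(1.00, 0.18, 0.070), c(0.74, 0.44, 0.095),
                 c(0.10, 0.70, 0.060), j1))
  j2 <- 0.10
  ds2 <- list(
    H2    = .spec3("H2",    c(1.00, 0.16, 0.055), c(0.50, 0.33, 0.080),
                   c(0.20, 0.64, 0.060), j2),
    BP    = .spec3("BP",    c(1.00, 0.16, 0.055), c(0.68, 0.33, 0.080),
                   c(0.20, 0.64, 0.060), j2),
    CAVI  = .spec3("CAVI",  c(1.00, 0.16, 0.055), c(0.64, 0.34, 0.080),
                   c(0.20, 0.64, 0.060), j2),
    baPWV = .spec3("baPWV", c(1.00, 0.16, 0.055), c(0.66, 0.32, 0.080),
                   c(0.20, 0.64, 0.060), j2),
    BV    = .spec3("BV",    c(1.00, 0.16, 0.060), c(0.62, 0.33, 0.080),
                   c(0.20, 0.64, 0.060), j2))
  switch(as.character(dataset),
         "1" = ds1, "2" = ds2, all = c(ds1, ds2),
         stop("dataset must be 1, 2 or 'all'"))
}

.jitter_component <- function(comp, jitter) {
  a <- max(0, comp$amplitude * (1 + rnorm(1, 0, jitter[["amplitude"]])))
  c0 <- comp$center * (1 + rnorm(1, 0, jitter[["center"]]))
  w <- comp$width * (1 + rnorm(1, 0, jitter[["width"]]))
  list(amplitude = a,
       center = min(max(c0, 0.02), 0.98),
       width = min(max(w, 0.005), 0.45))
}

#' Generate one pulse cycle
#'
#' Evaluates the sum of the class's Gaussian components on a uniform grid
#' `t = (0:(n_points-1)) / n_points` over one cycle, with per-draw jitter
#' applied to component amplitude, center and width. Deterministic given the
#' R random seed.
#'
#' @param spec A [pulse_class_spec()].
#' @param n_points Number of samples, >= 16.
#' @param jitter Apply the spec's jitter? (`FALSE` gives the class mean
#'   curve.)
#' @return Numeric vector of length `n_points`.
#' @export
generate_cycle <- function(spec, n_points, jitter = TRUE) {
  stopifnot(inherits(spec, "pulse_class_spec"))
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 16)
    stop("n_points must be a single number >= 16")
  n_points <- as.integer(n_points)
  t <- (seq_len(n_points) - 1) / n_points
  y <- numeric(n_points)
  for (comp in spec$components) {
    cj <- if (jitter) .jitter_component(comp, spec$jitter) else comp
    y <- y + cj$amplitude * exp(-0.5 * ((t - cj$center) / cj$width)^2)
  }
  y
}

#' Convert a target signal-to-noise ratio to a relative noise level
#'
#' @param snr_db Target SNR in dB, defined as
#'   `10 * log10(var(clean) / var(noise))`.
#' @return Noise standard deviation relative to the clean-signal standard
#'   deviation, for use as `noise_sd` in [generate_record()].
#' @export
noise_sd_for_snr <- function(snr_db) 10^(-snr_db / 20)

#' Generate a multi-cycle pulse record
#'
#' Concatenates jittered cycles of the class, records the true cycle-start
#' boundaries, then adds white Gaussian noise and a slow sinusoidal baseline
#' wander. The clean (pre-noise) signal is retained for oracle use.
#'
#' @param spec A [pulse_class_spec()].
#' @param n_cycles Number of cycles, >= 1.
#' @param noise_sd White-noise standard deviation relative to the clean
#'   signal's standard deviation (see [noise_sd_for_snr()]).
#' @param wander_amplitude Baseline-wander amplitude relative to the clean
#'   signal range; frequency 0.3 Hz.
#' @param fs Sampling rate in Hz.
#' @param subject_id Identifier carried through the pipeline.
#' @return A `pulse_record` with fields `samples`, `fs`, `true_boundaries`
#'   (1-based cycle-start indices, one per cycle), `true_label`,
#'   `subject_id` and `clean`.
#' @export
generate_record <- function(spec, n_cycles, noise_sd = 0,
                            wander_amplitude = 0, fs = 100,
                            subject_id = "S1") {
  stopifnot(inherits(spec, "pulse_class_spec"))
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1)
    stop("n_cycles must be a single number >= 1")
  n_cycles <- as.integer(n_cycles)
  dur <- pmax(0.4, rnorm(n_cycles, spec$cycle_s[["mean"]],
                         spec$cycle_s[["sd"]]))
  lens <- pmax(16L, as.integer(round(dur * fs)))
  cycles <- lapply(lens, function(n) generate_cycle(spec, n))
  clean <- unlist(cycles, use.names = FALSE)
  bounds <- cumsum(c(1L, head(lens, -1L)))
  x <- clean
  if (wander_amplitude > 0) {
    tt <- (seq_along(x) - 1) / fs
    x <- x + wander_amplitude * diff(range(clean)) *
      sin(2 * pi * 0.3 * tt + runif(1, 0, 2 * pi))
  }
  if (noise_sd > 0)
    x <- x + rnorm(length(x), 0, noise_sd * sd(clean))
  structure(list(samples = x, fs = fs, true_boundaries = bounds,
                 true_label = spec$label, subject_id = subject_id,
                 clean = clean),
            class = "pulse_record")
}

#' Empirical signal-to-noise ratio of a synthetic record
#'
#' @param record A `pulse_record` produced by [generate_record()].
#' @return SNR in dB of `samples` relative to the stored clean signal
#'   (wander counted as noise).
#' @export
empirical_snr_db <- function(record) {
  stopifnot(inherits(record, "pulse_record"))
  noise <- record$samples - record$clean
  10 * log10(var(record$clean) / var(noise))
}

#' Default physiological-parameter model
#'
#' Maps a pattern label to a per-parameter sampling rule. Normal ranges
#' (systolic 100-140 mmHg, diastolic 60-90 mmHg, CAVI 6-9, baPWV 1000-1400
#' cm/s, viscosity 3.5-5) follow the screening thresholds; the pattern's own
#' parameter is drawn above its threshold. Disease patterns map onto the
#' physiologically matching parameter (hypertension -> blood pressure,
#' atherosclerosis -> CAVI, type 2 diabetes -> baPWV, hyperlipidaemia ->
#' blood viscosity).
#'
#' @return A function `(label) -> named list of c(lo, hi) ranges`.
#' @export
default_parameter_model <- function() {
  normal <- list(systolic = c(105, 138), diastolic = c(62, 88),
                 cavi = c(6.0, 8.8), bapwv = c(1050, 1380),
                 viscosity = c(3.6, 4.9))
  high <- list(bp = list(systolic = c(145, 180), diastolic = c(91, 108)),
               cavi = c(9.2, 12.0), bapwv = c(1430, 1800),
               viscosity = c(5.2, 7.0))
  function(label) {
    r <- normal
    if (label %in% c("Hn", "BP", "HCA")) {
      r$systolic <- high$bp$systolic
      r$diastolic <- high$bp$diastolic
    }
    if (label %in% c("At", "CAVI", "HCA")) r$cavi <- high$cavi
    if (label %in% c("Td", "baPWV")) r$bapwv <- high$bapwv
    if (label %in% c("Ha", "BV")) r$viscosity <- high$viscosity
    r
  }
}

.label_diseases <- function(label) {
  switch(label,
         H1 = , H2 = , BP = , CAVI = , baPWV = , BV = character(0),
         Hn = "hypertension", At = "atherosclerosis",
         Ha = "hyperlipidaemia", Td = "type 2 diabetes",
         HCA = c("hypertension", "atherosclerosis"),
         stop("unknown pattern label: ", label))
}

.parse_comorbidity <- function(key) {
  if (grepl("+", key, fixed = TRUE)) {
    abbr <- trimws(strsplit(key, "+", fixed = TRUE)[[1]])
    unname(vapply(abbr, function(a)
      if (a %in% names(.disease_abbrev)) .disease_abbrev[[a]] else a, ""))
  } else key
}

.draw_params <- function(ranges) {
  lapply(ranges, function(r) runif(1, r[1], r[2]))
}

#' Generate a labelled cohort of subjects with pulse records
#'
#' Each subject carries a disease set and physiological parameters
#' consistent with the intended pattern (e.g. a BP-pattern subject has only
#' blood pressure out of range) plus an attached multi-cycle pulse record.
#' Comorbid entries use "A+B" keys over the pattern abbreviations (Hn, At,
#' Ha, Td, HF) or literal disease names, and exist so that screening can
#' exclude them.
#'
#' @param class_mix Named integer vector/list: pattern label -> subject
#'   count.
#' @param comorbidity_mix Named integer vector/list: condition-set key ->
#'   subject count.
#' @param parameter_model See [default_parameter_model()].
#' @param class_specs Morphology specs by label; comorbid subjects fall back
#'   to the first ds1 spec matching one of their diseases, else "H1".
#' @param n_cycles_per_subject,noise_sd,wander_amplitude,fs Passed to
#'   [generate_record()].
#' @return List of subject profiles: `subject_id`, `diseases`, `systolic`,
#'   `diastolic`, `cavi`, `bapwv`, `viscosity`, `label`, `record`.
#' @export
generate_cohort <- function(class_mix = c(), comorbidity_mix = c(),
                            parameter_model = default_parameter_model(),
                            class_specs = default_class_specs("all"),
                            n_cycles_per_subject = 3, noise_sd = 0.02,
                            wander_amplitude = 0.05, fs = 100) {
  subjects <- list()
  idx <- 0L
  add_subject <- function(diseases, label, spec_label) {
    idx <<- idx + 1L
    id <- sprintf("S%04d", idx)
    pars <- .draw_params(parameter_model(label))
    spec <- class_specs[[spec_label]]
    if (is.null(spec)) spec <- class_specs[[1]]
    rec <- generate_record(spec, n_cycles_per_subject, noise_sd,
                           wander_amplitude, fs, subject_id = id)
    rec$true_label <- label
    subjects[[idx]] <<- c(list(subject_id = id, diseases = diseases),
                          pars, list(label = label, record = rec))
  }
  for (label in names(class_mix)) {
    n <- class_mix[[label]]
    if (n > 0) for (i in seq_len(n))
      add_subject(.label_diseases(label), label, label)
  }
  for (key in names(comorbidity_mix)) {
    n <- comorbidity_mix[[key]]
    diseases <- .parse_comorbidity(key)
    spec_label <- "H1"
    for (ab in names(.disease_abbrev))
      if (.disease_abbrev[[ab]] %in% diseases && ab %in% names(class_specs)) {
        spec_label <- ab
        break
      }
    if (n > 0) for (i in seq_len(n))
      add_subject(diseases, paste(diseases, collapse = "+"), spec_label)
  }
  subjects
}

#' Cohort metadata as a data frame
#'
#' @param cohort Output of [generate_cohort()].
#' @return A data.frame with one row per subject (diseases collapsed with
#'   ";").
#' @export
cohort_profiles <- function(cohort) {
  if (length(cohort) == 0)
    return(data.frame(subject_id = character(), diseases = character(),
                      systolic = numeric(), diastolic = numeric(),
                      cavi = numeric(), bapwv = numeric(),
                      viscosity = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$subject_id,
               diseases = paste(s$diseases, collapse = ";"),
               systolic = s$systolic, diastolic = s$diastolic,
               cavi = s$cavi, bapwv = s$bapwv, viscosity = s$viscosity,
               label = s$label, stringsAsFactors = FALSE)))
}
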