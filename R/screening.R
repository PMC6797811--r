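#' Screening thresholds for the parameter-based criterion
#'
#' All thresholds are exclusive lower bounds ("greater than" semantics).
#' Blood pressure is out of range when systolic > 140 mmHg OR diastolic >
#' 90 mmHg (the standard hypertension convention).
#'
#' @param bp_systolic,bp_diastolic mmHg.
#' @param cavi Cardio-ankle vascular index (dimensionless).
#' @param bapwv Brachial-ankle pulse-wave velocity, cm/s.
#' @param viscosity Blood viscosity (device units).
#' @param min_class_size Patterns with kept count not exceeding this are
#'   dropped entirely ("more than 20" rule).
#' @return A `screening_thresholds` list.
#' @export
screening_thresholds <- function(bp_systolic = 140, bp_diastolic = 90,
                                 cavi = 9.0, bapwv = 1400, viscosity = 5.0,
                                 min_class_size = 20) {
  vals <- c(bp_systolic, bp_diastolic, cavi, bapwv, viscosity,
            min_class_size)
  stopifnot(all(is.finite(vals)), all(vals > 0))
  structure(list(bp_systolic = bp_systolic, bp_diastolic = bp_diastolic,
                 cavi = cavi, bapwv = bapwv, viscosity = viscosity,
                 min_class_size = min_class_size),
            class = "screening_thresholds")
}

.decision <- function(subject_id, dataset, outcome, pattern = NA_character_,
                      reason = NA_character_) {
  data.frame(subject_id = subject_id, dataset = dataset, outcome = outcome,
             pattern = pattern, reason = reason, stringsAsFactors = FALSE)
}

#' Assign a pattern under the disease-based criterion (dataset 1)
#'
#' Exactly one allowed disease maps to its pattern; no disease maps to the
#' healthy control H1; hypertension together with atherosclerosis (and
#' nothing else) maps to the comorbid pattern HCA; any other multi-disease
#' combination or out-of-vocabulary disease is excluded.
#'
#' @param subject A subject profile (list with `subject_id` and `diseases`).
#' @param allowed_diseases Disease vocabulary; defaults to hypertension,
#'   atherosclerosis, hyperlipidaemia, type 2 diabetes.
#' @return One-row decision data.frame: `subject_id`, `dataset`, `outcome`
#'   (kept/excluded), `pattern`, `reason`.
#' @export
assign_pattern_ds1 <- function(subject, allowed_diseases = .disease_vocab) {
  d <- unique(tolower(trimws(subject$diseases)))
  d <- d[nzchar(d)]
  id <- subject$subject_id
  disease_pattern <- c("hypertension" = "Hn", "atherosclerosis" = "At",
                       "hyperlipidaemia" = "Ha", "type 2 diabetes" = "Td")
  if (length(d) == 0)
    return(.decision(id, 1L, "kept", pattern = "H1"))
  if (any(!d %in% tolower(allowed_diseases)))
    return(.decision(id, 1L, "excluded", reason = "disease_not_in_vocabulary"))
  if (length(d) == 1)
    return(.decision(id, 1L, "kept", pattern = unname(disease_pattern[d])))
  if (setequal(d, c("hypertension", "atherosclerosis")))
    return(.decision(id, 1L, "kept", pattern = "HCA"))
  .decision(id, 1L, "excluded", reason = "comorbid_combination")
}

#' Assign a pattern under the parameter-based criterion (dataset 2)
#'
#' Counts how many of the four physiological parameters are out of range
#' (blood pressure, CAVI, baPWV, blood viscosity). Exactly one out of range
#' maps to that parameter's pattern; none maps to the healthy control H2;
#' two or more are excluded.
#'
#' @param subject Profile with `systolic`, `diastolic`, `cavi`, `bapwv`,
#'   `viscosity`.
#' @param thresholds A [screening_thresholds()].
#' @return One-row decision data.frame (see [assign_pattern_ds1()]).
#' @export
assign_pattern_ds2 <- function(subject, thresholds = screening_thresholds()) {
  need <- c("systolic", "diastolic", "cavi", "bapwv", "viscosity")
  vals <- subject[need]
  if (any(vapply(vals, function(v) is.null(v) || !is.finite(v), TRUE)))
    stop("incomplete record: subject ", subject$subject_id,
         " is missing a physiological parameter")
  out <- c(
    BP    = subject$systolic > thresholds$bp_systolic ||
            subject$diastolic > thresholds$bp_diastolic,
    CAVI  = subject$cavi > thresholds$cavi,
    baPWV = subject$bapwv > thresholds$bapwv,
    BV    = subject$viscosity > thresholds$viscosity)
  k <- sum(out)
  id <- subject$subject_id
  if (k == 0) return(.decision(id, 2L, "kept", pattern = "H2"))
  if (k == 1) return(.decision(id, 2L, "kept", pattern = names(out)[out]))
  .decision(id, 2L, "excluded", reason = "multiple_parameters_out_of_range")
}

#' Screen a cohort under one classification criterion
#'
#' Applies the per-subject rule ([assign_pattern_ds1()] or
#' [assign_pattern_ds2()]), then drops every pattern whose kept count does
#' not exceed `min_class_size` (those subjects are re-marked excluded with
#' reason `class_too_small`). An optional quality gate excludes subjects
#' whose pulse record yields no valid cycle.
#'
#' @param cohort List of subject profiles (see [generate_cohort()]).
#' @param criteria 1 (disease-based) or 2 (parameter-based).
#' @param thresholds A [screening_thresholds()].
#' @param quality_gate If `TRUE`, subjects with an attached record that
#'   segments into zero valid cycles (or produces non-finite normalized
#'   values) are excluded with reason `abnormal_pulse_wave`.
#' @return List with `decisions` (one row per subject) and `kept_counts`
#'   (named vector of kept subjects per pattern).
#' @export
screen_cohort <- function(cohort, criteria = 1,
                          thresholds = screening_thresholds(),
                          quality_gate = FALSE) {
  if (length(cohort) == 0)
    return(list(decisions = data.frame(subject_id = character(0),
                                       dataset = integer(0),
                                       outcome = character(0),
                                       pattern = character(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE),
                kept_counts = integer(0)))
  rule <- if (criteria == 1) {
    function(s) assign_pattern_ds1(s)
  } else {
    function(s) assign_pattern_ds2(s, thresholds)
  }
  decisions <- do.call(rbind, lapply(cohort, function(s) {
    dec <- rule(s)
    if (quality_gate && dec$outcome == "kept" && !is.null(s$record)) {
      pp <- tryCatch(suppressWarnings(preprocess_record(s$record)),
                     error = function(e) list(images = list()))
      if (length(pp$images) == 0) {
        dec$outcome <- "excluded"
        dec$pattern <- NA_character_
        dec$reason <- "abnormal_pulse_wave"
      }
    }
    dec
  }))
  kept <- decisions$outcome == "kept"
  counts <- table(decisions$pattern[kept])
  small <- names(counts)[counts <= thresholds$min_class_size]
  drop <- kept & decisions$pattern %in% small
  decisions$outcome[drop] <- "excluded"
  decisions$reason[drop] <- "class_too_small"
  decisions$pattern[drop] <- NA_character_
  kept_counts <- table(decisions$pattern[decisions$outcome == "kept"])
  list(decisions = decisions,
       kept_counts = stats::setNames(as.integer(kept_counts),
                                     names(kept_counts)))
}

#' Write screening decisions to CSV
#'
#' @param screening Output of [screen_cohort()].
#' @param path CSV path.
#' @export
write_decisions_csv <- function(screening, path) {
  write.csv(screening$decisions, path, row.names = FALSE)
  invisible(path)
}
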