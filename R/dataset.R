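#' Dataset split configuration
#'
#' @param cycles_per_pattern Total cycles sampled per pattern (210).
#' @param train_per_pattern,test_per_pattern Split sizes (140/70); must sum
#'   to `cycles_per_pattern`.
#' @param seed Seed for the sampling and the split.
#' @return A `split_config` list.
#' @export
split_config <- function(cycles_per_pattern = 210, train_per_pattern = 140,
                         test_per_pattern = 70, seed = 1L) {
  stopifnot(cycles_per_pattern > 0, train_per_pattern > 0,
            test_per_pattern > 0,
            train_per_pattern + test_per_pattern == cycles_per_pattern)
  structure(list(cycles_per_pattern = cycles_per_pattern,
                 train_per_pattern = train_per_pattern,
                 test_per_pattern = test_per_pattern,
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Assemble a balanced image dataset with a train/test split
#'
#' Samples exactly `cycles_per_pattern` distinct cycles per pattern without
#' replacement, then assigns `train_per_pattern` of them to the training set
#' uniformly at random (seeded); the rest form the test set. The split is by
#' cycle, not by subject; the fraction of test cycles whose subject also
#' appears in the training set is recorded per pattern in attribute
#' `"leakage"`.
#'
#' @param images_by_pattern Named list: pattern label -> list of entries,
#'   each a list with `image` (200 x 200 `pulse_image`), `subject_id` and
#'   `cycle_index`.
#' @param cfg A [split_config()].
#' @param dataset_id 1 or 2.
#' @param split_by `"cycle"` (default): cycles are assigned to train/test
#'   individually, so one subject's cycles may appear in both splits.
#'   `"subject"`: whole subjects are assigned to a split before sampling
#'   cycles, guaranteeing zero subject leakage (quotas still exact; errors
#'   if a pattern's subjects cannot fill both quotas).
#' @return A `pulse_dataset`: `manifest` data.frame (pattern, split,
#'   subject_id, cycle_index, path), parallel `images` list, `dataset_id`,
#'   `labels` (pattern order).
#' @export
build_dataset <- function(images_by_pattern, cfg = split_config(),
                          dataset_id = 1L,
                          split_by = c("cycle", "subject")) {
  split_by <- match.arg(split_by)
  stopifnot(length(images_by_pattern) > 0,
            !is.null(names(images_by_pattern)))
  for (p in names(images_by_pattern))
    if (length(images_by_pattern[[p]]) < cfg$cycles_per_pattern)
      stop("pattern ", p, " supplies only ", length(images_by_pattern[[p]]),
           " cycles; ", cfg$cycles_per_pattern, " required")
  set.seed(cfg$seed)
  rows <- list()
  images <- list()
  leakage <- numeric(0)
  for (p in names(images_by_pattern)) {
    pool <- images_by_pattern[[p]]
    if (split_by == "cycle") {
      pick <- sample(length(pool), cfg$cycles_per_pattern)
      tr <- sample(cfg$cycles_per_pattern, cfg$train_per_pattern)
      split <- rep("test", cfg$cycles_per_pattern)
      split[tr] <- "train"
    } else {
      subj_all <- vapply(pool, function(e) as.character(e$subject_id), "")
      subjects <- sample(unique(subj_all))
      counts <- cumsum(table(factor(subj_all, levels = subjects))[subjects])
      n_test_subj <- which(counts >= cfg$test_per_pattern)[1]
      if (is.na(n_test_subj))
        stop("pattern ", p, ": not enough cycles for a subject-wise split")
      test_subj <- subjects[seq_len(n_test_subj)]
      test_pool <- which(subj_all %in% test_subj)
      train_pool <- which(!subj_all %in% test_subj)
      if (length(train_pool) < cfg$train_per_pattern)
        stop("pattern ", p, ": subjects cannot fill both quotas ",
             "in a subject-wise split")
      pick <- c(sample(train_pool, cfg$train_per_pattern),
                sample(test_pool, cfg$test_per_pattern))
      split <- rep(c("train", "test"),
                   c(cfg$train_per_pattern, cfg$test_per_pattern))
    }
    entries <- pool[pick]
    subj <- vapply(entries, function(e) as.character(e$subject_id), "")
    cyc <- vapply(entries, function(e) as.integer(e$cycle_index), 0L)
    if (anyDuplicated(paste(subj, cyc)))
      stop("pattern ", p, ": duplicate (subject_id, cycle_index) entries")
    path <- file.path(paste0("dataset_", dataset_id), p, split,
                      sprintf("%s_%03d.png", subj, cyc))
    rows[[p]] <- data.frame(pattern = p, split = split, subject_id = subj,
                            cycle_index = cyc, path = path,
                            stringsAsFactors = FALSE)
    images <- c(images, lapply(entries, `[[`, "image"))
    leakage[p] <- mean(subj[split == "test"] %in% subj[split == "train"])
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, images = images,
                 dataset_id = as.integer(dataset_id),
                 labels = names(images_by_pattern)),
            class = "pulse_dataset", leakage = leakage)
}

#' Persist / load a pulse image dataset
#'
#' `write_dataset()` writes one grayscale PNG per manifest entry under
#' `out_dir` (layout `dataset_<id>/<pattern>/<split>/<subject>_<cycle>.png`)
#' plus `manifest.csv`; `read_dataset()` loads them back. The round trip is
#' lossless for both pixels and manifest rows; images that are missing or
#' not 200 x 200 raise an integrity error.
#'
#' @param dataset A `pulse_dataset`.
#' @param out_dir Output directory.
#' @return `read_dataset()` returns a `pulse_dataset`.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "pulse_dataset"))
  m <- dataset$manifest
  for (i in seq_len(nrow(m))) {
    f <- file.path(out_dir, m$path[i])
    dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
    write_pulse_png(dataset$images[[i]], f)
  }
  meta <- cbind(m, dataset_id = dataset$dataset_id)
  write.csv(meta, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(out_dir) {
  mf <- file.path(out_dir, "manifest.csv")
  if (!file.exists(mf)) stop("integrity error: missing manifest.csv")
  meta <- read.csv(mf, stringsAsFactors = FALSE)
  images <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    f <- file.path(out_dir, meta$path[i])
    if (!file.exists(f)) stop("integrity error: missing image ", meta$path[i])
    img <- read_pulse_png(f)
    if (nrow(img) != 200 || ncol(img) != 200)
      stop("integrity error: image ", meta$path[i], " is ",
           nrow(img), "x", ncol(img), ", expected 200x200")
    images[[i]] <- img
  }
  structure(list(manifest = meta[names(meta) != "dataset_id"],
                 images = images,
                 dataset_id = as.integer(meta$dataset_id[1]),
                 labels = unique(meta$pattern)),
            class = "pulse_dataset")
}

# Stack a pulse_dataset split into an array (n x 200 x 200, pixels in
# [0, 1]) plus an integer label vector aligned with dataset$labels.
dataset_tensors <- function(dataset, split) {
  keep <- dataset$manifest$split == split
  imgs <- dataset$images[keep]
  n <- length(imgs)
  x <- array(0, c(n, 200, 200))
  for (i in seq_len(n)) x[i, , ] <- imgs[[i]] / 255
  y <- match(dataset$manifest$pattern[keep], dataset$labels)
  list(x = x, y = y)
}
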