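#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the order given by
#' `labels`.
#'
#' @param y_true,y_pred Equal-length label vectors drawn from `labels`.
#' @param labels Ordered class labels.
#' @return K x K integer matrix with `dimnames = list(true, predicted)`.
#' @export
confusion_matrix <- function(y_true, y_pred, labels) {
  stopifnot(length(y_true) == length(y_pred))
  if (any(!y_true %in% labels) || any(!y_pred %in% labels))
    stop("vocabulary error: labels outside the declared set")
  ft <- factor(y_true, levels = labels)
  fp <- factor(y_pred, levels = labels)
  cm <- unclass(table(ft, fp))
  dimnames(cm) <- list(true = labels, predicted = labels)
  storage.mode(cm) <- "integer"
  cm
}

#' Evaluation metrics from a confusion matrix
#'
#' For class c: TP = cm[c, c], FP = column sum - TP, FN = row sum - TP;
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F = 2PR/(P+R). Overall
#' accuracy = trace/total; overall precision/recall/F-measure are unweighted
#' (macro) class means; micro averages are also reported (on balanced
#' classes the two coincide). Divisions by zero yield 0 and are flagged.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return An `evaluation_report`: `per_class` data.frame (class, precision,
#'   recall, f_measure, support), `accuracy`, `macro` and `micro` summary
#'   vectors, `confusion`, `zero_division` flag.
#' @export
metrics_from_confusion <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty evaluation: all-zero confusion matrix")
  if (is.null(rownames(cm)))
    dimnames(cm) <- list(true = as.character(seq_len(nrow(cm))),
                         predicted = as.character(seq_len(ncol(cm))))
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  zero_division <- FALSE
  safe_div <- function(a, b) {
    out <- ifelse(b == 0, 0, a / ifelse(b == 0, 1, b))
    if (any(b == 0)) zero_division <<- TRUE
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(class = rownames(cm), precision = precision,
                          recall = recall, f_measure = f,
                          support = rowSums(cm), row.names = NULL,
                          stringsAsFactors = FALSE)
  accuracy <- sum(tp) / total
  macro <- c(precision = mean(precision), recall = mean(recall),
             f_measure = mean(f))
  micro_p <- sum(tp) / sum(tp + fp)
  micro_r <- sum(tp) / sum(tp + fn)
  micro <- c(precision = micro_p, recall = micro_r,
             f_measure = 2 * micro_p * micro_r / (micro_p + micro_r))
  structure(list(per_class = per_class, accuracy = accuracy, macro = macro,
                 micro = micro, confusion = cm,
                 zero_division = zero_division),
            class = "evaluation_report")
}

# Round half away from zero at `digits` decimals (used for the printed
# 2-decimal tables; base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (", nrow(x$confusion), " classes, ",
      sum(x$confusion), " samples)\n", sep = "")
  tab <- x$per_class
  tab[2:4] <- lapply(tab[2:4], function(v) sprintf("%.2f", round_half_up(v)))
  print(tab, row.names = FALSE)
  cat(sprintf("Overall accuracy %.2f | macro P %.2f R %.2f F %.2f\n",
              round_half_up(x$accuracy), round_half_up(x$macro[1]),
              round_half_up(x$macro[2]), round_half_up(x$macro[3])))
  invisible(x)
}

#' Write evaluation artifacts
#'
#' Writes `metrics.csv` (full precision, per-class rows plus an overall
#' row), `metrics_rounded.csv` (2 decimals, half-up, mirroring the printed
#' tables), `confusion.csv`, and `curves.csv` when a training history is
#' supplied.
#'
#' @param report An `evaluation_report`.
#' @param out_dir Output directory (created if needed).
#' @param history Optional training-history data.frame (epoch, cost,
#'   train_error, test_error).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, out_dir, history = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pc <- report$per_class
  overall <- data.frame(class = "overall",
                        precision = report$macro[["precision"]],
                        recall = report$macro[["recall"]],
                        f_measure = report$macro[["f_measure"]],
                        support = sum(pc$support),
                        stringsAsFactors = FALSE)
  metrics <- rbind(pc, overall)
  metrics$accuracy <- c(rep(NA, nrow(pc)), report$accuracy)
  paths <- file.path(out_dir, c("metrics.csv", "metrics_rounded.csv",
                                "confusion.csv"))
  write.csv(metrics, paths[1], row.names = FALSE)
  rounded <- metrics
  num <- vapply(rounded, is.numeric, TRUE)
  rounded[num] <- lapply(rounded[num], round_half_up)
  write.csv(rounded, paths[2], row.names = FALSE)
  cm <- as.data.frame.matrix(report$confusion)
  cm <- cbind(true = rownames(report$confusion), cm)
  write.csv(cm, paths[3], row.names = FALSE)
  if (!is.null(history)) {
    p4 <- file.path(out_dir, "curves.csv")
    write.csv(history, p4, row.names = FALSE)
    paths <- c(paths, p4)
  }
  invisible(paths)
}
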