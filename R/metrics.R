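#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted classes; pure counts.
#'
#' @param true,pred Equal-length integer label vectors with values in
#'   `0 .. K - 1`.
#' @param n_classes Number of classes K.
#' @return K x K integer matrix.
#' @export
confusion_matrix <- function(true, pred, n_classes) {
  if (length(true) != length(pred))
    stop("`true` and `pred` must have the same length")
  K <- as.integer(n_classes)
  true <- as.integer(true); pred <- as.integer(pred)
  if (any(true < 0L | true >= K) || any(pred < 0L | pred >= K))
    stop("labels must lie in 0 .. n_classes - 1")
  cm <- matrix(tabulate(true * K + pred + 1L, nbins = K * K),
               K, K, byrow = TRUE)
  dimnames(cm) <- list(true = 0:(K - 1L), pred = 0:(K - 1L))
  cm
}

#' The six evaluation metrics from a confusion matrix
#'
#' Per class c (one-vs-rest): TP, FP, FN, TN are read off the matrix;
#' precision = TP/(TP+FP), sensitivity = recall = TP/(TP+FN),
#' specificity = TN/(TN+FP) and F = 2PR/(P+R), with the 0/0 convention
#' of 0. The summary values are the macro (unweighted) averages over
#' classes by default; `average = "micro"` pools the per-class counts
#' instead. Accuracy is trace/total either way. Sensitivity and recall
#' are the same quantity under either averaging and are reported with
#' both names.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param average `"macro"` (default) or `"micro"`.
#' @return Object of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `sensitivity`, `specificity`, `f_measure` (all in
#'   `[0, 1]`), plus a `per_class` data.frame and the matrix itself.
#' @export
compute_metrics <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("`cm` must be a square matrix")
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, tp + fp)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * prec * sens, prec + sens)
  per_class <- data.frame(class = seq_len(nrow(cm)) - 1L,
                          precision = prec, sensitivity = sens,
                          specificity = spec, f_measure = f1)
  if (average == "macro") {
    out <- list(precision = mean(prec), sensitivity = mean(sens),
                specificity = mean(spec), f_measure = mean(f1))
  } else {
    mp <- safe_div(sum(tp), sum(tp + fp))
    ms <- safe_div(sum(tp), sum(tp + fn))
    out <- list(precision = mp, sensitivity = ms,
                specificity = safe_div(sum(tn), sum(tn + fp)),
                f_measure = safe_div(2 * mp * ms, mp + ms))
  }
  structure(c(list(accuracy = sum(tp) / total), out,
              list(recall = out$sensitivity, average = average,
                   per_class = per_class, confusion = cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics (%s-averaged over %d classes, n = %d)\n",
              x$average, nrow(x$confusion), sum(x$confusion)))
  for (f in c("accuracy", "precision", "recall", "sensitivity",
              "specificity", "f_measure"))
    cat(sprintf("  %-12s %.4f\n", f, x[[f]]))
  invisible(x)
}

#' Write a metrics report as JSON and/or one-line CSV
#'
#' @param report A `metrics_report`.
#' @param json_path,csv_path Optional output paths.
#' @param provenance Optional named list embedded in the outputs.
#' @return The JSON string, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL,
                          provenance = NULL) {
  fields <- c("accuracy", "precision", "recall", "sensitivity",
              "specificity", "f_measure")
  payload <- c(report[fields],
               list(average = report$average,
                    confusion = unname(report$confusion)),
               provenance)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(json_path)) writeLines(js, json_path)
  if (!is.null(csv_path)) {
    row <- as.data.frame(report[fields])
    con <- file(csv_path, "w")
    on.exit(close(con))
    if (!is.null(provenance))
      writeLines(paste0("# ", paste(names(provenance), unlist(provenance),
                                    sep = "=", collapse = " ")), con)
    utils::write.csv(row, con, row.names = FALSE)
  }
  invisible(js)
}
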