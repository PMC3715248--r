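# Matching-matrix construction, per-class metrics, ROC points and
# cross-scene aggregation.
#
# Conventions: rows of the matching matrix are the truth class, columns the
# predicted class, order fixed to (FRUIT, STEM, LEAF, BRANCH, BACKGROUND).
# All rates are percentages in [0,100]. The printed FP-rate formula omits
# the x100 factor; it is returned as a percentage here for consistency with
# every other rate. Undefined metrics (class absent from truth, or never
# predicted) are NA, never silently zero.

#' Matching (confusion) matrix of a classification
#'
#' Counts pixels by (truth class, predicted class). Pixels whose truth label
#' is in `ignore` are excluded from evaluation (by default only `UNLABELED`,
#' so partial manual annotations are handled).
#'
#' @param pred,truth `vineseg_label_map`s of equal dimensions; `truth` must
#'   be fully labelled over the evaluated pixels.
#' @param ignore Character vector of truth labels to exclude.
#' @return A `vineseg_confusion`: integer 5 x 5 `counts` matrix plus the
#'   evaluated pixel `total`.
#' @export
confusion <- function(pred, truth, ignore = "UNLABELED") {
  if (!identical(dim(pred), dim(truth))) {
    stop("dimension mismatch between pred and truth", call. = FALSE)
  }
  classes <- vineseg_classes()
  keep <- !(as.vector(truth) %in% ignore)
  t_f <- factor(as.vector(truth)[keep], levels = classes)
  p_f <- factor(as.vector(pred)[keep], levels = classes)
  if (anyNA(t_f)) {
    stop("truth contains labels outside the five classes that are not in ",
         "the ignore set", call. = FALSE)
  }
  if (anyNA(p_f)) {
    stop("pred contains UNLABELED pixels over the evaluated region",
         call. = FALSE)
  }
  counts <- unclass(table(truth = t_f, pred = p_f))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, total = sum(counts)),
            class = "vineseg_confusion")
}

#' Construct a confusion object from a counts matrix
#'
#' For synthetic matrices in tests and for metrics recomputation; rows are
#' truth, columns prediction, in the fixed class order.
#'
#' @param counts Non-negative 5 x 5 integer matrix.
#' @return A `vineseg_confusion`.
#' @export
as_confusion <- function(counts) {
  classes <- vineseg_classes()
  counts <- as.matrix(counts)
  if (!all(dim(counts) == length(classes))) {
    stop("counts must be 5 x 5 in the fixed class order", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(truth = classes, pred = classes)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, total = sum(counts)),
            class = "vineseg_confusion")
}

#' @export
print.vineseg_confusion <- function(x, ...) {
  cat("<vineseg_confusion> ", x$total, " pixels\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @rdname confusion
#' @param x A `vineseg_confusion`.
#' @param ... Unused.
#' @method tidy vineseg_confusion
#' @export
tidy.vineseg_confusion <- function(x, ...) {
  df <- as.data.frame.table(x$counts, responseName = "n")
  tibble::as_tibble(df)
}

class_index <- function(i) {
  classes <- vineseg_classes()
  if (is.character(i)) i <- match(i, classes)
  if (is.na(i) || i < 1 || i > length(classes)) {
    stop("unknown class", call. = FALSE)
  }
  i
}

#' True positive rate (hit rate / recall) of one class
#'
#' `100 * diag_i / row_i`: the proportion of the class's true pixels that
#' were correctly labelled. `NA` when the class has no truth pixels.
#'
#' @param cm A `vineseg_confusion`.
#' @param i Class name or index.
#' @return Percentage in \[0,100\], or `NA`.
#' @export
tp_rate <- function(cm, i) {
  i <- class_index(i)
  row_total <- sum(cm$counts[i, ])
  if (row_total == 0) return(NA_real_)
  100 * cm$counts[i, i] / row_total
}

#' False positive rate of one class
#'
#' `100 * (col_i - diag_i) / (total - row_i)`: the proportion of pixels
#' outside class i that were wrongly given its label. Returned as a
#' percentage (the printed formula omits the factor). `NA` when no pixel
#' lies outside the class.
#'
#' @inheritParams tp_rate
#' @return Percentage in \[0,100\], or `NA`.
#' @export
fp_rate <- function(cm, i) {
  i <- class_index(i)
  outside <- cm$total - sum(cm$counts[i, ])
  if (outside == 0) return(NA_real_)
  100 * (sum(cm$counts[, i]) - cm$counts[i, i]) / outside
}

#' Precision of one class
#'
#' `100 * tP_i / (tP_i + fP_i)` where `tP_i` is the diagonal entry and
#' `fP_i` the rest of column i. `NA` when the class was never predicted.
#'
#' @inheritParams tp_rate
#' @return Percentage in \[0,100\], or `NA`.
#' @export
precision_class <- function(cm, i) {
  i <- class_index(i)
  col_total <- sum(cm$counts[, i])
  if (col_total == 0) return(NA_real_)
  100 * cm$counts[i, i] / col_total
}

#' Overall accuracy and error rate
#'
#' `100 * trace / total` and `100 * (total - trace) / total`; the two sum to
#' 100.
#'
#' @param cm A `vineseg_confusion`.
#' @return Named numeric vector `c(accuracy =, error_rate =)`.
#' @export
accuracy_and_error <- function(cm) {
  if (cm$total == 0) stop("empty matching matrix", call. = FALSE)
  tr <- sum(diag(cm$counts))
  c(accuracy = 100 * tr / cm$total,
    error_rate = 100 * (cm$total - tr) / cm$total)
}

#' Per-class metrics report for one scene
#'
#' One row per class with the hit rate, FP rate and precision, plus the
#' scene-level accuracy and error rate repeated on every row so reports
#' from several scenes stack with `bind_rows()`.
#'
#' @param cm A `vineseg_confusion`.
#' @param scene_id Scene identifier recorded in the report.
#' @return Tibble with columns `scene_id`, `class`, `tp_rate`, `fp_rate`,
#'   `precision`, `accuracy`, `error_rate`.
#' @export
metrics_report <- function(cm, scene_id = "scene") {
  classes <- vineseg_classes()
  acc <- accuracy_and_error(cm)
  tibble::tibble(
    scene_id = as.character(scene_id),
    class = classes,
    tp_rate = vapply(classes, function(cl) tp_rate(cm, cl), numeric(1),
                     USE.NAMES = FALSE),
    fp_rate = vapply(classes, function(cl) fp_rate(cm, cl), numeric(1),
                     USE.NAMES = FALSE),
    precision = vapply(classes, function(cl) precision_class(cm, cl),
                       numeric(1), USE.NAMES = FALSE),
    accuracy = acc[["accuracy"]],
    error_rate = acc[["error_rate"]]
  )
}

#' Evaluate a classification against ground truth
#'
#' Convenience wrapper: matching matrix plus [metrics_report()].
#'
#' @param pred,truth `vineseg_label_map`s.
#' @param scene_id Scene identifier.
#' @param ignore Truth labels excluded from evaluation.
#' @return Tibble as in [metrics_report()].
#' @export
evaluate_labels <- function(pred, truth, scene_id = "scene",
                            ignore = "UNLABELED") {
  metrics_report(confusion(pred, truth, ignore = ignore), scene_id)
}

#' ROC points from metrics reports
#'
#' One (FP rate, TP rate) point per class per scene, on \[0,100\] axes;
#' perfect classification sits at (0, 100). Rows with an undefined rate are
#' skipped with a warning.
#'
#' @param reports A metrics-report tibble (rows from one or more scenes).
#' @return Tibble with columns `class`, `scene_id`, `fp_rate`, `tp_rate`.
#' @export
roc_points <- function(reports) {
  if (nrow(reports) == 0) stop("no reports supplied", call. = FALSE)
  bad <- is.na(reports$tp_rate) | is.na(reports$fp_rate)
  if (any(bad)) {
    warning(sum(bad), " report rows with undefined rates skipped",
            call. = FALSE)
  }
  dplyr::select(reports[!bad, ], "class", "scene_id", "fp_rate", "tp_rate")
}

# Round half away from zero (base round() is banker's rounding); reported
# aggregates are printed to one decimal this way.
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Aggregate metrics over scenes
#'
#' Arithmetic means over scenes of the per-class hit rate, FP rate and
#' precision, and of the overall accuracy, reported to one decimal (half
#' away from zero). When a baseline summary is supplied the per-class
#' precision improvement in percentage points and the accuracy ratio
#' (one decimal) are included.
#'
#' @param reports Metrics-report tibble covering >= 1 scene.
#' @param baseline Optional metrics-report tibble of a comparison method on
#'   the same scenes.
#' @return A `vineseg_summary`: `per_class` tibble (`class`,
#'   `mean_tp_rate`, `mean_fp_rate`, `mean_precision`, and
#'   `improvement_points` when a baseline is given), `mean_accuracy`,
#'   `baseline_mean_accuracy`, `accuracy_ratio`, `n_scenes`.
#' @export
aggregate_scenes <- function(reports, baseline = NULL) {
  if (nrow(reports) == 0) stop("no reports supplied", call. = FALSE)
  summarise_reports <- function(rep) {
    missing_cls <- setdiff(vineseg_classes(), unique(rep$class))
    if (length(missing_cls) > 0) {
      stop("reports have mixed/missing class sets: ",
           paste(missing_cls, collapse = ", "), call. = FALSE)
    }
    per_class <- rep |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(
        mean_tp_rate = round_half_away(mean(.data$tp_rate)),
        mean_fp_rate = round_half_away(mean(.data$fp_rate)),
        mean_precision = round_half_away(mean(.data$precision)),
        .groups = "drop"
      ) |>
      dplyr::arrange(match(.data$class, vineseg_classes()))
    scene_acc <- dplyr::distinct(rep, .data$scene_id, .data$accuracy)
    list(per_class = per_class,
         mean_accuracy = round_half_away(mean(scene_acc$accuracy)),
         n = nrow(scene_acc))
  }
  main <- summarise_reports(reports)
  out <- list(per_class = main$per_class,
              mean_accuracy = main$mean_accuracy,
              baseline_mean_accuracy = NULL,
              accuracy_ratio = NULL,
              n_scenes = main$n)
  if (!is.null(baseline)) {
    base <- summarise_reports(baseline)
    out$per_class <- dplyr::left_join(
      out$per_class,
      dplyr::transmute(base$per_class, class = .data$class,
                       baseline_mean_precision = .data$mean_precision),
      by = "class"
    )
    out$per_class$improvement_points <- round_half_away(
      out$per_class$mean_precision - out$per_class$baseline_mean_precision
    )
    out$baseline_mean_accuracy <- base$mean_accuracy
    out$accuracy_ratio <- round_half_away(
      main$mean_accuracy / base$mean_accuracy
    )
  }
  structure(out, class = "vineseg_summary")
}

#' @export
print.vineseg_summary <- function(x, ...) {
  cat("<vineseg_summary> over ", x$n_scenes, " scene(s)\n", sep = "")
  print(x$per_class)
  cat("mean accuracy: ", x$mean_accuracy, "%\n", sep = "")
  if (!is.null(x$baseline_mean_accuracy)) {
    cat("baseline mean accuracy: ", x$baseline_mean_accuracy,
        "% (ratio ", x$accuracy_ratio, ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname aggregate_scenes
#' @param x A `vineseg_summary`.
#' @param ... Unused.
#' @method glance vineseg_summary
#' @export
glance.vineseg_summary <- function(x, ...) {
  tibble::tibble(
    n_scenes = x$n_scenes,
    mean_accuracy = x$mean_accuracy,
    baseline_mean_accuracy = x$baseline_mean_accuracy %||% NA_real_,
    accuracy_ratio = x$accuracy_ratio %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-scene metrics printed in the source study
#'
#' The per-scene hit rates, FP rates, precisions, accuracies and error rates
#' of both the sequential masking classifier (`method = "sequential"`) and
#' the RGB-only baseline (`method = "rgb_baseline"`) over the six field
#' scenes, exactly as printed. Baseline hit and FP rates were not printed
#' and are `NA`. These serve as worked-example inputs to
#' [aggregate_scenes()].
#'
#' @return Tibble with columns `method`, `scene_id`, `class`, `tp_rate`,
#'   `fp_rate`, `precision`, `accuracy`, `error_rate`.
#' @export
reported_scene_metrics <- function() {
  path <- system.file("extdata", "reported_scene_metrics.csv",
                      package = "vineseg", mustWork = TRUE)
  raw <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  long <- tidyr::pivot_longer(raw, cols = -c("method", "metric", "class"),
                              names_to = "scene_id", values_to = "value")
  wide <- tidyr::pivot_wider(long, names_from = "metric",
                             values_from = "value")
  totals <- dplyr::filter(wide, .data$class == "TOTAL") |>
    dplyr::select("method", "scene_id", "accuracy", "error_rate")
  per_class <- dplyr::filter(wide, .data$class != "TOTAL") |>
    dplyr::select(-"accuracy", -"error_rate")
  out <- dplyr::left_join(per_class, totals, by = c("method", "scene_id"))
  dplyr::arrange(out, .data$method, .data$scene_id,
                 match(.data$class, vineseg_classes()))
}
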