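#' Accuracy disparity across groups
#'
#' The fairness measure: the sample standard deviation of per-group
#' accuracies, sqrt(sum_i (Acc_i - mean(Acc))^2 / (|G| - 1)). Smaller is
#' fairer; 0 means exactly uniform performance.
#'
#' @param acc numeric vector of per-group accuracies in [0, 1] (length >= 2).
#' @return nonnegative scalar disparity.
#' @export
disparity <- function(acc) {
  if (length(acc) < 2) stop("disparity needs at least 2 groups")
  stats::sd(acc)
}

#' Harmonic combination of two disparities
#'
#' Combines a client-level and an attribute-level disparity into the
#' multilevel fairness score: 1 / (1/a + 1/b) (reciprocal-sum inverse,
#' without the factor 2 of the standard harmonic mean, so equal inputs give
#' x/2). Used for disparity-style quantities where smaller is better.
#'
#' @param a,b positive disparities.
#' @return their reciprocal-sum inverse.
#' @export
harmonic_disparity <- function(a, b) {
  if (a <= 0 || b <= 0) stop("inputs must be positive")
  1 / (1 / a + 1 / b)
}

#' Harmonic mean of two accuracies
#'
#' The standard harmonic mean 2 / (1/a + 1/b), used to combine worst-client
#' and worst-attribute accuracy into a single worst-case score (equal inputs
#' give the input back).
#'
#' @param a,b positive accuracies (fractions or percentages, consistently).
#' @return their harmonic mean.
#' @export
harmonic_accuracy <- function(a, b) {
  if (a <= 0 || b <= 0) stop("inputs must be positive")
  2 / (1 / a + 1 / b)
}

#' Overall (sample-size-weighted) accuracy
#'
#' @param predictions integer predicted labels.
#' @param labels integer true labels of equal length.
#' @return total correct / total rows.
#' @export
overall_accuracy <- function(predictions, labels) {
  if (length(predictions) == 0) stop("empty input")
  if (length(predictions) != length(labels)) stop("length mismatch")
  mean(predictions == labels)
}

#' Relative fairness improvement
#'
#' 100 * (baseline - new) / baseline, in percent: how much a disparity fell
#' relative to the baseline method's.
#'
#' @param baseline positive baseline disparity.
#' @param new the improved method's disparity.
#' @return improvement in percent.
#' @export
relative_improvement <- function(baseline, new) {
  if (baseline <= 0) stop("baseline must be positive")
  100 * (baseline - new) / baseline
}

#' Equal-opportunity-style gap between two attribute groups
#'
#' Default (`mode = "as_printed"`): the absolute difference of
#' P(Y = 1 | Yhat = 1, A = a) across the two attribute values (a
#' predictive-parity-style conditional, conditioning on the positive
#' prediction). `mode = "standard"`: the absolute TPR gap
#' |P(Yhat = 1 | Y = 1, A = 0) - P(Yhat = 1 | Y = 1, A = 1)|.
#' An empty conditioning cell yields NA with a warning.
#'
#' @param predictions 0/1 predicted labels.
#' @param labels 0/1 true labels.
#' @param attribute 0/1 sensitive-attribute vector.
#' @param mode `"as_printed"` or `"standard"`.
#' @return the gap in [0, 1], with attribute `"mode"`; NA if undefined.
#' @export
eo_gap <- function(predictions, labels, attribute,
                   mode = c("as_printed", "standard")) {
  mode <- match.arg(mode)
  stopifnot(all(predictions %in% 0:1), all(labels %in% 0:1),
            all(attribute %in% 0:1))
  rate <- function(cond, event) {
    if (!any(cond)) return(NA_real_)
    mean(event[cond])
  }
  vals <- vapply(0:1, function(a) {
    if (mode == "as_printed") {
      rate(predictions == 1 & attribute == a, labels == 1)
    } else {
      rate(labels == 1 & attribute == a, predictions == 1)
    }
  }, 0)
  if (anyNA(vals)) {
    warning("undefined conditional for one attribute group; gap is NA")
    return(structure(NA_real_, mode = mode))
  }
  structure(abs(vals[1] - vals[2]), mode = mode)
}

#' Worst-group true-positive rate
#'
#' min over attribute values of P(Yhat = 1 | A = a, Y = 1). Groups with no
#' positive labels are flagged (NA with warning).
#'
#' @inheritParams eo_gap
#' @return the minimum within-group TPR in [0, 1].
#' @export
worst_tpr <- function(predictions, labels, attribute) {
  stopifnot(all(predictions %in% 0:1), all(labels %in% 0:1))
  vals <- vapply(sort(unique(attribute)), function(a) {
    pos <- labels == 1 & attribute == a
    if (!any(pos)) return(NA_real_)
    mean(predictions[pos] == 1)
  }, 0)
  if (anyNA(vals)) {
    warning("attribute group(s) with no positive labels; worst TPR is NA")
    return(NA_real_)
  }
  min(vals)
}

#' Full fairness evaluation of a model on held-out federated data
#'
#' Computes per-client and per-attribute-group accuracies on the test rows,
#' the client/attribute disparities and their harmonic combination, the
#' worst-group accuracies and their harmonic mean, overall accuracy, and
#' (for binary label and a binary first attribute) the equal-opportunity gap
#' and worst-group TPR.
#'
#' @param state a `predictor_state`.
#' @param dataset the full [tabular_dataset()].
#' @param test_partition `federated_partition` view of held-out rows.
#' @param attribute_columns attribute columns defining the attribute groups.
#' @param eo_mode passed to [eo_gap()].
#' @return An object of class `metrics_report` (a list; see fields).
#' @export
evaluate_model <- function(state, dataset, test_partition, attribute_columns,
                           eo_mode = "as_printed") {
  rows_all <- sort(unlist(test_partition$client_rows))
  pred <- predict_class(state, dataset$features[rows_all, , drop = FALSE])
  truth <- dataset$labels[rows_all]

  # clients with no held-out rows cannot contribute an accuracy
  occupied <- vapply(test_partition$client_rows, length, 1L) > 0
  client_acc <- vapply(test_partition$client_rows[occupied], function(rows) {
    sel <- match(rows, rows_all)
    mean(pred[sel] == truth[sel])
  }, 0)

  combo <- do.call(paste, c(dataset$attributes[attribute_columns],
                            list(sep = ":")))
  groups <- factor(combo[rows_all])
  attr_acc <- vapply(levels(groups), function(gl) {
    sel <- groups == gl
    mean(pred[sel] == truth[sel])
  }, 0)

  disp_c <- if (length(client_acc) >= 2) disparity(client_acc) else NA_real_
  disp_a <- if (length(attr_acc) >= 2) disparity(attr_acc) else NA_real_
  harm_d <- if (!is.na(disp_c) && !is.na(disp_a) && disp_c > 0 && disp_a > 0) {
    harmonic_disparity(disp_c, disp_a)
  } else NA_real_
  worst_c <- min(client_acc)
  worst_a <- min(attr_acc)
  harm_w <- if (worst_c > 0 && worst_a > 0) {
    harmonic_accuracy(worst_c, worst_a)
  } else NA_real_

  eo <- NA_real_; wtpr <- NA_real_
  a1 <- dataset$attributes[[attribute_columns[1]]][rows_all]
  if (dataset$n_classes == 2 && all(a1 %in% 0:1)) {
    eo <- suppressWarnings(as.numeric(eo_gap(pred, truth, a1, mode = eo_mode)))
    wtpr <- suppressWarnings(worst_tpr(pred, truth, a1))
  }

  structure(
    list(client_accuracy = client_acc,
         attribute_accuracy = attr_acc,
         disparity_client = disp_c,
         disparity_attribute = disp_a,
         harmonic_disparity = harm_d,
         worst_client_acc = worst_c,
         worst_attribute_acc = worst_a,
         harmonic_worst_acc = harm_w,
         overall_acc = overall_accuracy(pred, truth),
         eo_gap = eo, eo_mode = eo_mode,
         worst_tpr = wtpr,
         n_test = length(rows_all)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  overall accuracy      : %.4f\n", x$overall_acc))
  cat(sprintf("  client disparity      : %.4f  (worst client acc %.4f)\n",
              x$disparity_client, x$worst_client_acc))
  if (!is.na(x$disparity_attribute)) {
    cat(sprintf("  attribute disparity   : %.4f  (worst attribute acc %.4f)\n",
                x$disparity_attribute, x$worst_attribute_acc))
  }
  if (!is.na(x$harmonic_disparity)) {
    cat(sprintf("  multilevel (harmonic) : disparity %.4f, worst acc %.4f\n",
                x$harmonic_disparity, x$harmonic_worst_acc))
  }
  if (!is.na(x$eo_gap)) {
    cat(sprintf("  EO gap (%s)   : %.4f, worst TPR %.4f\n",
                x$eo_mode, x$eo_gap, x$worst_tpr))
  }
  invisible(x)
}

#' Evaluate multilevel fairness under an unseen client distribution
#'
#' Re-partitions the held-out rows across clients with a fresh Dirichlet
#' draw at `alpha_eval` (simulating deployment hospitals whose data
#' distribution was not seen in training), rebuilds the groupings, and
#' computes the full metric suite on the new partition.
#'
#' @param state the trained `predictor_state`.
#' @param benchmark the benchmark whose test rows are evaluated.
#' @param alpha_eval positive Dirichlet concentration of the evaluation
#'   partition.
#' @param attribute_columns attribute columns (default the benchmark's).
#' @param seed seed of the evaluation partition.
#' @return A `metrics_report` on the repartitioned held-out data.
#' @export
agnostic_evaluate <- function(state, benchmark, alpha_eval,
                              attribute_columns = NULL, seed = 1L) {
  stopifnot(alpha_eval > 0)
  if (is.null(attribute_columns)) {
    attribute_columns <- benchmark$attribute_columns
  }
  ds <- benchmark$dataset
  test_rows <- sort(unlist(benchmark$test$client_rows))
  sub <- tabular_dataset(ds$features[test_rows, , drop = FALSE],
                         ds$labels[test_rows],
                         lapply(ds$attributes, `[`, test_rows))
  part <- partition_dirichlet(sub, benchmark$test$n_clients, alpha_eval,
                              seed = seed)
  evaluate_model(state, sub, part, attribute_columns)
}
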