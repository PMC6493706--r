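#' Confusion matrix of class proportions
#'
#' Cell proportions over all evaluated instances, with "electricity" the
#' positive class: `tn` (predicted no / actual no), `fn` (predicted no /
#' actual yes), `fp` (predicted yes / actual no), `tp` (predicted yes /
#' actual yes). Cells must sum to 1; inputs on the percentage scale are
#' normalised.
#'
#' @param tn,fn,fp,tp Cell values (proportions or percentages).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fn, fp, tp) {
  cells <- c(tn = tn, fn = fn, fp = fp, tp = tp)
  stopifnot(all(cells >= 0))
  s <- sum(cells)
  if (s <= 0) stop("confusion matrix cells sum to zero")
  cells <- cells / s
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
#' @method print confusion_matrix
print.confusion_matrix <- function(x, ...) {
  m <- matrix(100 * c(x$tn, x$fp, x$fn, x$tp), 2, 2,
              dimnames = list(predicted = c("no electricity",
                                            "electricity"),
                              actual = c("no electricity",
                                         "electricity")))
  print(round(m, 2))
  invisible(x)
}

#' Generate synthetic class instances from cluster proportions
#'
#' For each cluster, draws `draws_per_cluster` independent Bernoulli labels
#' with success probability equal to the cluster's observed electrified
#' proportion `k/n` — the randomised ground truth used to validate the
#' thresholded predictions.
#'
#' @param clusters Cluster data frame (every `n_households > 0`).
#' @param draws_per_cluster Number of labels per cluster (default 1).
#' @param seed Integer seed.
#' @return Integer matrix (`n_clusters` x `draws_per_cluster`) of 0/1
#'   labels.
#' @export
generate_synthetic_classes <- function(clusters, draws_per_cluster = 1,
                                       seed = 1) {
  stopifnot(draws_per_cluster >= 1)
  if (any(clusters$n_households == 0)) {
    stop("cluster with zero households cannot define a proportion")
  }
  prop <- clusters$n_electrified / clusters$n_households
  nc <- nrow(clusters)
  with_seed(seed, {
    matrix(rbinom(nc * draws_per_cluster,
                  1, rep(prop, draws_per_cluster)),
           nrow = nc, ncol = draws_per_cluster)
  })
}

#' Build a confusion matrix from predicted and true classes
#'
#' @param pred_class Binary vector of predicted classes (1 = electricity).
#' @param true_class Binary vector of true (synthetic) classes, same
#'   length.
#' @return A [confusion_matrix()] of cell proportions.
#' @export
build_confusion <- function(pred_class, true_class) {
  if (length(pred_class) != length(true_class)) {
    stop("predicted and true class vectors differ in length")
  }
  if (!length(pred_class)) stop("empty class vectors")
  confusion_matrix(
    tn = mean(pred_class == 0 & true_class == 0),
    fn = mean(pred_class == 0 & true_class == 1),
    fp = mean(pred_class == 1 & true_class == 0),
    tp = mean(pred_class == 1 & true_class == 1))
}

#' Accuracy, precision and sensitivity of a confusion matrix
#'
#' `accuracy = tn + tp`, `precision = tp / (tp + fp)` (positive predictive
#' value), `sensitivity = tp / (tp + fn)` (recall). Undefined metrics
#' (zero denominator) are returned as `NA` with a warning rather than
#' silently zeroed.
#'
#' @param matrix A [confusion_matrix()].
#' @return List with `accuracy`, `precision`, `sensitivity` as
#'   proportions.
#' @export
compute_metrics <- function(matrix) {
  stopifnot(inherits(matrix, "confusion_matrix"))
  tp <- matrix$tp; fp <- matrix$fp; fn <- matrix$fn; tn <- matrix$tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("precision undefined: no predicted positives")
    NA_real_
  }
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("sensitivity undefined: no actual positives")
    NA_real_
  }
  list(accuracy = tn + tp, precision = precision,
       sensitivity = sensitivity)
}

#' Validate predictions against synthetic classes
#'
#' Runs the full validation recipe: predicted classes are compared to
#' synthetic Bernoulli(k/n) class instances per cluster; with
#' `draws_per_cluster > 1` the confusion matrices are averaged over
#' draws.
#'
#' @param pred_class Binary vector of per-cluster predictions.
#' @param clusters Matching cluster data frame.
#' @param draws_per_cluster Synthetic instances per cluster.
#' @param seed Integer seed for the synthetic classes.
#' @return A validation report: `matrix` ([confusion_matrix()]),
#'   `accuracy`, `precision`, `sensitivity`, `n_evaluated`, `seed`.
#' @export
validate_predictions <- function(pred_class, clusters,
                                 draws_per_cluster = 1, seed = 1) {
  labels <- generate_synthetic_classes(clusters, draws_per_cluster, seed)
  cells <- c(tn = 0, fn = 0, fp = 0, tp = 0)
  for (d in seq_len(ncol(labels))) {
    cm <- build_confusion(pred_class, labels[, d])
    cells <- cells + c(cm$tn, cm$fn, cm$fp, cm$tp) / ncol(labels)
  }
  cm <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
  met <- compute_metrics(cm)
  structure(list(matrix = cm, accuracy = met$accuracy,
                 precision = met$precision,
                 sensitivity = met$sensitivity,
                 n_evaluated = as.integer(nrow(clusters) *
                                            draws_per_cluster),
                 seed = seed),
            class = "validation_report")
}

#' @export
#' @method print validation_report
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation over %d synthetic instances\n", x$n_evaluated))
  print(x$matrix)
  cat(sprintf("accuracy    %6.2f%%\nprecision   %6.2f%%\nsensitivity %6.2f%%\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$sensitivity))
  invisible(x)
}
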