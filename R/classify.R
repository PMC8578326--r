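## Recurrence-feature SVM classifier with nested leave-one-out
## cross-validation.

#' Recurrence feature vector of one multi-channel trace
#'
#' The full feature pipeline for one subject: z-score each channel, compute
#' the pairwise distance matrix of the (already multi-dimensional) trace,
#' apply the local-binary-pattern transform, mask the high-curvature code
#' band, and summarise the mask with the nine recurrence statistics.
#'
#' @param x numeric matrix (samples x channels) or vector; at least 3
#'   samples.
#' @param band code band for the binary mask (default `c(64, 191)`).
#' @param l_min,v_min minimum diagonal/vertical line lengths for the
#'   recurrence statistics (default 2).
#' @return Named numeric vector of length 9 (see [rqa_features()]).
#' @export
extract_features <- function(x, band = c(64L, 191L), l_min = 2L,
                             v_min = 2L) {
  xm <- as_series_matrix(x, min_n = 3L)
  xm <- apply(xm, 2L, zscore)
  D <- distance_matrix(xm)
  codes <- lotra_transform(D)
  mask <- code_band_mask(codes, band)
  rqa_features(mask, l_min = l_min, v_min = v_min)
}

#' Feature table for a cohort
#'
#' Applies [extract_features()] to every trace of a cohort.
#'
#' @param cohort a `"spiral_cohort"` from [synthetic_cohort()], or a list
#'   with elements `series` (list of matrices) and `labels` (0/1 vector).
#' @param band code band (default `c(64, 191)`).
#' @return List with `features` (n x 9 matrix), `labels` and `subject_ids`.
#' @export
cohort_features <- function(cohort, band = c(64L, 191L)) {
  feats <- t(vapply(cohort$series, extract_features, numeric(9), band = band))
  ids <- cohort$subject_ids
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(nrow(feats)))
  rownames(feats) <- ids
  list(features = feats, labels = as.integer(cohort$labels),
       subject_ids = ids)
}

#' Default SVM hyperparameter grid
#'
#' RBF-kernel grid: cost `{0.1, 1, 10, 100}` crossed with kernel width
#' gamma `{0.01, 0.1, 1, 10}` (applied to fold-standardised features).
#' Ordered so that deterministic tie-breaking picks the smallest cost, then
#' the smallest gamma.
#'
#' @return Data frame with columns `cost` and `gamma`.
#' @export
default_svm_grid <- function() {
  g <- expand.grid(gamma = c(0.01, 0.1, 1, 10),
                   cost = c(0.1, 1, 10, 100))[, c("cost", "gamma")]
  g[order(g$cost, g$gamma), , drop = FALSE]
}

# fit-and-predict one standardised SVM: centre/scale fitted on the training
# rows only, then applied to the test rows
.svm_fold <- function(x_train, y_train, x_test, cost, gamma) {
  mu <- colMeans(x_train)
  sc <- apply(x_train, 2L, sd)
  sc[sc == 0] <- 1  # constant feature in a fold: leave it centred
  xt <- sweep(sweep(x_train, 2L, mu), 2L, sc, "/")
  xs <- sweep(sweep(matrix(x_test, ncol = ncol(x_train)), 2L, mu), 2L, sc, "/")
  fit <- e1071::svm(xt, factor(y_train, levels = c(0L, 1L)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  as.integer(as.character(predict(fit, xs)))
}

#' Nested leave-one-out cross-validation of the recurrence-feature SVM
#'
#' Outer leave-one-out loop measures generalisation; for each outer fold an
#' inner leave-one-out loop over the remaining subjects selects the SVM
#' hyperparameters from `grid` by inner accuracy (ties broken towards the
#' smallest cost, then the smallest gamma). Feature standardisation is
#' fitted on each (inner-)training split only, so the held-out subject never
#' leaks into model selection or scaling.
#'
#' @param features numeric matrix, one row per subject.
#' @param labels binary labels (0/1), one per subject; at least 2 per class.
#' @param grid data frame of `cost`/`gamma` combinations
#'   (default [default_svm_grid()]).
#' @param seed integer recorded in the report; the procedure itself is
#'   deterministic.
#' @return Object of class `"lotra_cv"`: confusion counts, the rates from
#'   [classification_metrics()], per-fold chosen hyperparameters, and the
#'   outer predictions.
#' @export
nested_loocv <- function(features, labels, grid = default_svm_grid(),
                         seed = 1L) {
  x <- as.matrix(features)
  y <- as.integer(labels)
  n <- nrow(x)
  if (length(y) != n) stop("labels must match the feature rows")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (min(table(factor(y, levels = c(0L, 1L)))) < 2L)
    stop("need at least 2 subjects per class")
  if (anyNA(x) || !all(is.finite(x))) stop("features must be finite")
  stopifnot(all(c("cost", "gamma") %in% names(grid)))

  preds <- integer(n)
  chosen <- data.frame(cost = numeric(n), gamma = numeric(n))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (min(table(factor(y[tr], levels = c(0L, 1L)))) < 2L)
      stop("degenerate fold: a class would vanish from an inner training split")
    # inner LOO accuracy for every grid point
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      ok <- vapply(seq_along(tr), function(j) {
        itr <- tr[-j]
        p <- .svm_fold(x[itr, , drop = FALSE], y[itr],
                       x[tr[j], , drop = FALSE],
                       grid$cost[g], grid$gamma[g])
        p == y[tr[j]]
      }, logical(1))
      mean(ok)
    }, numeric(1))
    best <- which.max(acc)  # grid is ordered for deterministic ties
    chosen$cost[i] <- grid$cost[best]
    chosen$gamma[i] <- grid$gamma[best]
    preds[i] <- .svm_fold(x[tr, , drop = FALSE], y[tr],
                          x[i, , drop = FALSE],
                          grid$cost[best], grid$gamma[best])
  }

  tp <- sum(preds == 1L & y == 1L); fn <- sum(preds == 0L & y == 1L)
  fp <- sum(preds == 1L & y == 0L); tn <- sum(preds == 0L & y == 0L)
  metrics <- classification_metrics(tp = tp, fp = fp, tn = tn, fn = fn)
  structure(list(confusion = metrics$confusion, rates = metrics$rates,
                 notes = metrics$notes, fold_params = chosen,
                 predictions = preds, labels = y, seed = as.integer(seed)),
            class = "lotra_cv")
}

#' Diagnostic rates from a binary confusion matrix
#'
#' @param tp,fp,tn,fn nonnegative integer counts (positive class = disease).
#' @return Object of class `"classification_metrics"`: list with `confusion`
#'   (the four counts) and `rates` — accuracy, sensitivity, specificity,
#'   precision, recall (= sensitivity) and F1. A rate whose denominator is
#'   empty is reported as 0 and named in `notes`.
#' @examples
#' classification_metrics(tp = 55, fp = 1, tn = 14, fn = 0)
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  notes <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) {
      notes <<- c(notes, sprintf("%s undefined (empty denominator); reported as 0", what))
      return(0)
    }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else {
    notes <- c(notes, "F1 undefined; reported as 0"); 0
  }
  rates <- c(accuracy = (tp + tn) / total, sensitivity = sens,
             specificity = spec, precision = prec, recall = sens, f1 = f1)
  structure(list(confusion = counts, rates = rates, notes = notes),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, digits = 4, ...) {
  cat("confusion: ")
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$confusion["tp"],
              x$confusion["fp"], x$confusion["tn"], x$confusion["fn"]))
  print(round(x$rates, digits))
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' @export
print.lotra_cv <- function(x, digits = 4, ...) {
  n <- sum(x$confusion)
  cat(sprintf("nested leave-one-out cross-validation (%d subjects)\n", n))
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$confusion["tp"],
              x$confusion["fp"], x$confusion["tn"], x$confusion["fn"]))
  print(round(x$rates, digits))
  invisible(x)
}

#' @export
summary.lotra_cv <- function(object, ...) {
  cat(sprintf("outer folds: %d; hyperparameters chosen per fold:\n",
              length(object$predictions)))
  print(table(cost = object$fold_params$cost,
              gamma = object$fold_params$gamma))
  print(object)
  invisible(object)
}
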