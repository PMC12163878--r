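# PLS-DA classification: dummy coding, decision rules, class regrouping,
# and the standard figures of merit (ACC, sens, spec, FPR, FNR).

#' One-hot dummy coding for class labels
#'
#' @param labels Factor or character vector.
#' @param classes Class order (defaults to factor levels / sorted unique).
#' @return 0/1 matrix, one column per class; every row sums to 1.
#' @export
dummy_code <- function(labels, classes = NULL) {
  if (is.null(classes)) classes <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  if (!all(labels %in% classes)) stop("label outside class list: ",
                                      paste(setdiff(labels, classes), collapse = ", "))
  Y <- outer(labels, classes, `==`) * 1
  colnames(Y) <- classes
  Y
}

#' Fit a PLS-DA model
#'
#' Dummy-codes the class labels one-hot (one column per class, including
#' the binary case, so the argmax decision rule applies uniformly) and
#' fits a multi-response NIPALS PLS model to the dummy matrix.
#'
#' @param X Predictor matrix (preprocessed spectra).
#' @param labels Class label per row of `X`.
#' @param n_lv Number of latent variables.
#' @param classes Optional explicit class order.
#' @return A `plsda_model`: list with `classes`, the underlying `core`
#'   (`pls_model`) and the decision `rule` ("argmax").
#' @export
fit_plsda <- function(X, labels, n_lv, classes = NULL) {
  Y <- dummy_code(labels, classes)
  if (ncol(Y) < 2) stop("need at least 2 classes")
  if (any(colSums(Y) < 2)) stop("every class needs at least 2 training spectra")
  core <- fit_pls(X, Y, n_lv = n_lv)
  structure(list(classes = colnames(Y), core = core, rule = "argmax"),
            class = "plsda_model")
}

#' Predict class labels from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Predictor matrix.
#' @param n_lv Optional truncated component count.
#' @param type "class" for labels, "score" for the raw predicted dummy
#'   scores.
#' @param ... Unused.
#' @return Character vector of labels, or score matrix.
#' @export
predict.plsda_model <- function(object, newdata, n_lv = object$core$n_lv,
                                type = c("class", "score"), ...) {
  type <- match.arg(type)
  sc <- predict(object$core, newdata, n_lv = n_lv)
  colnames(sc) <- object$classes
  if (type == "score") return(sc)
  assign_class(sc, rule = object$rule, classes = object$classes)
}

#' Turn predicted class scores into labels
#'
#' Default rule is the argmax of the predicted dummy scores with ties
#' broken by the lowest class index. The alternative "threshold" rule
#' assigns the class whose score exceeds 0.5 and returns "unassigned" when
#' none (or several) do.
#'
#' @param scores Predicted dummy score matrix, columns aligned to `classes`.
#' @param rule "argmax" or "threshold".
#' @param classes Class labels for the columns.
#' @return Character label per row.
#' @export
assign_class <- function(scores, rule = c("argmax", "threshold"), classes = colnames(scores)) {
  rule <- match.arg(rule)
  scores <- rbind(scores)
  if (is.null(classes)) stop("class labels for score columns required")
  if (rule == "argmax") {
    classes[max.col(scores, ties.method = "first")]
  } else {
    hits <- scores > 0.5
    out <- rep("unassigned", nrow(scores))
    one <- rowSums(hits) == 1
    out[one] <- classes[apply(hits[one, , drop = FALSE], 1, which)]
    out
  }
}

#' Regroup class labels through an explicit mapping
#'
#' Used to build the three-class task (control / intermediate / high) from
#' four-class annotations by merging the 250 and 500 mg/kg doses.
#'
#' @param labels Label vector.
#' @param mapping Named character vector `old -> new`; labels absent from
#'   the mapping must not occur unless `keep_unmapped = TRUE`.
#' @param keep_unmapped Pass through labels not in the mapping.
#' @return Character vector of regrouped labels.
#' @export
regroup_classes <- function(labels, mapping, keep_unmapped = FALSE) {
  labels <- as.character(labels)
  hit <- labels %in% names(mapping)
  if (!keep_unmapped && !all(hit | labels %in% mapping))
    stop("unmapped label(s): ", paste(unique(labels[!hit & !(labels %in% mapping)]), collapse = ", "))
  labels[hit] <- unname(mapping[labels[hit]])
  labels
}

#' Classification figures of merit
#'
#' Per class, one-vs-rest: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' accuracy (TP+TN)/n, false-positive rate FP/(FP+TN) and false-negative
#' rate FN/(FN+TP), plus the confusion matrix (rows = truth) and macro
#' averages.
#'
#' @param y_true,y_pred Aligned label vectors.
#' @param classes Class order; defaults to the union of observed labels.
#' @return A `class_metrics` object: list with `per_class` (data frame),
#'   `confusion`, `macro` and overall `accuracy`.
#' @export
classification_metrics <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors must align")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% classes))
    stop("label outside class list")
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  n <- length(y_true)
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- n - tp - fn - fp
    data.frame(class = cl,
               acc = (tp + tn) / n,
               sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               fpr = if (tn + fp > 0) fp / (fp + tn) else NA_real_,
               fnr = if (tp + fn > 0) fn / (fn + tp) else NA_real_)
  }))
  structure(list(per_class = per, confusion = cm,
                 macro = colMeans(per[, -1], na.rm = TRUE),
                 accuracy = sum(diag(cm)) / n),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("overall accuracy %.3f\n", x$accuracy))
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}
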