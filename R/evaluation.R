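## Macro-averaged multiclass metrics: accuracy, macro F1, one-vs-rest macro
## AUC (exact rank statistic), macro AUPRC (average precision), and
## confusion matrices.  Macro averaging weights every class equally so that
## rare phenotypes count as much as common ones.

#' Classification accuracy
#'
#' @param pred,true Equal-length label vectors.
#' @return Fraction of positions where `pred == true`.
#' @export
accuracy <- function(pred, true) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(true)) stop("length mismatch")
  mean(as.character(pred) == as.character(true))
}

#' Macro-averaged F1 score
#'
#' Computes per-class F1 (harmonic mean of precision and recall, one class
#' versus the rest) over a fixed class vocabulary and returns the unweighted
#' mean.  A class with no true positives -- including one absent from both
#' `pred` and `true` -- contributes F1 = 0.
#'
#' @param pred,true Label vectors.
#' @param classes Class vocabulary; defaults to the union of observed labels.
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(pred, true, classes = NULL) {
  pred <- as.character(pred); true <- as.character(true)
  classes <- classes %||% sort(unique(c(pred, true)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & true == cl)
    fp <- sum(pred == cl & true != cl)
    fn <- sum(pred != cl & true == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

## One-vs-rest AUC via the rank (Mann-Whitney) statistic; ties get 0.5
## credit.  Returns NA when the class lacks positives or negatives.
ovr_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest AUC
#'
#' For each class, the area under the ROC curve of its probability column
#' against the one-vs-rest labels, computed exactly as the normalised
#' Mann-Whitney rank statistic (ties credited 0.5).  Classes without both a
#' positive and a negative example are skipped with a warning, and the mean
#' is taken over the remaining classes.
#'
#' @param scores Numeric matrix (samples x classes) of predicted scores;
#'   column order follows `classes`.
#' @param true True label vector.
#' @param classes Class vocabulary; defaults to `colnames(scores)`.
#' @return Macro AUC in `[0, 1]`.
#' @export
macro_auc <- function(scores, true, classes = colnames(scores)) {
  true <- as.character(true)
  aucs <- vapply(seq_along(classes), function(j)
    ovr_auc(scores[, j], true == classes[j]), numeric(1))
  if (anyNA(aucs))
    warning("class(es) without both positives and negatives skipped: ",
            paste(classes[is.na(aucs)], collapse = ", "))
  mean(aucs, na.rm = TRUE)
}

## Average precision (step-wise integral of the precision-recall curve),
## grouping tied scores at a single threshold.
average_precision <- function(scores, positive) {
  n_pos <- sum(positive)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  ## indices where the threshold actually drops (end of each tie group)
  last <- which(c(s[-length(s)] != s[-1L], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Macro-averaged area under the precision-recall curve
#'
#' Per-class average precision (step-wise integral over the ranking induced
#' by the class's score column, tied scores grouped at one threshold),
#' macro-averaged over the classes that have at least one positive example;
#' classes without positives are skipped with a warning.
#'
#' @inheritParams macro_auc
#' @return Macro AUPRC in `[0, 1]`.
#' @export
macro_auprc <- function(scores, true, classes = colnames(scores)) {
  true <- as.character(true)
  aps <- vapply(seq_along(classes), function(j)
    average_precision(scores[, j], true == classes[j]), numeric(1))
  if (anyNA(aps))
    warning("class(es) without positives skipped: ",
            paste(classes[is.na(aps)], collapse = ", "))
  mean(aps, na.rm = TRUE)
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes.  With
#' `normalize = TRUE` each nonempty row is divided by its support so rows
#' sum to 1.
#'
#' @param pred,true Label vectors.
#' @param classes Class vocabulary; defaults to the union of observed labels.
#' @param normalize Row-normalise the counts.
#' @return A `length(classes)` square matrix.
#' @export
confusion_matrix <- function(pred, true, classes = NULL, normalize = FALSE) {
  pred <- as.character(pred); true <- as.character(true)
  classes <- classes %||% sort(unique(c(pred, true)))
  m <- table(factor(true, levels = classes), factor(pred, levels = classes))
  m <- unclass(m)
  dimnames(m) <- list(true = classes, predicted = classes)
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs == 0, 1, rs)
  }
  m
}

## All four metrics for one task from hard labels + a score matrix.
task_metrics <- function(pred, true, scores, classes) {
  c(acc = accuracy(pred, true),
    f1 = macro_f1(pred, true, classes),
    auc = suppressWarnings(macro_auc(scores, true, classes)),
    auprc = suppressWarnings(macro_auprc(scores, true, classes)))
}

#' Evaluate a prediction bundle against true labels
#'
#' Computes accuracy, macro F1, macro AUC and macro AUPRC for the disease
#' task and, when the model has metadata decoders, for every metadata task
#' over the samples whose true value is observed.
#'
#' @param bundle A `kp_predictions` from [model_forward()].
#' @param meta Metadata data frame with true labels (`NA` = missing) and a
#'   `phenotype` column.
#' @param config The model's `kp_config`.
#' @return A data frame with one row per task and columns `task`, `n`,
#'   `acc`, `f1`, `auc`, `auprc`.
#' @export
evaluate_bundle <- function(bundle, meta, config) {
  labels <- predict_labels(bundle, config)
  rows <- list()
  rows[["disease"]] <- c(task_metrics(labels$phenotype,
                                      as.character(meta$phenotype),
                                      bundle$disease_probs,
                                      config$vocab$disease))
  n <- c(disease = nrow(meta))
  if (config$use_metadata) {
    cols <- c(age = "age_class", gender = "gender", bmi = "bmi_class",
              body_site = "body_site")
    for (task in KP_META_TASKS) {
      true <- as.character(meta[[cols[[task]]]])
      keep <- !is.na(true)
      n[[task]] <- sum(keep)
      if (!any(keep)) next
      scores <- bundle$meta_probs[[task]][keep, , drop = FALSE]
      if (task == "gender") scores <- cbind(1 - scores, scores)
      rows[[task]] <- task_metrics(labels[[cols[[task]]]][keep], true[keep],
                                   scores, config$vocab[[task]])
    }
  }
  out <- data.frame(task = names(rows), n = as.integer(n[names(rows)]),
                    do.call(rbind, rows), row.names = NULL)
  out
}
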