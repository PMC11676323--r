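# Independent brute-force oracles for the evaluation metrics.  These are
# deliberately naive (explicit loops, pairwise counting, threshold sweeps)
# and share no code with the package implementations.

oracle_accuracy <- function(pred, true) {
  hits <- 0
  for (i in seq_along(pred)) if (pred[i] == true[i]) hits <- hits + 1
  hits / length(pred)
}

oracle_macro_f1 <- function(pred, true, classes) {
  f1s <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- fp <- fn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == cl && true[i] == cl) tp <- tp + 1
      if (pred[i] == cl && true[i] != cl) fp <- fp + 1
      if (pred[i] != cl && true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  mean(f1s)
}

# AUC by exhaustive positive/negative pair counting (ties count 1/2).
oracle_ovr_auc <- function(scores, positive) {
  pos <- which(positive); neg <- which(!positive)
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) wins <- wins + 1
    else if (scores[i] == scores[j]) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

oracle_macro_auc <- function(scores, true, classes) {
  vals <- sapply(seq_along(classes), function(k)
    oracle_ovr_auc(scores[, k], true == classes[k]))
  mean(vals, na.rm = TRUE)
}

# Average precision by an explicit sweep over every distinct threshold.
oracle_average_precision <- function(scores, positive) {
  n_pos <- sum(positive)
  if (n_pos == 0) return(NA_real_)
  ap <- 0
  prev_recall <- 0
  for (th in sort(unique(scores), decreasing = TRUE)) {
    called <- scores >= th
    tp <- sum(called & positive)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

oracle_macro_auprc <- function(scores, true, classes) {
  vals <- sapply(seq_along(classes), function(k)
    oracle_average_precision(scores[, k], true == classes[k]))
  mean(vals, na.rm = TRUE)
}

# Cross-entropy pieces for the loss tests, computed directly from
# probabilities.
oracle_ce <- function(p, y_idx) -sum(log(p[cbind(seq_along(y_idx), y_idx)]))
oracle_bce <- function(p, y) -sum(y * log(p) + (1 - y) * log(1 - p))
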