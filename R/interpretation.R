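## Attribution-based interpretation: integrated gradients (IG) for input and
## fused-metadata importance to disease prediction, and layer conductance
## (LC) for hidden-node importance to metadata prediction.  Raw attributions
## are signed; importance scores are their absolute values, averaged over
## samples, over the task's classes, and over independently trained restarts.

## Midpoint Riemann discretisation of the path integral.
ig_alphas <- function(steps) (seq_len(steps) - 0.5) / steps

## Batch forward keeping the intermediates the gradient formulas need.
attr_forward <- function(model, x, obs_idx = NULL) {
  cfg <- model$config
  B <- nrow(x)
  Wm <- model$W * model$mask
  z1 <- x %*% Wm + rep(model$b1, each = B)
  h <- pmax(z1, 0)
  Pt <- fused <- obs <- NULL
  if (cfg$use_metadata) {
    Pt <- lapply(stats::setNames(KP_META_TASKS, KP_META_TASKS), function(t) {
      z <- h %*% model$A[[t]] + rep(model$a[[t]], each = B)
      if (t == "gender") sigmoid(z) else softmax_rows(z)
    })
    fusion <- fuse_metadata(Pt, obs_idx, cfg)
    fused <- fusion$fused
    obs <- fusion$observed
  }
  u <- if (cfg$use_metadata) cbind(h, do.call(cbind, fused[KP_META_TASKS]))
       else h
  pd <- softmax_rows(u %*% model$V + rep(model$cbias, each = B))
  list(Wm = Wm, z1 = z1, h = h, Pt = Pt, fused = fused, obs = obs, pd = pd)
}

## dF/dh for each sample (B x H), where F is the probability of
## `class_idx` under `task`.  For the disease task the derivative includes
## the indirect paths through predicted (fused) metadata.
dF_dh_batch <- function(model, fw, task, class_idx) {
  cfg <- model$config
  if (task == "disease") {
    P <- fw$pd
    dZd <- P[, class_idx] * (-P)
    dZd[, class_idx] <- dZd[, class_idx] + P[, class_idx]
    dU <- dZd %*% t(model$V)
    dh <- dU[, seq_len(cfg$n_hidden), drop = FALSE]
    if (cfg$use_metadata && cfg$fusion == "probabilities") {
      offset <- cfg$n_hidden
      for (t in KP_META_TASKS) {
        k <- task_width(cfg, t)
        dF <- dU[, offset + seq_len(k), drop = FALSE]
        offset <- offset + k
        miss <- which(!fw$obs[[t]])
        if (length(miss) == 0L) next
        dZ <- matrix(0, nrow(P), k)
        if (t == "gender") {
          pg <- fw$Pt[[t]][miss, 1L]
          dZ[miss, 1L] <- dF[miss, 1L] * pg * (1 - pg)
        } else {
          Pm <- fw$Pt[[t]][miss, , drop = FALSE]
          r <- dF[miss, , drop = FALSE]
          dZ[miss, ] <- Pm * (r - rowSums(r * Pm))
        }
        dh <- dh + dZ %*% t(model$A[[t]])
      }
    }
    return(dh)
  }
  if (!task %in% KP_META_TASKS) stop("unknown task: ", task)
  P <- fw$Pt[[task]]
  if (task == "gender") {
    sgn <- if (class_idx == 2L) 1 else -1   # male is the sigmoid's class
    dz <- sgn * P[, 1L] * (1 - P[, 1L])
    return(dz * matrix(model$A$gender[, 1L], nrow(P), model$config$n_hidden,
                       byrow = TRUE))
  }
  dZ <- P[, class_idx] * (-P)
  dZ[, class_idx] <- dZ[, class_idx] + P[, class_idx]
  dZ %*% t(model$A[[task]])
}

## Scalar target value per sample for completeness checks.
target_value <- function(model, fw, task, class_idx) {
  if (task == "disease") return(fw$pd[, class_idx])
  if (task == "gender") {
    p <- fw$Pt$gender[, 1L]
    return(if (class_idx == 2L) p else 1 - p)
  }
  fw$Pt[[task]][, class_idx]
}

#' Integrated gradients over input features
#'
#' Path-integral attribution: the gradient of the target output is
#' accumulated along the straight line from a baseline to the input
#' (midpoint rule), and each feature receives its accumulated gradient times
#' its displacement.  As the number of steps grows, the attributions sum to
#' the difference in the target output between input and baseline
#' (completeness).
#'
#' `model` is either a `kp_model` (the target is then the probability of
#' `target_class` for `task`) or, for generic use, a list with functions
#' `value(x)` and `grad(x)` defining an arbitrary differentiable scalar
#' function of the input vector.
#'
#' @param model A `kp_model`, or `list(value = , grad = )`.
#' @param x Input vector (one sample, model scale).
#' @param baseline Baseline vector; default all zeros ("absence of signal").
#' @param target_class Class index or label of the target output.
#' @param steps Number of path steps (default 50).
#' @param task Target task for a `kp_model` (default `"disease"`).
#' @param observed Optional one-row metadata data frame for the sample;
#'   default treats all metadata as missing (predicted and fused).
#' @return Named attribution vector with attributes `"value"`, `"baseline_value"`
#'   and `"completeness_gap"`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL,
                                 target_class = 1L, steps = 50,
                                 task = "disease", observed = NULL) {
  if (steps < 1) stop("steps must be >= 1")
  x <- as.numeric(x)
  baseline <- if (is.null(baseline)) numeric(length(x)) else as.numeric(baseline)
  if (length(baseline) != length(x)) stop("baseline length mismatch")

  if (inherits(model, "kp_model")) {
    class_idx <- resolve_class(model$config, task, target_class)
    obs_idx <- if (is.data.frame(observed))
      meta_indices(observed, model$config) else observed
    value_fn <- function(v) {
      fw <- attr_forward(model, matrix(v, 1L), obs_idx)
      target_value(model, fw, task, class_idx)[1L]
    }
    grad_fn <- function(v) {
      fw <- attr_forward(model, matrix(v, 1L), obs_idx)
      dh <- dF_dh_batch(model, fw, task, class_idx)
      dz1 <- dh * (fw$z1 > 0)
      as.numeric(fw$Wm %*% t(dz1))
    }
    nm <- model$config$species
  } else {
    value_fn <- model$value
    grad_fn <- model$grad
    nm <- names(x)
  }
  if (!all(is.finite(x)) || !all(is.finite(baseline)))
    stop("non-finite input or baseline")

  grad_sum <- numeric(length(x))
  for (a in ig_alphas(steps)) {
    g <- grad_fn(baseline + a * (x - baseline))
    if (!all(is.finite(g))) stop("non-finite gradient along the path")
    grad_sum <- grad_sum + g
  }
  ig <- (x - baseline) * grad_sum / steps
  names(ig) <- nm
  fx <- value_fn(x); f0 <- value_fn(baseline)
  structure(ig, value = fx, baseline_value = f0,
            completeness_gap = abs(sum(ig) - (fx - f0)))
}

resolve_class <- function(config, task, target_class) {
  vocab <- if (task == "disease") config$vocab$disease else config$vocab[[task]]
  if (is.character(target_class)) {
    idx <- match(target_class, vocab)
    if (is.na(idx)) stop("unknown class '", target_class, "' for task ", task)
    idx
  } else as.integer(target_class)
}

#' Layer conductance of the hidden nodes
#'
#' Neuron-level path attribution at the knowledge-primed hidden layer: along
#' the straight input path from baseline to input, each hidden node
#' accumulates the product of the downstream gradient of the target output
#' with respect to that node and the node's activation change along the path
#' (midpoint rule).  The per-node scores sum to the output difference
#' between input and baseline up to discretisation (layer completeness).
#'
#' @param model A `kp_model`.
#' @param x Input matrix (samples x species) or a single vector.
#' @param baseline Baseline vector (default zeros).
#' @param target List with `task` (a metadata task or `"disease"`) and
#'   `class` (index or label).
#' @param steps Number of path steps (default 50).
#' @param observed Optional metadata data frame aligned with `x`.
#' @return Matrix (samples x hidden nodes) of signed conductances, node
#'   names as colnames, with attribute `"completeness_gap"` (per sample).
#' @export
layer_conductance <- function(model, x, baseline = NULL,
                              target = list(task = "age", class = 1L),
                              steps = 50, observed = NULL) {
  if (steps < 1) stop("steps must be >= 1")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  S <- model$config$n_species
  baseline <- if (is.null(baseline)) numeric(S) else as.numeric(baseline)
  class_idx <- resolve_class(model$config, target$task, target$class)
  obs_idx <- if (is.data.frame(observed))
    meta_indices(observed, model$config) else observed

  B <- nrow(x)
  X0 <- matrix(baseline, B, S, byrow = TRUE)
  dX <- x - X0
  Wm <- model$W * model$mask
  dZ1_const <- dX %*% Wm            # dh/dalpha before the relu gate
  lc <- matrix(0, B, model$config$n_hidden)
  for (a in ig_alphas(steps)) {
    fw <- attr_forward(model, X0 + a * dX, obs_idx)
    dh <- dF_dh_batch(model, fw, target$task, class_idx)
    if (!all(is.finite(dh))) stop("non-finite gradient along the path")
    lc <- lc + dh * (fw$z1 > 0) * dZ1_const / steps
  }
  colnames(lc) <- model$config$node_names
  fx <- target_value(model, attr_forward(model, x, obs_idx),
                     target$task, class_idx)
  f0 <- target_value(model, attr_forward(model, X0, obs_idx),
                     target$task, class_idx)
  structure(lc, completeness_gap = abs(rowSums(lc) - (fx - f0)))
}

as_model_list <- function(models) {
  if (inherits(models, "kp_model") || inherits(models, "kp_fit"))
    models <- list(models)
  lapply(models, function(m) if (inherits(m, "kp_fit")) m$model else m)
}

#' Impact of the metadata blocks on disease prediction
#'
#' Integrated-gradients attribution of each disease class's probability with
#' respect to the fused metadata vector actually consumed by the disease
#' decoder (the trunk output is held at its per-sample value; the baseline
#' is the fused vector the model produces for a zero-abundance,
#' all-metadata-missing input).  Attributions are converted to importances
#' by absolute value, summed within each metadata block, averaged over
#' samples, then over disease classes for the overall score, then over
#' restarts.
#'
#' @param models A `kp_model`/`kp_fit` or list of them (independently
#'   trained restarts).
#' @param dataset A `kp_dataset`; its observed metadata are fused as during
#'   prediction.
#' @param steps Path steps for the integral (default 50).
#' @return Matrix with one row per disease class plus `"overall"`, one
#'   column per metadata block; per-restart raw scores in attribute
#'   `"per_restart"`.
#' @export
metadata_impact <- function(models, dataset, steps = 50) {
  models <- as_model_list(models)
  cfg <- models[[1L]]$config
  if (!cfg$use_metadata) stop("abundance-only models carry no metadata blocks")
  D <- length(cfg$vocab$disease)
  widths <- vapply(KP_META_TASKS, task_width, integer(1), config = cfg)
  block <- rep(KP_META_TASKS, widths)
  X <- model_matrix(dataset)
  out <- array(0, c(D + 1L, 4L, length(models)),
               dimnames = list(c(cfg$vocab$disease, "overall"),
                               KP_META_TASKS, NULL))
  for (r in seq_along(models)) {
    model <- models[[r]]
    fw <- attr_forward(model, X, meta_indices(dataset$meta, cfg))
    Fx <- do.call(cbind, fw$fused[KP_META_TASKS])
    fw0 <- attr_forward(model, matrix(0, 1L, cfg$n_species), NULL)
    F0 <- matrix(do.call(cbind, fw0$fused[KP_META_TASKS]),
                 nrow(X), sum(widths), byrow = TRUE)
    dF <- Fx - F0
    Vf <- model$V[cfg$n_hidden + seq_len(sum(widths)), , drop = FALSE]
    Vh <- model$V[seq_len(cfg$n_hidden), , drop = FALSE]
    zh <- fw$h %*% Vh + rep(model$cbias, each = nrow(X))  # fixed trunk part
    for (d in seq_len(D)) {
      grad_sum <- matrix(0, nrow(X), sum(widths))
      for (a in ig_alphas(steps)) {
        P <- softmax_rows(zh + (F0 + a * dF) %*% Vf)
        dZd <- P[, d] * (-P)
        dZd[, d] <- dZd[, d] + P[, d]
        grad_sum <- grad_sum + dZd %*% t(Vf)
      }
      ig <- dF * grad_sum / steps
      imp <- abs(ig)
      out[d, , r] <- vapply(KP_META_TASKS, function(t)
        mean(rowSums(imp[, block == t, drop = FALSE])), numeric(1))
    }
    out[D + 1L, , r] <- colMeans(out[seq_len(D), , r, drop = FALSE][, , 1L])
  }
  res <- apply(out, c(1L, 2L), mean)
  structure(res, per_restart = out)
}

#' Hidden-node importance for a metadata task
#'
#' Layer-conductance importances of the knowledge-primed hidden nodes for
#' one metadata prediction task: per node, the absolute conductance is
#' averaged over samples, then over the task's classes, then over restarts.
#'
#' @param models A `kp_model`/`kp_fit` or list of independently trained
#'   restarts.
#' @param dataset A `kp_dataset` supplying the evaluation samples.
#' @param task One of `"age"`, `"gender"`, `"bmi"`, `"body_site"` (or
#'   `"disease"`).
#' @param steps Path steps (default 50).
#' @param top_k Optionally return only the `top_k` highest-scoring nodes.
#' @return Data frame with columns `node`, `group`, `score`, sorted by
#'   decreasing importance; per-restart node scores in attribute
#'   `"per_restart"`.
#' @export
node_importance_for_metadata <- function(models, dataset, task, steps = 50,
                                         top_k = NULL) {
  models <- as_model_list(models)
  cfg <- models[[1L]]$config
  n_classes <- if (task == "disease") length(cfg$vocab$disease)
               else length(cfg$vocab[[task]])
  X <- model_matrix(dataset)
  per_restart <- matrix(0, cfg$n_hidden, length(models),
                        dimnames = list(cfg$node_names, NULL))
  for (r in seq_along(models)) {
    model <- models[[r]]
    class_scores <- matrix(0, cfg$n_hidden, n_classes)
    for (cl in seq_len(n_classes)) {
      lc <- layer_conductance(model, X, target = list(task = task, class = cl),
                              steps = steps)
      class_scores[, cl] <- colMeans(abs(lc))
    }
    per_restart[, r] <- rowMeans(class_scores)
  }
  score <- rowMeans(per_restart)
  out <- data.frame(node = cfg$node_names, group = cfg$node_groups,
                    score = score, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  structure(out, per_restart = per_restart)
}
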