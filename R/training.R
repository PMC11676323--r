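## Training: the sample-count-weighted multitask loss, analytic gradients,
## AdamW optimisation with early stopping, and cross-validation
## orchestration.

#' Training hyperparameters
#'
#' @param learning_rate AdamW learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 16).
#' @param max_epochs Maximum number of epochs (default 200).
#' @param patience Early-stopping patience in epochs without validation-loss
#'   improvement (default 10).
#' @param val_fraction Fraction of the training split held out (stratified by
#'   phenotype) for early stopping (default 0.1; 0 monitors training loss).
#' @param monitor Validation quantity for early stopping: `"disease"`
#'   (default) tracks the primary task's cross-entropy; `"total"` tracks the
#'   full weighted multitask loss.  With heavily weighted rare metadata
#'   tasks (weights `n / n_task`), the total loss on a small holdout is
#'   dominated by a handful of rare-task samples and can rise while the
#'   disease task still improves, so the primary-task monitor is the default.
#' @param weight_decay Decoupled weight decay (default 0.01).
#' @param beta1,beta2,eps AdamW moment parameters.
#' @param seed Integer seed controlling initialisation, the validation split
#'   and batch shuffling; same seed, same run.
#' @param verbose Print per-epoch losses.
#' @return A list of class `kp_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16,
                         max_epochs = 200, patience = 10,
                         val_fraction = 0.1,
                         monitor = c("disease", "total"),
                         weight_decay = 0.01,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = NULL, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 0,
            patience >= 1, val_fraction >= 0, val_fraction < 1,
            weight_decay >= 0)
  monitor <- match.arg(monitor)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 val_fraction = val_fraction, monitor = monitor,
                 weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = seed, verbose = verbose),
            class = "kp_train_config")
}

#' Per-task loss weights from metadata availability
#'
#' Each metadata task is weighted by `n / n_task`, the ratio of the total
#' training-sample count to the number of training samples with that
#' metadata observed, so tasks with scarce labels are not drowned out.
#' Tasks with no observed labels are excluded (weight `NA`) with a warning.
#'
#' @param meta Training-split metadata data frame.
#' @return Named numeric vector of weights for `age`, `gender`, `bmi`,
#'   `body_site`, with the total count `n` as attribute `"n"`.
#' @export
compute_task_weights <- function(meta) {
  n <- nrow(meta)
  if (n < 1) stop("need at least one training sample")
  cols <- c(age = "age_class", gender = "gender", bmi = "bmi_class",
            body_site = "body_site")
  n_task <- vapply(cols, function(col) sum(!is.na(meta[[col]])), numeric(1))
  names(n_task) <- names(cols)
  w <- ifelse(n_task > 0, n / n_task, NA_real_)
  if (anyNA(w))
    warning("task(s) with no observed labels dropped from the loss: ",
            paste(names(w)[is.na(w)], collapse = ", "))
  structure(w, n = n, n_task = n_task)
}

## Stable cross-entropy of one-hot targets given a logit matrix:
## CE_i = logsumexp(z_i) - z_i[y_i].
ce_from_logits <- function(z, y_idx) {
  m <- apply(z, 1L, max)
  lse <- m + log(rowSums(exp(z - m)))
  lse - z[cbind(seq_along(y_idx), y_idx)]
}

## Stable binary cross-entropy given the logit: max(z,0) - z*y + log1p(exp(-|z|)).
bce_from_logits <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

#' Weighted multitask loss
#'
#' The training objective: the sum over samples of the disease
#' cross-entropy, plus, for each metadata task, `w_task` times the sum of
#' that task's cross-entropy (binary cross-entropy for gender) over the
#' samples whose metadata value is observed.  Missing metadata contribute
#' nothing to their task's term.
#'
#' @param bundle A `kp_predictions` from [model_forward()].
#' @param labels Metadata data frame with `phenotype` plus the metadata
#'   columns (`NA` = missing), aligned with the bundle.
#' @param weights Task weights from [compute_task_weights()].
#' @return The scalar loss, with the per-task breakdown attached as
#'   attribute `"terms"`.
#' @export
multitask_loss <- function(bundle, labels, weights) {
  cfg_vocab <- list(age = KP_AGE_LEVELS, gender = KP_GENDER_LEVELS,
                    bmi = KP_BMI_LEVELS)
  p_dis <- clamp_prob(bundle$disease_probs)
  y_dis <- match(as.character(labels$phenotype), colnames(bundle$disease_probs))
  if (anyNA(y_dis)) stop("phenotype label outside the model's vocabulary")
  terms <- c(disease = -sum(log(p_dis[cbind(seq_along(y_dis), y_dis)])))
  if (!is.null(bundle$meta_probs)) {
    cols <- c(age = "age_class", gender = "gender", bmi = "bmi_class",
              body_site = "body_site")
    for (task in KP_META_TASKS) {
      w <- weights[[task]]
      lab <- labels[[cols[[task]]]]
      obs <- which(!is.na(lab))
      if (is.na(w) || length(obs) == 0L) { terms[[task]] <- 0; next }
      p <- bundle$meta_probs[[task]]
      if (task == "gender") {
        y <- as.numeric(as.character(lab[obs]) == "male")
        pg <- clamp_prob(p[obs, 1L])
        terms[[task]] <- -w * sum(y * log(pg) + (1 - y) * log(1 - pg))
      } else {
        vocab <- cfg_vocab[[task]] %||% colnames(p)
        if (task == "body_site") vocab <- colnames(p) %||% levels(lab)
        y <- match(as.character(lab[obs]), vocab)
        pc <- clamp_prob(p[obs, , drop = FALSE])
        terms[[task]] <- -w * sum(log(pc[cbind(seq_along(obs), y)]))
      }
    }
  }
  structure(sum(terms), terms = terms)
}

## ---------------------------------------------------------------------------
## Internal: forward + analytic gradients of the multitask loss.

flatten_params <- function(model) {
  p <- list(W = model$W, b1 = model$b1, V = model$V, cbias = model$cbias)
  if (model$config$use_metadata) {
    for (t in KP_META_TASKS) {
      p[[paste0("A_", t)]] <- model$A[[t]]
      p[[paste0("a_", t)]] <- model$a[[t]]
    }
  }
  p
}

unflatten_params <- function(model, p) {
  model$W <- p$W; model$b1 <- p$b1; model$V <- p$V; model$cbias <- p$cbias
  if (model$config$use_metadata) {
    for (t in KP_META_TASKS) {
      model$A[[t]] <- p[[paste0("A_", t)]]
      model$a[[t]] <- p[[paste0("a_", t)]]
    }
  }
  model
}

## Loss and gradients on one batch.  x: B x S model-scale abundances;
## y_dis: integer disease labels; meta_idx: per-task integer labels with NA.
## Returns list(loss, grads) with grads named like flatten_params().
loss_and_grads <- function(model, x, y_dis, meta_idx, weights,
                           want_grads = TRUE) {
  cfg <- model$config
  B <- nrow(x)
  Wm <- model$W * model$mask
  Z1 <- x %*% Wm + rep(model$b1, each = B)
  H <- pmax(Z1, 0)

  Zt <- Pt <- Ft <- obs <- list()
  if (cfg$use_metadata) {
    for (t in KP_META_TASKS) {
      Zt[[t]] <- H %*% model$A[[t]] + rep(model$a[[t]], each = B)
      Pt[[t]] <- if (t == "gender") sigmoid(Zt[[t]]) else softmax_rows(Zt[[t]])
    }
    fusion <- fuse_metadata(Pt, meta_idx, cfg)
    Ft <- fusion$fused
    obs <- fusion$observed
    U <- cbind(H, do.call(cbind, Ft[KP_META_TASKS]))
  } else {
    U <- H
  }
  Zd <- U %*% model$V + rep(model$cbias, each = B)
  Pd <- softmax_rows(Zd)

  loss <- sum(ce_from_logits(Zd, y_dis))
  if (cfg$use_metadata) {
    for (t in KP_META_TASKS) {
      w <- weights[[t]]
      o <- which(obs[[t]])
      if (is.na(w) || length(o) == 0L) next
      loss <- loss + if (t == "gender") {
        w * sum(bce_from_logits(Zt[[t]][o, 1L],
                                as.numeric(meta_idx[[t]][o] == 2L)))
      } else {
        w * sum(ce_from_logits(Zt[[t]][o, , drop = FALSE], meta_idx[[t]][o]))
      }
    }
  }
  if (!want_grads) return(list(loss = loss))

  D <- ncol(Pd)
  dZd <- Pd - one_hot(y_dis, D)
  g <- list(V = crossprod(U, dZd), cbias = colSums(dZd))
  dU <- dZd %*% t(model$V)
  Hn <- cfg$n_hidden
  dH <- dU[, seq_len(Hn), drop = FALSE]

  if (cfg$use_metadata) {
    offset <- Hn
    soft_fusion <- cfg$fusion == "probabilities" && cfg$grad_through_predicted
    for (t in KP_META_TASKS) {
      k <- task_width(cfg, t)
      dF <- dU[, offset + seq_len(k), drop = FALSE]
      offset <- offset + k
      dZ <- matrix(0, B, k)
      o <- which(obs[[t]]); mi <- which(!obs[[t]])
      w <- weights[[t]]
      if (!is.na(w) && length(o) > 0L) {
        if (t == "gender") {
          y <- as.numeric(meta_idx[[t]][o] == 2L)
          dZ[o, 1L] <- w * (Pt[[t]][o, 1L] - y)
        } else {
          dZ[o, ] <- w * (Pt[[t]][o, , drop = FALSE] -
                            one_hot(meta_idx[[t]][o], k))
        }
      }
      if (soft_fusion && length(mi) > 0L) {
        if (t == "gender") {
          pg <- Pt[[t]][mi, 1L]
          dZ[mi, 1L] <- dZ[mi, 1L] + dF[mi, 1L] * pg * (1 - pg)
        } else {
          P <- Pt[[t]][mi, , drop = FALSE]
          r <- dF[mi, , drop = FALSE]
          dZ[mi, ] <- dZ[mi, , drop = FALSE] + P * (r - rowSums(r * P))
        }
      }
      g[[paste0("A_", t)]] <- crossprod(H, dZ)
      g[[paste0("a_", t)]] <- colSums(dZ)
      dH <- dH + dZ %*% t(model$A[[t]])
    }
  }
  dZ1 <- dH * (Z1 > 0)
  g$W <- crossprod(x, dZ1) * model$mask
  g$b1 <- colSums(dZ1)
  list(loss = loss, grads = g)
}

## One AdamW step over a flat parameter list.
adamw_step <- function(par, grads, state, control) {
  state$t <- state$t + 1L
  b1 <- control$beta1; b2 <- control$beta2
  lr <- control$learning_rate
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gmat
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gmat^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + control$eps) -
      lr * control$weight_decay * par[[nm]]
  }
  list(par = par, state = state)
}

## Stratified holdout of a fraction of indices (>=1 per class when the
## fraction is positive and the class has >=2 samples).
holdout_split <- function(phenotype, fraction) {
  if (fraction <= 0) return(integer())
  val <- integer()
  for (cl in unique(as.character(phenotype))) {
    idx <- which(as.character(phenotype) == cl)
    n_val <- floor(fraction * length(idx))
    if (n_val >= 1L)
      val <- c(val, idx[sample.int(length(idx), n_val)])
  }
  sort(val)
}

#' Train a model
#'
#' Fits the multitask network with AdamW and early stopping: a stratified
#' slice of the training data is held out, the total multitask loss on it is
#' monitored after every epoch, and the best-scoring weights are returned
#' when no improvement is seen for `patience` epochs.  Task weights are
#' computed once, from the optimisation split.  The mask is re-applied after
#' every update, so masked trunk positions stay exactly zero.
#'
#' @param dataset A `kp_dataset` of training samples.
#' @param schema A `kp_schema` (the mask is built from it), or a precomputed
#'   mask matrix if `config` is supplied.
#' @param config Optional `kp_config`; by default one is built from the
#'   schema and the dataset's phenotype/body-site levels.
#' @param control A `kp_train_config`.
#' @return A list of class `kp_fit`: `model` (the best `kp_model`), `log`
#'   (per-epoch train/validation losses), `weights` (task weights) and
#'   `best_epoch`.
#' @export
train_model <- function(dataset, schema, config = NULL,
                        control = train_config()) {
  if (inherits(schema, "kp_schema")) {
    mask <- build_mask(schema, dataset$species)
    if (is.null(config))
      config <- model_config(dataset$species, schema,
                             disease_levels = levels(dataset$meta$phenotype),
                             body_site_levels = levels(dataset$meta$body_site))
  } else {
    mask <- schema
    if (is.null(config))
      stop("when passing a raw mask, 'config' must be supplied")
  }

  with_seed(control$seed, {
    model <- init_model(config, mask)
    n <- nrow(dataset$abundance)
    val_idx <- holdout_split(dataset$meta$phenotype, control$val_fraction)
    opt_idx <- setdiff(seq_len(n), val_idx)
    weights <- suppressWarnings(
      compute_task_weights(dataset$meta[opt_idx, , drop = FALSE]))

    x_all <- model_matrix(dataset)
    meta_all <- meta_indices(dataset$meta, config)
    y_all <- match(as.character(dataset$meta$phenotype), config$vocab$disease)

    par <- flatten_params(model)
    opt_state <- list(t = 0L,
                      m = lapply(par, function(p) p * 0),
                      v = lapply(par, function(p) p * 0))

    no_meta <- structure(rep(NA_real_, 4L), names = KP_META_TASKS)
    eval_loss <- function(par, idx, w = weights) {
      m <- unflatten_params(model, par)
      loss_and_grads(m, x_all[idx, , drop = FALSE], y_all[idx],
                     lapply(meta_all, `[`, idx), w,
                     want_grads = FALSE)$loss
    }

    log_rows <- list()
    best_par <- par
    best_loss <- Inf
    best_epoch <- 0L
    stale <- 0L
    monitor_idx <- if (length(val_idx) > 0L) val_idx else opt_idx

    if (control$max_epochs > 0L) {
      for (epoch in seq_len(control$max_epochs)) {
        perm <- opt_idx[sample.int(length(opt_idx))]
        starts <- seq(1L, length(perm), by = control$batch_size)
        train_loss <- 0
        for (s in starts) {
          b <- perm[s:min(s + control$batch_size - 1L, length(perm))]
          m <- unflatten_params(model, par)
          lg <- loss_and_grads(m, x_all[b, , drop = FALSE], y_all[b],
                               lapply(meta_all, `[`, b), weights)
          if (!is.finite(lg$loss))
            stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate", epoch))
          train_loss <- train_loss + lg$loss
          upd <- adamw_step(par, lg$grads, opt_state, control)
          par <- upd$par
          opt_state <- upd$state
          par$W <- par$W * model$mask
        }
        val_loss <- eval_loss(par, monitor_idx)
        val_disease <- suppressWarnings(eval_loss(par, monitor_idx, no_meta))
        log_rows[[epoch]] <- data.frame(epoch = epoch,
                                        train_loss = train_loss,
                                        val_loss = val_loss,
                                        val_disease = val_disease)
        if (control$verbose)
          message(sprintf("epoch %3d  train %.4f  val %.4f  val(dis) %.4f",
                          epoch, train_loss, val_loss, val_disease))
        if (control$monitor == "disease") val_loss <- val_disease
        if (is.finite(val_loss) && val_loss < best_loss) {
          best_loss <- val_loss
          best_par <- par
          best_epoch <- epoch
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= control$patience) break
        }
      }
    }
    model <- unflatten_params(model, best_par)
    model$W <- model$W * model$mask
    structure(list(model = model,
                   log = if (length(log_rows)) do.call(rbind, log_rows)
                         else data.frame(epoch = integer(),
                                         train_loss = numeric(),
                                         val_loss = numeric(),
                                         val_disease = numeric()),
                   weights = weights, best_epoch = best_epoch),
              class = "kp_fit")
  })
}

#' @export
print.kp_fit <- function(x, ...) {
  cat(sprintf("kp_fit: %d epochs run, best validation loss %.4f at epoch %d\n",
              nrow(x$log),
              if (nrow(x$log)) min(x$log$val_loss) else NA_real_,
              x$best_epoch))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into `k` phenotype-stratified folds, trains a model on
#' each training portion (fold seeds derived as `seed + fold`), evaluates on
#' the held-out fold with observed test metadata fused in, and aggregates
#' the per-task metrics.
#'
#' @param dataset A `kp_dataset`.
#' @param schema A `kp_schema`.
#' @param k Number of folds (default 5).
#' @param seed Base integer seed.
#' @param config Optional `kp_config` (defaults as in [train_model()]).
#' @param control A `kp_train_config` (its `seed` is overridden per fold).
#' @return A list of class `kp_cv`: `per_fold` (fold x task metric rows),
#'   `summary` (mean and sd per task and metric), `folds`, the fitted
#'   models, and `oof` (out-of-fold phenotype predictions per sample, with
#'   the disease probability matrix as attribute `"disease_probs"`).
#' @export
cross_validate <- function(dataset, schema, k = 5, seed = 0, config = NULL,
                           control = train_config()) {
  if (k < 2) stop("k must be at least 2")
  if (is.null(config))
    config <- model_config(dataset$species, schema,
                           disease_levels = levels(dataset$meta$phenotype),
                           body_site_levels = levels(dataset$meta$body_site))
  folds <- stratified_folds(dataset$meta$phenotype, k = k, seed = seed)
  per_fold <- list()
  fits <- list()
  oof <- list()
  oof_probs <- list()
  for (f in seq_len(k)) {
    train_ds <- subset_dataset(dataset, which(folds != f))
    test_ds <- subset_dataset(dataset, which(folds == f))
    ctl <- control
    ctl$seed <- (seed %||% 0) + f
    fit <- train_model(train_ds, schema, config = config, control = ctl)
    bundle <- model_forward(fit$model, model_matrix(test_ds),
                            observed = test_ds$meta)
    res <- evaluate_bundle(bundle, test_ds$meta, config)
    res$fold <- f
    per_fold[[f]] <- res
    fits[[f]] <- fit
    oof[[f]] <- data.frame(
      sample_id = test_ds$meta$sample_id, fold = f,
      phenotype_true = as.character(test_ds$meta$phenotype),
      phenotype_pred = predict_labels(bundle, config)$phenotype,
      stringsAsFactors = FALSE)
    oof_probs[[f]] <- bundle$disease_probs
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("acc", "f1", "auc", "auprc")
  summary <- do.call(rbind, lapply(split(per_fold, per_fold$task), function(d)
    data.frame(task = d$task[1L],
               metric = metric_cols,
               mean = vapply(metric_cols, function(mc) mean(d[[mc]]), numeric(1)),
               sd = vapply(metric_cols, function(mc) stats::sd(d[[mc]]), numeric(1)),
               row.names = NULL)))
  rownames(summary) <- NULL
  oof <- do.call(rbind, oof)
  attr(oof, "disease_probs") <- do.call(rbind, oof_probs)
  structure(list(per_fold = per_fold, summary = summary, folds = folds,
                 fits = fits, oof = oof), class = "kp_cv")
}

#' @export
print.kp_cv <- function(x, ...) {
  cat("cross-validation summary (mean over folds):\n")
  print(x$summary, digits = 3)
  invisible(x)
}
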