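## The multitask knowledge-primed network: a masked linear trunk over
## species abundances, one decoder per metadata task (age, gender, BMI,
## body site), fusion of observed/predicted metadata, and a multiclass
## disease decoder consuming the trunk output plus the fused metadata.

KP_META_TASKS <- c("age", "gender", "bmi", "body_site")

#' Model configuration
#'
#' Collects the architectural choices of the network.  Age (6 classes), BMI
#' (4 classes) and gender (single sigmoid unit) are fixed by the metadata
#' vocabulary; body-site and disease class sets are supplied by the caller
#' (normally taken from the dataset's factor levels).
#'
#' @param species Character vector of input species ids (input-layer order).
#' @param schema `kp_schema` describing the hidden layer (see
#'   [build_hidden_schema()]).
#' @param disease_levels Character vector of phenotype class labels (>= 2).
#' @param body_site_levels Character vector of body-site labels (>= 2).
#' @param fusion `"probabilities"` (default) fuses the decoder's probability
#'   vector for missing metadata; `"hard_one_hot"` fuses the one-hot of its
#'   argmax instead.
#' @param grad_through_predicted Should the disease loss backpropagate
#'   through predicted (fused) metadata into the metadata decoders and the
#'   trunk?  Default `TRUE`; observed metadata are always constants.
#' @param use_metadata If `FALSE`, build an abundance-only model: no metadata
#'   decoders, the disease decoder sees only the trunk output.
#' @return An object of class `kp_config`.
#' @export
model_config <- function(species, schema, disease_levels, body_site_levels,
                         fusion = c("probabilities", "hard_one_hot"),
                         grad_through_predicted = TRUE,
                         use_metadata = TRUE) {
  fusion <- match.arg(fusion)
  if (length(disease_levels) < 2L) stop("need at least 2 disease classes")
  if (use_metadata && length(body_site_levels) < 2L)
    stop("need at least 2 body-site classes")
  node_names <- vapply(schema, `[[`, character(1), "name")
  structure(list(
    species = as.character(species),
    n_species = length(species),
    n_hidden = length(schema),
    node_names = node_names,
    node_groups = vapply(schema, `[[`, character(1), "group"),
    vocab = list(age = KP_AGE_LEVELS, gender = KP_GENDER_LEVELS,
                 bmi = KP_BMI_LEVELS,
                 body_site = as.character(body_site_levels),
                 disease = as.character(disease_levels)),
    fusion = fusion,
    grad_through_predicted = isTRUE(grad_through_predicted),
    use_metadata = isTRUE(use_metadata)), class = "kp_config")
}

## Number of output units per task.
task_width <- function(config, task) {
  if (task == "gender") 1L else length(config$vocab[[task]])
}

## Width of the fused-metadata block consumed by the disease decoder.
fused_width <- function(config) {
  if (!config$use_metadata) return(0L)
  sum(vapply(KP_META_TASKS, task_width, integer(1), config = config))
}

#' Initialise model weights
#'
#' Draws He-scaled random weights for the trunk (then applies the mask, so
#' masked positions start exactly zero) and Glorot-scaled weights for the
#' decoders; biases start at zero.
#'
#' @param config A `kp_config`.
#' @param mask Binary mask from [build_mask()], dimension
#'   `n_species x n_hidden`.
#' @param seed Optional integer seed.
#' @return An object of class `kp_model` holding all weights, the frozen
#'   mask, and the configuration.
#' @export
init_model <- function(config, mask, seed = NULL) {
  stopifnot(inherits(config, "kp_config"))
  if (!all(dim(mask) == c(config$n_species, config$n_hidden)))
    stop("mask dimensions do not match the configuration")
  S <- config$n_species; H <- config$n_hidden
  with_seed(seed, {
    fan_in <- pmax(colSums(mask), 1)
    W <- matrix(stats::rnorm(S * H), S, H) *
      rep(sqrt(2 / fan_in), each = S) * mask
    dec <- function(n_out) matrix(stats::rnorm(H * n_out, sd = sqrt(1 / H)),
                                  H, n_out)
    A <- a <- NULL
    if (config$use_metadata) {
      A <- lapply(stats::setNames(KP_META_TASKS, KP_META_TASKS),
                  function(t) dec(task_width(config, t)))
      a <- lapply(A, function(m) numeric(ncol(m)))
    }
    Dw <- H + fused_width(config)
    D <- length(config$vocab$disease)
    V <- matrix(stats::rnorm(Dw * D, sd = sqrt(1 / Dw)), Dw, D)
    structure(list(W = W, b1 = numeric(H), A = A, a = a,
                   V = V, cbias = numeric(D),
                   mask = mask, config = config),
              class = "kp_model")
  })
}

#' @export
print.kp_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("kp_model: %d species -> %d hidden nodes -> %d phenotype classes\n",
              cfg$n_species, cfg$n_hidden, length(cfg$vocab$disease)))
  cat(sprintf("metadata decoders: %s; fusion: %s\n",
              if (cfg$use_metadata) paste(KP_META_TASKS, collapse = ", ")
              else "none", cfg$fusion))
  cat(sprintf("mask density: %.3f\n", mean(x$mask)))
  invisible(x)
}

#' Masked linear trunk
#'
#' Computes the hidden activations `h = relu((W * M)' x + b)`: a fully
#' connected layer whose weights are multiplied elementwise by the frozen
#' binary mask, so species connect only to the hidden nodes their prior
#' knowledge supports.
#'
#' @param x Numeric matrix (samples x species) or a single abundance vector.
#' @param model A `kp_model`.
#' @return Matrix of hidden activations (samples x hidden nodes).
#' @export
masked_linear <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$config$n_species)
    stop(sprintf("input has %d species, model expects %d",
                 ncol(x), model$config$n_species))
  z <- x %*% (model$W * model$mask) + rep(model$b1, each = nrow(x))
  pmax(z, 0)
}

## Pre-activation of the trunk (needed for gradients).
masked_linear_pre <- function(x, model) {
  x %*% (model$W * model$mask) + rep(model$b1, each = nrow(x))
}

#' Metadata decoder output
#'
#' A single affine map from the hidden activations to the task's logits,
#' followed by a softmax (age, BMI, body site) or a sigmoid (gender's single
#' output unit).
#'
#' @param h Hidden activation matrix from [masked_linear()].
#' @param model A `kp_model` with metadata decoders.
#' @param task One of `"age"`, `"gender"`, `"bmi"`, `"body_site"`.
#' @return Probability matrix (samples x classes); for gender a one-column
#'   matrix of P(male).
#' @export
decode_metadata <- function(h, model, task) {
  if (!task %in% KP_META_TASKS) stop("unknown task: ", task)
  if (!model$config$use_metadata) stop("model was built without metadata decoders")
  z <- h %*% model$A[[task]] + rep(model$a[[task]], each = nrow(h))
  if (task == "gender") sigmoid(z) else softmax_rows(z)
}

## Encode a metadata data frame into per-task integer indices (NA = missing).
meta_indices <- function(meta, config) {
  if (is.null(meta)) return(NULL)
  v <- config$vocab
  cols <- c(age = "age_class", gender = "gender", bmi = "bmi_class",
            body_site = "body_site")
  out <- lapply(KP_META_TASKS, function(task) {
    col <- meta[[cols[[task]]]]
    if (is.null(col)) return(rep(NA_integer_, nrow(meta)))
    idx <- match(as.character(col), v[[task]])
    bad <- !is.na(col) & is.na(idx)
    if (any(bad))
      stop(sprintf("invalid %s label(s): %s", task,
                   paste(unique(as.character(col)[bad]), collapse = ", ")))
    idx
  })
  names(out) <- KP_META_TASKS
  out
}

#' Fuse observed and predicted metadata
#'
#' For each task and sample: if the metadata value is observed, the fused
#' representation is its exact one-hot (gender: a 0/1 scalar) and is treated
#' as a constant during training; otherwise it is the decoder's predicted
#' probability vector (or, under `fusion = "hard_one_hot"`, the one-hot of
#' the predicted class).  Fusion is per-sample: one sample's observedness
#' never affects another's fused values.
#'
#' @param predicted Named list of per-task probability matrices from
#'   [decode_metadata()].
#' @param observed Named list of per-task integer label indices with `NA`
#'   for missing (see `meta_indices`), or `NULL` for all-missing.
#' @param config A `kp_config`.
#' @return A list with per-task fused matrices and a parallel list of
#'   logical observedness vectors.
#' @export
fuse_metadata <- function(predicted, observed, config) {
  fused <- list(); obs <- list()
  n <- nrow(predicted[[1L]])
  for (task in KP_META_TASKS) {
    p <- predicted[[task]]
    o <- if (is.null(observed)) rep(NA_integer_, n) else observed[[task]]
    if (length(o) != n) stop("observed labels length mismatch for task ", task)
    k <- task_width(config, task)
    if (any(!is.na(o) & (o < 1 | o > length(config$vocab[[task]]))))
      stop("invalid label index for task ", task)
    f <- p
    if (config$fusion == "hard_one_hot") {
      f <- if (task == "gender") matrix(as.numeric(p > 0.5), ncol = 1L)
           else one_hot(max.col(p, ties.method = "first"), k)
    }
    is_obs <- !is.na(o)
    if (any(is_obs)) {
      if (task == "gender") f[is_obs, 1L] <- as.numeric(o[is_obs] == 2L)
      else f[is_obs, ] <- one_hot(o[is_obs], k)
    }
    fused[[task]] <- f
    obs[[task]] <- is_obs
  }
  list(fused = fused, observed = obs)
}

#' Disease decoder
#'
#' A single affine map plus softmax over the concatenation of the trunk
#' output and the fused metadata blocks in fixed task order (age, gender,
#' BMI, body site).
#'
#' @param h Hidden activation matrix.
#' @param fused Fusion result from [fuse_metadata()] (or `NULL` for an
#'   abundance-only model).
#' @param model A `kp_model`.
#' @return Probability matrix (samples x disease classes).
#' @export
decode_disease <- function(h, fused, model) {
  u <- if (model$config$use_metadata)
    cbind(h, do.call(cbind, fused$fused[KP_META_TASKS])) else h
  softmax_rows(u %*% model$V + rep(model$cbias, each = nrow(u)))
}

#' Full forward pass
#'
#' Composes [masked_linear()], the four metadata decoders, [fuse_metadata()]
#' and [decode_disease()].
#'
#' @param model A `kp_model`.
#' @param x Abundance matrix (samples x species), already on the model input
#'   scale (see [microbiome_dataset()]).
#' @param observed Optional metadata data frame (columns `age_class`,
#'   `gender`, `bmi_class`, `body_site`, `NA` = missing) aligned with the
#'   rows of `x`, or `NULL` for all-missing.
#' @return An object of class `kp_predictions`: hidden activations `h`,
#'   per-task probabilities `meta_probs`, fused metadata `fused`,
#'   observedness flags, and `disease_probs`.
#' @export
model_forward <- function(model, x, observed = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  h <- masked_linear(x, model)
  cfg <- model$config
  meta_probs <- fused <- obs <- NULL
  if (cfg$use_metadata) {
    meta_probs <- lapply(stats::setNames(KP_META_TASKS, KP_META_TASKS),
                         function(t) decode_metadata(h, model, t))
    for (t in KP_META_TASKS)
      colnames(meta_probs[[t]]) <- if (t == "gender") "male" else cfg$vocab[[t]]
    oidx <- if (is.data.frame(observed)) meta_indices(observed, cfg) else observed
    fusion <- fuse_metadata(meta_probs, oidx, cfg)
    fused <- fusion$fused
    obs <- fusion$observed
  }
  disease_probs <- decode_disease(h, list(fused = fused), model)
  colnames(disease_probs) <- cfg$vocab$disease
  structure(list(h = h, meta_probs = meta_probs, fused = fused,
                 observed = obs, disease_probs = disease_probs),
            class = "kp_predictions")
}

#' Hard labels from a prediction bundle
#'
#' Argmax per categorical task (ties broken toward the lowest class index);
#' gender thresholded at 0.5 with ties going to the first class (female).
#'
#' @param bundle A `kp_predictions` from [model_forward()].
#' @param config The model's `kp_config`.
#' @return A data frame of predicted labels, one column per task.
#' @export
predict_labels <- function(bundle, config) {
  v <- config$vocab
  out <- data.frame(
    phenotype = v$disease[max.col(bundle$disease_probs, ties.method = "first")])
  if (config$use_metadata) {
    out$age_class <- v$age[max.col(bundle$meta_probs$age, ties.method = "first")]
    out$gender <- v$gender[1L + as.integer(bundle$meta_probs$gender[, 1L] > 0.5)]
    out$bmi_class <- v$bmi[max.col(bundle$meta_probs$bmi, ties.method = "first")]
    out$body_site <- v$body_site[max.col(bundle$meta_probs$body_site,
                                         ties.method = "first")]
  }
  out
}

#' Predict phenotype and metadata for new samples
#'
#' @param object A trained `kp_model`.
#' @param abundance Abundance matrix on the percent scale (samples x
#'   species, columns matching the model's species).
#' @param metadata Optional metadata data frame; observed values are fused
#'   into the disease decoder, missing ones are predicted.
#' @param renormalize Renormalise abundance rows to sum to 1 (default TRUE,
#'   matching training).
#' @param ... Unused.
#' @return A data frame of per-sample predicted labels with the disease
#'   probability matrix attached as attribute `"disease_probs"` and the full
#'   bundle as `"bundle"`.
#' @export
predict.kp_model <- function(object, abundance, metadata = NULL,
                             renormalize = TRUE, ...) {
  if (!identical(colnames(abundance), object$config$species)) {
    if (!setequal(colnames(abundance), object$config$species))
      stop("abundance species do not match the model's species")
    abundance <- abundance[, object$config$species, drop = FALSE]
  }
  x <- abundance
  if (renormalize) {
    s <- rowSums(x); s[s == 0] <- 1
    x <- x / s
  }
  bundle <- model_forward(object, x, observed = metadata)
  labels <- predict_labels(bundle, object$config)
  labels <- cbind(sample_id = rownames(abundance) %||%
                    seq_len(nrow(abundance)), labels)
  attr(labels, "disease_probs") <- bundle$disease_probs
  attr(labels, "bundle") <- bundle
  labels
}
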