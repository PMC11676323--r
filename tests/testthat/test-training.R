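test_that("task weights are n over n_task, computed from the supplied split", {
  meta <- data.frame(
    age_class = c(rep("infant", 50), rep(NA, 50)),
    gender = rep("male", 100),
    bmi_class = rep(NA_character_, 100),
    body_site = rep("gut", 100))
  w <- suppressWarnings(compute_task_weights(meta))
  expect_equal(unname(w[["age"]]), 2.0)
  expect_equal(unname(w[["gender"]]), 1.0)
  expect_true(is.na(w[["bmi"]]))
  expect_equal(attr(w, "n"), 100L)

  # the ratio reported for a large cohort: 34233 samples, 2094 with BMI
  meta_big <- data.frame(
    age_class = rep("infant", 34233), gender = rep("male", 34233),
    bmi_class = c(rep("obesity", 2094), rep(NA, 34233 - 2094)),
    body_site = rep("gut", 34233))
  w_big <- compute_task_weights(meta_big)
  expect_equal(unname(w_big[["bmi"]]), 34233 / 2094, tolerance = 1e-12)
  expect_equal(round(unname(w_big[["bmi"]]), 3), 16.348)

  # monotonicity: more missingness => larger weight, n fixed
  meta_less <- meta
  meta_less$age_class[26:50] <- NA
  w_less <- suppressWarnings(compute_task_weights(meta_less))
  expect_gt(w_less[["age"]], w[["age"]])
})

test_that("multitask loss matches hand-computed weighted cross-entropies", {
  # 2 samples, 2 diseases; age observed only for sample 1 => w_age = 2
  vocab_site <- c("gut", "skin")
  bundle <- list(
    disease_probs = matrix(c(0.7, 0.4, 0.3, 0.6), 2,
                           dimnames = list(NULL, c("healthy", "sick"))),
    meta_probs = list(
      age = matrix(rep(c(0.4, 0.12, 0.12, 0.12, 0.12, 0.12), each = 2), 2),
      gender = matrix(c(0.9, 0.2), 2),
      bmi = matrix(rep(0.25, 8), 2),
      body_site = matrix(rep(c(0.5, 0.5), each = 2), 2)))
  labels <- data.frame(
    phenotype = c("healthy", "sick"),
    age_class = c("infant", NA),
    gender = c(NA, NA),
    bmi_class = c(NA, NA),
    body_site = c(NA, NA))
  weights <- structure(c(age = 2, gender = NA, bmi = NA, body_site = NA))

  loss <- multitask_loss(bundle, labels, weights)
  hand <- -(log(0.7) + log(0.6)) + 2 * (-log(0.4))
  expect_equal(as.numeric(loss), hand, tolerance = 1e-9)

  # perfect one-hot predictions everywhere give zero loss
  perfect <- bundle
  perfect$disease_probs <- matrix(c(1, 0, 0, 1), 2,
                                  dimnames = list(NULL, c("healthy", "sick")))
  perfect$meta_probs$age <- matrix(rep(c(1, 0, 0, 0, 0, 0), each = 2), 2)
  expect_equal(as.numeric(multitask_loss(perfect, labels, weights)), 0,
               tolerance = 1e-6)

  # all metadata missing: loss reduces to the disease term alone
  labels_none <- labels
  labels_none$age_class <- c(NA, NA)
  loss_none <- multitask_loss(bundle, labels_none, weights)
  expect_equal(as.numeric(loss_none), -(log(0.7) + log(0.6)),
               tolerance = 1e-9)

  # decomposition: total equals the sum of the per-task terms, each matching
  # an oracle recomputation from the probabilities
  terms <- attr(loss, "terms")
  expect_equal(sum(terms), as.numeric(loss))
  expect_equal(unname(terms[["disease"]]),
               oracle_ce(bundle$disease_probs, c(1L, 2L)), tolerance = 1e-9)
  expect_equal(unname(terms[["age"]]),
               2 * oracle_ce(bundle$meta_probs$age[1, , drop = FALSE], 1L),
               tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  sim <- small_sim()
  ds <- sim$dataset
  cfg <- model_config(ds$species, sim$schema,
                      levels(ds$meta$phenotype), levels(ds$meta$body_site))
  mask <- build_mask(sim$schema, ds$species)
  m <- init_model(cfg, mask, seed = 1)
  x <- model_input(ds)[1:8, ]
  mi <- lapply(microkpnnmt:::meta_indices(ds$meta, cfg), `[`, 1:8)
  yd <- match(as.character(ds$meta$phenotype), cfg$vocab$disease)[1:8]
  w <- suppressWarnings(compute_task_weights(ds$meta[1:8, ]))

  lg <- microkpnnmt:::loss_and_grads(m, x, yd, mi, w)
  loss_at <- function(m2)
    microkpnnmt:::loss_and_grads(m2, x, yd, mi, w, want_grads = FALSE)$loss

  eps <- 1e-6
  num_grad <- function(setter) {
    (loss_at(setter(eps)) - loss_at(setter(-eps))) / (2 * eps)
  }
  set.seed(3)
  # a few random coordinates of every parameter block
  checks <- list(
    list("W", function(d) { m2 <- m; ij <- which(mask == 1, arr.ind = TRUE)[4, ]
      m2$W[ij[1], ij[2]] <- m2$W[ij[1], ij[2]] + d; m2 },
      function(g) { ij <- which(mask == 1, arr.ind = TRUE)[4, ]; g$W[ij[1], ij[2]] }),
    list("b1", function(d) { m2 <- m; m2$b1[5] <- m2$b1[5] + d; m2 },
      function(g) g$b1[5]),
    list("V", function(d) { m2 <- m; m2$V[2, 1] <- m2$V[2, 1] + d; m2 },
      function(g) g$V[2, 1]),
    list("cbias", function(d) { m2 <- m; m2$cbias[2] <- m2$cbias[2] + d; m2 },
      function(g) g$cbias[2]),
    list("A_age", function(d) { m2 <- m; m2$A$age[3, 2] <- m2$A$age[3, 2] + d; m2 },
      function(g) g$A_age[3, 2]),
    list("A_gender", function(d) { m2 <- m; m2$A$gender[2, 1] <- m2$A$gender[2, 1] + d; m2 },
      function(g) g$A_gender[2, 1]),
    list("a_bmi", function(d) { m2 <- m; m2$a$bmi[1] <- m2$a$bmi[1] + d; m2 },
      function(g) g$a_bmi[1]),
    list("A_body_site", function(d) { m2 <- m; m2$A$body_site[4, 2] <- m2$A$body_site[4, 2] + d; m2 },
      function(g) g$A_body_site[4, 2]))
  for (chk in checks) {
    expect_equal(unname(chk[[3]](lg$grads)), unname(num_grad(chk[[2]])),
                 tolerance = 1e-5, label = paste("grad of", chk[[1]]))
  }

  # masked positions: perturbing the weight leaves the loss unchanged and the
  # analytic gradient there is exactly zero
  ij0 <- unname(which(mask == 0, arr.ind = TRUE)[1, ])
  expect_identical(unname(lg$grads$W[ij0[1], ij0[2]]), 0)
  m3 <- m; m3$W[ij0[1], ij0[2]] <- m3$W[ij0[1], ij0[2]] + 5
  expect_equal(loss_at(m3), lg$loss, tolerance = 1e-12)
})

test_that("training preserves the mask exactly and is seed-deterministic", {
  sim <- small_sim()
  ds <- sim$dataset
  mask <- build_mask(sim$schema, ds$species)

  # ~8 epochs x 9 batches of 16 on 135 optimisation samples > 50 AdamW steps
  ctl <- train_config(seed = 6, max_epochs = 8, patience = 8)
  fit <- train_model(ds, sim$schema, control = ctl)
  expect_true(all(fit$model$W[mask == 0] == 0))
  expect_gt(sum(fit$model$W != 0), 0)

  fit2 <- train_model(ds, sim$schema, control = ctl)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$model$W, fit2$model$W)

  # zero epochs: the initialised state is returned untouched
  ctl0 <- train_config(seed = 6, max_epochs = 0)
  fit0 <- train_model(ds, sim$schema, control = ctl0)
  cfg <- model_config(ds$species, sim$schema,
                      levels(ds$meta$phenotype), levels(ds$meta$body_site))
  init <- microkpnnmt:::with_seed(6, init_model(cfg, mask))
  expect_equal(fit0$model$W, init$W)
  expect_equal(nrow(fit0$log), 0L)
})

test_that("early stopping returns the best monitored state", {
  sim <- small_sim()
  fit <- train_model(sim$dataset, sim$schema,
                     control = train_config(seed = 3, max_epochs = 30,
                                            patience = 5))
  best <- min(fit$log$val_disease)
  expect_equal(fit$log$val_disease[fit$best_epoch], best)
  # the returned model reproduces the best monitored loss
  ds <- sim$dataset
  expect_lte(fit$best_epoch, nrow(fit$log))
})

test_that("training fits strongly separable synthetic data", {
  spec <- sim_spec(n_samples = 220, n_species = 30, n_genera = 14,
                   n_phenotypes = 3, effect_disease = 4, effect_metadata = 1,
                   noise_sd = 0.2, seed = 17)
  sim <- simulate_dataset(spec)
  kn <- sim$knowledge
  schema <- build_hidden_schema(kn$species, kn$edges, kn$taxonomy,
                                kn$communities)
  fit <- train_model(sim$dataset, schema,
                     control = train_config(seed = 1, max_epochs = 120))
  expect_lt(utils::tail(fit$log$train_loss, 1), fit$log$train_loss[1])
  b <- model_forward(fit$model, model_input(sim$dataset),
                     observed = sim$dataset$meta)
  lab <- predict_labels(b, fit$model$config)
  expect_gte(macro_f1(lab$phenotype, sim$dataset$meta$phenotype), 0.95)
})

test_that("cross-validation folds are disjoint, covering, and aggregated correctly", {
  sim <- small_sim()
  cv <- cross_validate(sim$dataset, sim$schema, k = 3, seed = 2,
                       control = train_config(max_epochs = 3, patience = 3))
  expect_setequal(unique(cv$folds), 1:3)
  expect_equal(length(cv$folds), nrow(sim$dataset$abundance))
  # every sample appears exactly once out-of-fold
  expect_setequal(cv$oof$sample_id, sim$dataset$meta$sample_id)
  expect_equal(anyDuplicated(cv$oof$sample_id), 0L)
  # aggregate mean equals the arithmetic mean of fold values
  dis <- cv$per_fold[cv$per_fold$task == "disease", ]
  expect_equal(cv$summary$mean[cv$summary$task == "disease" &
                                 cv$summary$metric == "f1"],
               mean(dis$f1))
})
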