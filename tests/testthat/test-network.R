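# A tiny hand-controllable model: 4 species, toy schema (7 hidden nodes),
# 2 body sites, 2 diseases.
tiny_model <- function(seed = 1, ...) {
  schema <- toy_schema()
  cfg <- model_config(toy_species, schema,
                      disease_levels = c("healthy", "sick"),
                      body_site_levels = c("gut", "skin"), ...)
  list(config = cfg,
       model = init_model(cfg, build_mask(schema, toy_species), seed = seed))
}

test_that("masked linear layer ignores weights outside the mask", {
  tm <- tiny_model()
  m <- tm$model

  expect_equal(masked_linear(rep(0, 4), m), matrix(0, 1, 7),
               ignore_attr = TRUE)

  # closed form: one connection, relu(2 * 3) = 6
  schema1 <- build_hidden_schema("S1")
  cfg1 <- model_config("S1", schema1, c("a", "b"), c("gut", "skin"))
  m1 <- init_model(cfg1, build_mask(schema1, "S1"), seed = 1)
  m1$W[] <- 2; m1$b1[] <- 0
  expect_equal(unname(masked_linear(3, m1)), matrix(6, 1, 3))

  # oracle: equals a dense layer applied to W * M, for random W incl. values
  # planted outside the mask
  set.seed(7)
  m$W <- matrix(rnorm(28), 4, 7)
  x <- matrix(runif(12), 3, 4)
  dense <- pmax(x %*% (m$W * m$mask) + rep(m$b1, each = 3), 0)
  expect_equal(masked_linear(x, m), dense)

  expect_error(masked_linear(rep(0, 5), m), "expects 4")
})

test_that("metadata decoders apply softmax / sigmoid to one affine map", {
  tm <- tiny_model()
  m <- tm$model
  h <- masked_linear(matrix(runif(4), 1), m)

  m0 <- m
  for (t in c("age", "gender", "bmi", "body_site")) {
    m0$A[[t]][] <- 0; m0$a[[t]][] <- 0
  }
  expect_equal(unname(decode_metadata(h, m0, "age")), matrix(1 / 6, 1, 6))
  expect_equal(unname(decode_metadata(h, m0, "gender")), matrix(0.5, 1, 1))

  # hand-computed two-class softmax on h = (1, 0, ...)
  m2 <- m
  m2$A$bmi[] <- 0
  m2$A$bmi[1, 1] <- 1.2; m2$A$bmi[1, 2] <- -0.4
  m2$a$bmi <- c(0.1, 0, 0, 0)
  h10 <- matrix(c(1, rep(0, 6)), 1)
  z <- c(1.3, -0.4, 0, 0)
  expect_equal(unname(decode_metadata(h10, m2, "bmi")),
               matrix(exp(z) / sum(exp(z)), 1), tolerance = 1e-12)

  expect_error(decode_metadata(h, m, "height"), "unknown task")
})

test_that("fusion uses exact one-hots when observed and predictions otherwise", {
  tm <- tiny_model()
  cfg <- tm$config
  pred <- list(age = matrix(runif(12), 2), gender = matrix(c(0.3, 0.8), 2),
               bmi = matrix(runif(8), 2), body_site = matrix(runif(4), 2))
  pred <- lapply(pred, function(p) p / pmax(rowSums(p), 1e-9))
  pred$gender <- matrix(c(0.3, 0.8), 2)

  obs <- list(age = c(5L, NA), gender = c(NA, 1L), bmi = c(NA, NA),
              body_site = c(NA, 2L))
  fz <- fuse_metadata(pred, obs, cfg)
  expect_equal(fz$fused$age[1, ], c(0, 0, 0, 0, 1, 0))   # senior one-hot
  expect_equal(fz$fused$age[2, ], pred$age[2, ])
  expect_equal(fz$fused$gender[2, 1], 0)                  # observed female
  expect_equal(fz$fused$gender[1, 1], 0.3)
  expect_equal(fz$fused$body_site[2, ], c(0, 1))

  # all missing: fused equals predictions unchanged
  fz0 <- fuse_metadata(pred, NULL, cfg)
  expect_equal(fz0$fused, pred)

  # per-sample locality: changing sample 2's observedness leaves sample 1 alone
  obs2 <- obs; obs2$age[2] <- 3L
  fz2 <- fuse_metadata(pred, obs2, cfg)
  expect_equal(fz2$fused$age[1, ], fz$fused$age[1, ])

  expect_error(fuse_metadata(pred, list(age = c(9L, NA), gender = c(NA, NA),
                                        bmi = c(NA, NA),
                                        body_site = c(NA, NA)), cfg),
               "invalid label index")
})

test_that("disease decoder consumes trunk plus fused metadata in fixed order", {
  tm <- tiny_model()
  m <- tm$model
  x <- matrix(runif(8), 2, 4)
  h <- masked_linear(x, m)
  pred <- lapply(stats::setNames(c("age", "gender", "bmi", "body_site"),
                                 c("age", "gender", "bmi", "body_site")),
                 function(t) decode_metadata(h, m, t))
  fz <- fuse_metadata(pred, NULL, tm$config)

  m0 <- m; m0$V[] <- 0; m0$cbias[] <- 0
  expect_equal(unname(decode_disease(h, fz, m0)), matrix(0.5, 2, 2))

  # weights only on the age block: output depends only on the age vector
  m1 <- m0
  m1$V[7 + 1:6, 1] <- c(3, -1, 0, 2, 0, 0)    # age block sits after H = 7
  out <- decode_disease(h, fz, m1)
  z1 <- drop(fz$fused$age %*% m1$V[7 + 1:6, 1])
  expect_equal(out[, 1], exp(z1) / (exp(z1) + 1))
  fz_perturbed <- fz
  fz_perturbed$fused$bmi <- matrix(runif(8), 2)
  expect_equal(decode_disease(h, fz_perturbed, m1), out)

  # compositional oracle: generic dense forward on the concatenated input
  u <- cbind(h, fz$fused$age, fz$fused$gender, fz$fused$bmi,
             fz$fused$body_site)
  zd <- u %*% m$V + rep(m$cbias, each = 2)
  oracle <- exp(zd) / rowSums(exp(zd))
  expect_equal(unname(decode_disease(h, fz, m)), oracle, tolerance = 1e-12)
})

test_that("full forward equals the manual composition and is deterministic", {
  sim <- small_sim()
  ds <- sim$dataset
  cfg <- model_config(ds$species, sim$schema,
                      levels(ds$meta$phenotype), levels(ds$meta$body_site))
  m <- init_model(cfg, build_mask(sim$schema, ds$species), seed = 4)
  x <- model_input(ds)[1:10, ]
  meta <- ds$meta[1:10, ]

  b1 <- model_forward(m, x, observed = meta)
  b2 <- model_forward(m, x, observed = meta)
  expect_identical(b1, b2)

  h <- masked_linear(x, m)
  pred <- lapply(stats::setNames(c("age", "gender", "bmi", "body_site"),
                                 c("age", "gender", "bmi", "body_site")),
                 function(t) decode_metadata(h, m, t))
  fz <- fuse_metadata(pred, microkpnnmt:::meta_indices(meta, cfg), cfg)
  expect_equal(unname(b1$disease_probs), unname(decode_disease(h, fz, m)))
  expect_equal(b1$h, h)

  # toggling an observed metadata value changes the disease output
  meta2 <- meta
  meta2$body_site[1] <- setdiff(levels(meta2$body_site),
                                as.character(meta2$body_site[1]))[1]
  b3 <- model_forward(m, x, observed = meta2)
  expect_gt(max(abs(b3$disease_probs[1, ] - b1$disease_probs[1, ])), 0)
})

test_that("hard labels use lowest-index tie-breaking and a 0.5 gender threshold", {
  tm <- tiny_model()
  bundle <- list(
    disease_probs = matrix(c(0.5, 0.5), 1,
                           dimnames = list(NULL, c("healthy", "sick"))),
    meta_probs = list(age = matrix(1 / 6, 1, 6),
                      gender = matrix(0.49, 1, 1),
                      bmi = matrix(c(0.3, 0.3, 0.3, 0.1), 1),
                      body_site = matrix(c(0.2, 0.8), 1)))
  lab <- predict_labels(bundle, tm$config)
  expect_equal(lab$phenotype, "healthy")     # tie -> first class
  expect_equal(lab$age_class, "infant")      # uniform tie -> first class
  expect_equal(lab$gender, "female")         # p = 0.49 < 0.5
  expect_equal(lab$bmi_class, "underweight")

  # argmax equals a brute-force max scan on random probabilities
  set.seed(8)
  probs <- matrix(runif(40), 10, 4)
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("healthy", "a", "b", "c")
  brute <- apply(probs, 1, function(p) colnames(probs)[which(p == max(p))[1]])
  bundle2 <- list(disease_probs = probs)
  cfg2 <- tm$config; cfg2$vocab$disease <- colnames(probs)
  cfg2$use_metadata <- FALSE
  expect_equal(predict_labels(bundle2, cfg2)$phenotype, brute)
})

test_that("outputs are equivariant to species permutation", {
  sim <- small_sim()
  ds <- sim$dataset
  cfg <- model_config(ds$species, sim$schema,
                      levels(ds$meta$phenotype), levels(ds$meta$body_site))
  m <- init_model(cfg, build_mask(sim$schema, ds$species), seed = 4)
  x <- model_input(ds)[1:5, ]

  set.seed(1)
  perm <- sample.int(ncol(x))
  m_perm <- m
  m_perm$W <- m$W[perm, ]
  m_perm$mask <- m$mask[perm, ]
  m_perm$config$species <- cfg$species[perm]

  b <- model_forward(m, x, observed = ds$meta[1:5, ])
  b_perm <- model_forward(m_perm, x[, perm], observed = ds$meta[1:5, ])
  expect_equal(b_perm$disease_probs, b$disease_probs)
  expect_equal(b_perm$meta_probs, b$meta_probs)
})

test_that("with all metadata observed, decoder weights cannot touch the disease output", {
  sim <- small_sim(miss_age = 0, miss_gender = 0, miss_bmi = 0,
                   miss_body_site = 0)
  ds <- sim$dataset
  cfg <- model_config(ds$species, sim$schema,
                      levels(ds$meta$phenotype), levels(ds$meta$body_site))
  m <- init_model(cfg, build_mask(sim$schema, ds$species), seed = 9)
  x <- model_input(ds)

  b <- model_forward(m, x, observed = ds$meta)
  m2 <- m
  set.seed(2)
  for (t in c("age", "gender", "bmi", "body_site")) {
    m2$A[[t]] <- m2$A[[t]] + matrix(rnorm(length(m2$A[[t]])), nrow(m2$A[[t]]))
    m2$a[[t]] <- m2$a[[t]] + rnorm(length(m2$a[[t]]))
  }
  b2 <- model_forward(m2, x, observed = ds$meta)
  expect_identical(b2$disease_probs, b$disease_probs)
})
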