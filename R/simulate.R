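## Synthetic data with planted, recoverable structure: a Dirichlet-style
## compositional baseline, multiplicative log-fold shifts applied at the
## genus/community level (aligned with the knowledge graph, so the planted
## drivers are identifiable through the masked layer), log-normal noise,
## per-project offsets, metadata-driven phenotype assignment, and
## missing-at-random metadata masking.

#' Simulation specification
#'
#' Defaults describe a desk-scale study: 600 samples of 50 species across 6
#' projects, 4 phenotype classes (healthy + 3 diseases), and metadata
#' missingness mirroring large public microbiome compendia (body site always
#' recorded; age, gender and BMI largely missing).
#'
#' Each non-healthy phenotype, each age class, each BMI class and the male
#' gender is assigned its own driver genus, and each body site a driver
#' community; a sample's abundances in its drivers' member species are
#' multiplied by `exp(effect)`.  The phenotype itself is drawn from a logit
#' table over the sample's (age class, body site), with strength
#' `meta_effect`, so metadata carry phenotype information of their own.
#'
#' @param n_samples,n_species,n_metabolites,n_genera,n_communities Counts of
#'   simulated entities.
#' @param n_phenotypes Number of phenotype classes including healthy.
#' @param n_body_sites,n_projects Numbers of body sites and projects.
#' @param miss_age,miss_gender,miss_bmi,miss_body_site Per-task
#'   missing-at-random rates in `[0, 1]`.
#' @param effect_disease Log-fold shift applied to the phenotype driver
#'   genus.
#' @param effect_metadata Log-fold shift applied to the metadata driver
#'   groups.
#' @param meta_effect Strength of the (age, body site) to phenotype logit
#'   coupling.
#' @param noise_sd Log-normal multiplicative noise standard deviation.
#' @param base_shape Gamma shape of the compositional baseline: each sample's
#'   unshifted abundances are gamma draws with this shape around a fixed
#'   log-normal per-species mean profile (a Dirichlet-style draw).  Larger
#'   values give tighter sample-to-sample dispersion; the default 5 keeps the
#'   planted log-fold effects recoverable while leaving visible biological
#'   scatter.
#' @param project_sd Standard deviation of per-project, per-species log
#'   offsets (0 = no project structure).
#' @param age_probs,gender_probs,bmi_probs,site_probs Category marginals for
#'   the metadata draws (defaults uniform).
#' @param seed Integer seed; everything the generator emits is a
#'   deterministic function of the spec.
#' @return A list of class `kp_sim_spec`.
#' @export
sim_spec <- function(n_samples = 600, n_species = 50, n_metabolites = 8,
                     n_genera = 16, n_communities = 6, n_phenotypes = 4,
                     n_body_sites = 3, n_projects = 6,
                     miss_age = 0.81, miss_gender = 0.30, miss_bmi = 0.94,
                     miss_body_site = 0,
                     effect_disease = 2.5, effect_metadata = 2.5,
                     meta_effect = 1.5, noise_sd = 0.3, base_shape = 5,
                     project_sd = 0,
                     age_probs = rep(1 / 6, 6),
                     gender_probs = c(0.5, 0.5),
                     bmi_probs = rep(1 / 4, 4),
                     site_probs = rep(1 / n_body_sites, n_body_sites),
                     seed = 1) {
  spec <- as.list(environment())
  for (nm in grep("^n_", names(spec), value = TRUE))
    stopifnot_scalar_count(spec[[nm]], nm)
  rates <- unlist(spec[c("miss_age", "miss_gender", "miss_bmi",
                         "miss_body_site")])
  if (any(rates < 0 | rates > 1)) stop("missingness rates must lie in [0, 1]")
  if (spec$n_phenotypes < 2) stop("need at least 2 phenotype classes")
  n_driver_genera <- (spec$n_phenotypes - 1) + 6 + 1 + 4
  if (spec$n_genera < n_driver_genera)
    stop(sprintf("infeasible spec: %d driver genera needed (phenotypes + age + gender + BMI) but only %d genera",
                 n_driver_genera, spec$n_genera))
  if (spec$n_communities < spec$n_body_sites)
    stop("infeasible spec: need one driver community per body site")
  if (length(spec$age_probs) != 6 || length(spec$bmi_probs) != 4 ||
      length(spec$gender_probs) != 2 ||
      length(spec$site_probs) != spec$n_body_sites)
    stop("category probability vectors have wrong lengths")
  structure(spec, class = "kp_sim_spec")
}

sim_phenotype_levels <- function(spec) {
  c("healthy",
    sprintf("disease_%02d", seq_len(spec$n_phenotypes - 1L)))
}

#' Generate synthetic prior-knowledge sources
#'
#' Draws a random species-to-genus partition (every genus non-empty), a
#' random producer/consumer bipartite species-metabolite network (every
#' metabolite has both producers and consumers), and random overlapping
#' communities, then records which genera/communities act as planted drivers
#' for the phenotype and metadata categories.
#'
#' @param spec A `kp_sim_spec`.
#' @param dir Optional directory; when given, the three knowledge tables are
#'   written as `metabolic_edges.tsv`, `taxonomy.tsv`, `communities.tsv` in
#'   the dialect the parsers read.
#' @return A list of class `kp_knowledge`: `species`, `edges`, `taxonomy`,
#'   `communities`, `drivers`.
#' @export
make_knowledge <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "kp_sim_spec"))
  with_seed(spec$seed, {
    S <- spec$n_species
    species <- sprintf("S%03d", seq_len(S))
    genera <- sprintf("G%02d", seq_len(spec$n_genera))
    mets <- sprintf("M%02d", seq_len(spec$n_metabolites))
    comms <- sprintf("C%02d", seq_len(spec$n_communities))

    ## genus partition: one guaranteed member each, remainder random
    gidx <- c(seq_len(spec$n_genera),
              sample.int(spec$n_genera, S - spec$n_genera, replace = TRUE))
    taxonomy <- stats::setNames(genera[gidx], species)

    ## producer/consumer edges: both roles present for every metabolite
    edges <- do.call(rbind, lapply(mets, function(m) {
      prod <- sample(species, sample(2:4, 1L))
      cons <- sample(setdiff(species, prod), sample(2:4, 1L))
      data.frame(species_id = c(prod, cons), metabolite_id = m,
                 role = rep(c("producer", "consumer"),
                            c(length(prod), length(cons))),
                 stringsAsFactors = FALSE)
    }))

    ## overlapping communities
    communities <- do.call(rbind, lapply(comms, function(cm) {
      size <- sample(max(2L, floor(S / 6)):max(3L, floor(S / 3)), 1L)
      data.frame(species_id = sample(species, size), community_id = cm,
                 stringsAsFactors = FALSE)
    }))

    P <- spec$n_phenotypes
    drivers <- list(
      disease = stats::setNames(c(NA, genera[seq_len(P - 1L)]),
                                sim_phenotype_levels(spec)),
      age = stats::setNames(genera[(P - 1L) + 1:6], KP_AGE_LEVELS),
      gender = stats::setNames(genera[(P - 1L) + 7L], "male"),
      bmi = stats::setNames(genera[(P - 1L) + 7L + 1:4], KP_BMI_LEVELS),
      body_site = stats::setNames(comms[seq_len(spec$n_body_sites)],
                                  sprintf("site_%02d",
                                          seq_len(spec$n_body_sites))))

    kn <- structure(list(species = species, edges = edges,
                         taxonomy = taxonomy, communities = communities,
                         drivers = drivers), class = "kp_knowledge")
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(edges, file.path(dir, "metabolic_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      utils::write.table(data.frame(names(taxonomy), unname(taxonomy)),
                         file.path(dir, "taxonomy.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      utils::write.table(communities, file.path(dir, "communities.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
    kn
  })
}

## Species membership of a genus / community as a logical vector over the
## input species.
species_in_genus <- function(kn, genus) unname(kn$taxonomy == genus)
species_in_community <- function(kn, comm) {
  kn$species %in% kn$communities$species_id[kn$communities$community_id == comm]
}

#' Simulate a full dataset with planted signal
#'
#' Draws metadata from their category marginals, draws the phenotype from a
#' logit table over (age class, body site), composes abundances as a gamma
#' (Dirichlet) baseline times the exponential of the planted driver shifts,
#' per-project offsets and log-normal noise, renormalises each sample to
#' 100%, and finally masks metadata to missing at random.  Every quantity is
#' a deterministic function of the spec.
#'
#' @param spec A `kp_sim_spec`.
#' @param knowledge Optional `kp_knowledge`; regenerated from the spec if
#'   omitted.
#' @return A list of class `kp_sim`: `dataset` (a `kp_dataset` with masked
#'   metadata), `knowledge`, and `truth` (complete pre-masking metadata,
#'   driver assignments, project offsets).
#' @export
simulate_dataset <- function(spec, knowledge = NULL) {
  stopifnot(inherits(spec, "kp_sim_spec"))
  kn <- knowledge %||% make_knowledge(spec)
  with_seed(spec$seed + 1L, {
    n <- spec$n_samples; S <- spec$n_species
    P <- spec$n_phenotypes
    pheno_levels <- sim_phenotype_levels(spec)
    site_levels <- names(kn$drivers$body_site)

    project <- sample.int(spec$n_projects, n, replace = TRUE)
    age <- sample.int(6L, n, replace = TRUE, prob = spec$age_probs)
    gender <- sample.int(2L, n, replace = TRUE, prob = spec$gender_probs)
    bmi <- sample.int(4L, n, replace = TRUE, prob = spec$bmi_probs)
    site <- sample.int(spec$n_body_sites, n, replace = TRUE,
                       prob = spec$site_probs)

    ## phenotype class d is associated with one age class and one body site
    assoc_age <- ((seq_len(P) - 1L) %% 6L) + 1L
    assoc_site <- ((seq_len(P) - 1L) %% spec$n_body_sites) + 1L
    logits <- spec$meta_effect *
      (outer(age, assoc_age, "==") + outer(site, assoc_site, "=="))
    pheno <- apply(softmax_rows(logits), 1L, function(p)
      sample.int(P, 1L, prob = p))

    ## log-fold shifts from the planted drivers
    shift <- matrix(0, n, S)
    for (d in 2:P) {
      mem <- species_in_genus(kn, kn$drivers$disease[[pheno_levels[d]]])
      shift[pheno == d, mem] <- shift[pheno == d, mem] + spec$effect_disease
    }
    for (a in 1:6) {
      mem <- species_in_genus(kn, kn$drivers$age[[a]])
      shift[age == a, mem] <- shift[age == a, mem] + spec$effect_metadata
    }
    mem <- species_in_genus(kn, kn$drivers$gender[[1L]])
    shift[gender == 2L, mem] <- shift[gender == 2L, mem] + spec$effect_metadata
    for (b in 1:4) {
      mem <- species_in_genus(kn, kn$drivers$bmi[[b]])
      shift[bmi == b, mem] <- shift[bmi == b, mem] + spec$effect_metadata
    }
    for (s in seq_len(spec$n_body_sites)) {
      mem <- species_in_community(kn, kn$drivers$body_site[[s]])
      shift[site == s, mem] <- shift[site == s, mem] + spec$effect_metadata
    }

    offsets <- matrix(stats::rnorm(spec$n_projects * S, 0, spec$project_sd),
                      spec$n_projects, S)
    noise <- matrix(stats::rnorm(n * S, 0, spec$noise_sd), n, S)
    mean_profile <- exp(stats::rnorm(S, 0, 1))
    base <- matrix(stats::rgamma(n * S, shape = spec$base_shape,
                                 rate = spec$base_shape), n, S) *
      rep(mean_profile, each = n)
    x <- base * exp(shift + offsets[project, , drop = FALSE] + noise)
    x <- 100 * x / rowSums(x)
    dimnames(x) <- list(sprintf("sample_%04d", seq_len(n)), kn$species)

    true_meta <- data.frame(
      sample_id = rownames(x),
      age_class = factor(KP_AGE_LEVELS[age], levels = KP_AGE_LEVELS),
      gender = factor(KP_GENDER_LEVELS[gender], levels = KP_GENDER_LEVELS),
      bmi_class = factor(KP_BMI_LEVELS[bmi], levels = KP_BMI_LEVELS),
      body_site = factor(site_levels[site], levels = site_levels),
      phenotype = factor(pheno_levels[pheno], levels = pheno_levels),
      project_id = factor(sprintf("P%02d", project),
                          levels = sprintf("P%02d", seq_len(spec$n_projects))),
      stringsAsFactors = FALSE)

    meta <- true_meta
    rates <- c(age_class = spec$miss_age, gender = spec$miss_gender,
               bmi_class = spec$miss_bmi, body_site = spec$miss_body_site)
    for (col in names(rates))
      meta[[col]][stats::runif(n) < rates[[col]]] <- NA

    structure(list(dataset = microbiome_dataset(x, meta),
                   knowledge = kn,
                   truth = list(meta = true_meta, drivers = kn$drivers,
                                assoc_age = assoc_age,
                                assoc_site = assoc_site,
                                project_offsets = offsets)),
              class = "kp_sim")
  })
}

#' Synthetic project-held-out distribution-shift scenario
#'
#' Simulates a dataset whose projects carry independent per-species log
#' offsets (strength `spec$project_sd`), then splits it into train/test by
#' project, with no project overlap.  The metadata-to-phenotype mechanism is
#' shared between splits, so observed metadata remain informative across the
#' shift while project-specific abundance structure does not transfer.
#'
#' @param spec A `kp_sim_spec` with `n_projects >= 2`.
#' @param train_fraction Fraction of projects assigned to training (default
#'   2/3; at least one project on each side).
#' @return A list with `train` and `test` (`kp_dataset`s), the full `sim`
#'   object, and the project id split.
#' @export
make_shift_scenario <- function(spec, train_fraction = 2 / 3) {
  if (spec$n_projects < 2) stop("need at least 2 projects to hold projects out")
  sim <- simulate_dataset(spec)
  projects <- levels(sim$dataset$meta$project_id)
  n_train <- min(length(projects) - 1L,
                 max(1L, round(train_fraction * length(projects))))
  train_projects <- projects[seq_len(n_train)]
  test_projects <- setdiff(projects, train_projects)
  splits <- split_by_project(sim$dataset, train_projects, test_projects)
  list(train = splits$train, test = splits$test, sim = sim,
       train_projects = train_projects, test_projects = test_projects)
}
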