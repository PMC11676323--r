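# Fixtures are built in code at test time; nothing is read from disk except
# what the tests themselves write to tempdirs.

write_tsv_lines <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# The four-species toy: M1 produced by {S1,S2}, consumed by {S3};
# genera S1,S2 -> G1 and S3,S4 -> G2; community C1 = {S1,S3}.
toy_species <- c("S1", "S2", "S3", "S4")

toy_knowledge_files <- function() {
  list(
    metabolic = write_tsv_lines(c("S1\tM1\tproducer",
                                  "S2\tM1\tproducer",
                                  "S3\tM1\tconsumer")),
    taxonomy = write_tsv_lines(c("S1\tG1", "S2\tG1", "S3\tG2", "S4\tG2")),
    communities = write_tsv_lines(c("S1\tC1", "S3\tC1")))
}

toy_schema <- function() {
  f <- toy_knowledge_files()
  build_hidden_schema(toy_species,
                      parse_metabolic_edges(f$metabolic),
                      parse_taxonomy_map(f$taxonomy),
                      parse_communities(f$communities))
}

# Small simulated dataset + matching schema, shared across tests.
small_sim <- function(seed = 5, n_samples = 150, n_species = 25, ...) {
  spec <- sim_spec(n_samples = n_samples, n_species = n_species,
                   n_genera = 14, n_phenotypes = 3, seed = seed, ...)
  sim <- simulate_dataset(spec)
  kn <- sim$knowledge
  sim$schema <- build_hidden_schema(kn$species, kn$edges, kn$taxonomy,
                                    kn$communities)
  sim
}

# One small trained model reused by the interpretation tests (trained once
# per test run).
.kp_test_cache <- new.env(parent = emptyenv())

cached_toy_fit <- function() {
  if (is.null(.kp_test_cache$fit)) {
    sim <- small_sim()
    fit <- train_model(sim$dataset, sim$schema,
                       control = train_config(seed = 2, max_epochs = 60))
    .kp_test_cache$fit <- fit
    .kp_test_cache$sim <- sim
  }
  list(fit = .kp_test_cache$fit, sim = .kp_test_cache$sim)
}

model_input <- function(dataset) microkpnnmt:::model_matrix(dataset)
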