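## Prior-knowledge parsing and construction of the knowledge-primed hidden
## layer: named hidden nodes (metabolite production/consumption, genus,
## community, plus catch-all "unknown" nodes) and the binary species-to-node
## connectivity mask they induce.

KP_NODE_GROUPS <- c("metabolite_production", "metabolite_consumption",
                    "genus", "community",
                    "unknown_metabolite", "unknown_genus", "unknown_community")

#' Parse a producer/consumer metabolic edge list
#'
#' Reads a three-column delimited file (`species_id`, `metabolite_id`, `role`)
#' in the style of the NJS16 species-metabolite network, where `role` is
#' either `"producer"` or `"consumer"`.  Duplicate rows are collapsed.
#'
#' @param path Path to a TSV/CSV file.  A header row is auto-detected when its
#'   first field looks like a column label (e.g. `species_id`).
#' @return A data frame with columns `species_id`, `metabolite_id`, `role`
#'   (one row per unique edge).
#' @export
parse_metabolic_edges <- function(path) {
  parsed <- read_delim_rows(path, 3L, "metabolic edge")
  rows <- parsed$rows
  if (nrow(rows) == 0L)
    return(data.frame(species_id = character(), metabolite_id = character(),
                      role = character(), stringsAsFactors = FALSE))
  role <- tolower(rows[, 3L])
  bad <- !role %in% c("producer", "consumer")
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("unknown role '%s' at line %d of '%s' (expected 'producer' or 'consumer')",
                 rows[i, 3L], parsed$lines[i], path), call. = FALSE)
  }
  edges <- data.frame(species_id = rows[, 1L], metabolite_id = rows[, 2L],
                      role = role, stringsAsFactors = FALSE)
  unique(edges)
}

#' Parse a species-to-genus taxonomy map
#'
#' Reads a two-column delimited file (`species_id`, `genus_id`) derived from a
#' hierarchical taxonomy such as NCBI's.  The mapping must be functional: a
#' species listed with two different genera is an error.
#'
#' @inheritParams parse_metabolic_edges
#' @return A named character vector mapping species id to genus id.
#' @export
parse_taxonomy_map <- function(path) {
  rows <- read_delim_rows(path, 2L, "taxonomy")$rows
  if (nrow(rows) == 0L) return(stats::setNames(character(), character()))
  rows <- unique(rows)
  dup <- unique(rows[duplicated(rows[, 1L]), 1L])
  if (length(dup) > 0L)
    stop("conflicting genus assignments for species: ",
         paste(dup, collapse = ", "), call. = FALSE)
  stats::setNames(rows[, 2L], rows[, 1L])
}

#' Parse species-to-community memberships
#'
#' Reads a two-column delimited file (`species_id`, `community_id`).
#' Communities come from an upstream co-occurrence-network community
#' detection (e.g. Leiden) and may overlap: one species can belong to
#' several communities.
#'
#' @inheritParams parse_metabolic_edges
#' @return A data frame with columns `species_id`, `community_id`.
#' @export
parse_communities <- function(path) {
  rows <- read_delim_rows(path, 2L, "community")$rows
  unique(data.frame(species_id = rows[, 1L], community_id = rows[, 2L],
                    stringsAsFactors = FALSE))
}

kp_node <- function(name, group, members) {
  list(name = name, group = group, members = members)
}

#' Build the knowledge-primed hidden-layer schema
#'
#' Constructs the ordered list of named hidden nodes induced by the three
#' prior-knowledge sources, restricted to the species actually present in the
#' input layer:
#' * two nodes per metabolite (production and consumption), connected to the
#'   metabolite's producer and consumer species respectively;
#' * one node per genus, connected to its member species;
#' * one node per community, connected to its member species;
#' * one catch-all "unknown" node per knowledge source, collecting the input
#'   species that the source does not annotate (omitted when empty), so that
#'   every species keeps at least one connection into the hidden layer.
#'
#' Node order is deterministic: metabolite nodes sorted by metabolite id with
#' production before consumption, then genera (sorted), then communities
#' (sorted), then unknown nodes.
#'
#' @param species Character vector of input species ids (unique, non-empty);
#'   defines the input-layer order.
#' @param edges Data frame from [parse_metabolic_edges()].
#' @param taxmap Named character vector from [parse_taxonomy_map()].
#' @param commmap Data frame from [parse_communities()].
#' @return An object of class `kp_schema`: a list of nodes, each with `name`,
#'   `group` and `members`, with the species vector kept as an attribute.
#' @export
build_hidden_schema <- function(species, edges = NULL, taxmap = NULL,
                                commmap = NULL) {
  if (length(species) == 0L) stop("species list must be non-empty")
  if (anyDuplicated(species)) stop("species ids must be unique")
  species <- as.character(species)
  edges <- edges %||% data.frame(species_id = character(),
                                 metabolite_id = character(),
                                 role = character())
  taxmap <- taxmap %||% stats::setNames(character(), character())
  commmap <- commmap %||% data.frame(species_id = character(),
                                     community_id = character())

  nodes <- list()

  ## metabolite production/consumption nodes
  edges <- edges[edges$species_id %in% species, , drop = FALSE]
  mets <- sort(unique(edges$metabolite_id))
  for (m in mets) {
    for (role in c("producer", "consumer")) {
      mem <- unique(edges$species_id[edges$metabolite_id == m &
                                     edges$role == role])
      grp <- if (role == "producer") "metabolite_production"
             else "metabolite_consumption"
      suffix <- if (role == "producer") "production" else "consumption"
      if (length(mem) == 0L)
        warning(sprintf("metabolite '%s' has no %s among the input species; node kept with no connections",
                        m, if (role == "producer") "producers" else "consumers"))
      nodes[[length(nodes) + 1L]] <-
        kp_node(paste0(m, "_", suffix), grp, sort(mem))
    }
  }

  ## genus nodes
  taxmap <- taxmap[names(taxmap) %in% species]
  for (g in sort(unique(unname(taxmap)))) {
    nodes[[length(nodes) + 1L]] <-
      kp_node(g, "genus", sort(names(taxmap)[taxmap == g]))
  }

  ## community nodes
  commmap <- commmap[commmap$species_id %in% species, , drop = FALSE]
  for (cm in sort(unique(commmap$community_id))) {
    nodes[[length(nodes) + 1L]] <-
      kp_node(cm, "community",
              sort(unique(commmap$species_id[commmap$community_id == cm])))
  }

  ## catch-all nodes for species unannotated in each source
  unknowns <- list(
    unknown_metabolite = setdiff(species, unique(edges$species_id)),
    unknown_genus      = setdiff(species, names(taxmap)),
    unknown_community  = setdiff(species, unique(commmap$species_id)))
  for (nm in names(unknowns)) {
    if (length(unknowns[[nm]]) > 0L)
      nodes[[length(nodes) + 1L]] <- kp_node(nm, nm, unknowns[[nm]])
  }

  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names(nodes)))
    stop("hidden-node name collision across knowledge sources: ",
         paste(unique(names(nodes)[duplicated(names(nodes))]), collapse = ", "))
  structure(nodes, class = "kp_schema", species = species)
}

#' @export
print.kp_schema <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("kp_schema: %d hidden nodes over %d species\n",
              length(x), length(attr(x, "species"))))
  print(table(factor(groups, levels = KP_NODE_GROUPS)))
  invisible(x)
}

#' Node metadata of a hidden-layer schema
#'
#' @param schema A `kp_schema`.
#' @return A data frame with columns `name`, `group` and `n_members`.
#' @export
schema_nodes <- function(schema) {
  data.frame(name = vapply(schema, `[[`, character(1), "name"),
             group = vapply(schema, `[[`, character(1), "group"),
             n_members = vapply(schema, function(n) length(n$members),
                                integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the binary species-to-hidden-node mask
#'
#' Materialises the schema memberships as a binary matrix with one row per
#' input species (in input order) and one column per hidden node (in schema
#' order).  Entry `[i, j]` is 1 iff species `i` is a member of node `j`; this
#' matrix multiplies the first-layer weights elementwise so that only
#' knowledge-supported connections can be nonzero.
#'
#' @param schema A `kp_schema` built from the same species list.
#' @param species Character vector of species ids; must equal the schema's
#'   species set (any order; rows follow the order given here).
#' @return A binary matrix of dimension `length(species) x length(schema)`
#'   with species ids as rownames and node names as colnames.
#' @export
build_mask <- function(schema, species) {
  schema_species <- attr(schema, "species")
  if (!setequal(species, schema_species) ||
      length(species) != length(schema_species))
    stop("species list does not match the species the schema was built from")
  mask <- matrix(0, length(species), length(schema),
                 dimnames = list(species,
                                 unname(vapply(schema, `[[`, character(1),
                                               "name"))))
  for (j in seq_along(schema)) {
    mask[schema[[j]]$members, j] <- 1
  }
  mask
}
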