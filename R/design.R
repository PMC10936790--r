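#' Database design configuration
#'
#' @param cap Maximum genomes per database (commonly 200, 300 or 500).
#' @param rank_limit Taxonomic limit for phylogenetic filling; fixed at
#'   `"order"` — no genome from outside the source species' order is ever
#'   admitted.
#' @param small_db_threshold Databases smaller than this are reported as
#'   very small (default 5).
#' @param min_genome_size_bp Genomes below this size are excluded from the
#'   representative sketch database (default 200 kbp; such tiny genomes are
#'   outside the taxonomy's scope).
#' @return A `"design_config"` list.
#' @export
design_config <- function(cap, rank_limit = "order", small_db_threshold = 5,
                          min_genome_size_bp = 200000) {
  stopifnot(is.numeric(cap), length(cap) == 1L, cap >= 1,
            small_db_threshold >= 1)
  if (!identical(rank_limit, "order")) {
    stop("rank_limit is fixed at 'order'")
  }
  structure(list(cap = as.integer(cap), rank_limit = "order",
                 small_db_threshold = as.integer(small_db_threshold),
                 min_genome_size_bp = as.numeric(min_genome_size_bp)),
            class = "design_config")
}

.ranked_accessions <- function(x) {
  if (inherits(x, "ranked_list")) x$accessions else as.character(x)
}

#' Design the reference database for one species
#'
#' Fills the database from the species' own ranked genome list, truncated
#' at the cap.  If the cap is not reached, the ranked lists of neighbouring
#' species are appended in order of ascending tree distance, the final
#' donor truncated to land exactly on the cap.  Filling never reaches
#' outside the taxonomic order, so some databases stay below the cap
#' (submaximal).
#'
#' @param target Species label.
#' @param ranked_lists Named list of ranked lists (or plain accession
#'   vectors) keyed by species.
#' @param neighbors Data frame from [neighbor_species()] for `target`
#'   (same-order species by ascending distance).
#' @param config A [design_config()].
#' @return A `"db_design"`: list with `source_species`, `members` (ordered
#'   accessions), `donors` (data frame `species`, `genomes_contributed` in
#'   fill order), `submaximal`, `cap`.
#' @export
design_for_species <- function(target, ranked_lists, neighbors, config) {
  own <- ranked_lists[[target]]
  if (is.null(own) || length(.ranked_accessions(own)) == 0L) {
    stop("no genomes collected for species '", target, "'; cannot design DB")
  }
  cap <- config$cap
  members <- head(.ranked_accessions(own), cap)
  donors <- data.frame(species = character(), genomes_contributed = integer(),
                       stringsAsFactors = FALSE)
  if (length(members) < cap && nrow(neighbors) > 0) {
    for (i in seq_len(nrow(neighbors))) {
      if (length(members) >= cap) break
      donor_sp <- neighbors$species[i]
      donor <- ranked_lists[[donor_sp]]
      if (is.null(donor)) next  # species never collected: skip, adapt
      contrib <- head(.ranked_accessions(donor), cap - length(members))
      if (length(contrib) == 0L) next
      members <- c(members, contrib)
      donors <- rbind(donors, data.frame(species = donor_sp,
                                         genomes_contributed = length(contrib),
                                         stringsAsFactors = FALSE))
    }
  }
  structure(list(source_species = target, members = members, donors = donors,
                 submaximal = length(members) < cap, cap = cap),
            class = "db_design")
}

#' @export
print.db_design <- function(x, ...) {
  cat(sprintf("db_design for %s: %d genomes (%s), %d donor species\n",
              x$source_species, length(x$members),
              if (x$submaximal) "submaximal" else "at cap", nrow(x$donors)))
  invisible(x)
}

#' Design the full database set for a release
#'
#' Runs [design_for_species()] for every species (in lexicographic order),
#' deduplicates identical compositions, and assembles the design set with
#' its summary counts.  Per-species failures (e.g. species with no
#' collected genomes) are collected into an error manifest rather than
#' aborting the run.  A warning lists any databases smaller than the
#' small-DB threshold.
#'
#' @param species Character vector of species to design for.
#' @param ranked_lists Named list of ranked lists keyed by species (see
#'   [rank_all_species()]).
#' @param trees A single species tree or a named list of per-domain trees
#'   (e.g. `list(Bacteria = ..., Archaea = ...)`).
#' @param lineages Lineage table (one row per species with the seven
#'   ranks); a metadata table also works.
#' @param config A [design_config()].
#' @param release Release label stored in the set.
#' @return A `"design_set"`: list with `release`, `config`, `dbs` (unique
#'   designs keyed by db id), `species_map` (species to db id), `counts`
#'   and `errors`.
#' @export
design_all <- function(species, ranked_lists, trees, lineages, config,
                       release = "release") {
  species <- sort(unique(species))
  if (inherits(trees, "phylo")) trees <- list(all = trees)
  lineages <- unique(lineages[, .ranks, drop = FALSE])
  dist_mats <- lapply(trees, species_distance_matrix)
  tree_of <- function(sp) {
    for (nm in names(trees)) if (sp %in% trees[[nm]]$tip.label) return(nm)
    NA_character_
  }
  designs <- list()
  errors <- character()
  for (sp in species) {
    res <- tryCatch({
      dom <- tree_of(sp)
      if (is.na(dom)) stop("species '", sp, "' not found in any tree")
      nb <- neighbor_species(trees[[dom]], lineages, sp,
                             dist_matrix = dist_mats[[dom]])
      design_for_species(sp, ranked_lists, nb, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[sp] <- conditionMessage(res)
    } else {
      designs[[sp]] <- res
    }
  }
  set <- deduplicate(designs, config = config, release = release)
  set$errors <- errors
  small <- names(set$dbs)[vapply(set$dbs, function(d)
    length(d$members) < config$small_db_threshold, logical(1))]
  if (length(small)) {
    small_sp <- vapply(set$dbs[small], function(d) d$source_species,
                       character(1))
    warning("very small DB(s) (size < ", config$small_db_threshold, "): ",
            paste(sprintf("%s (%s, %d genomes)", small, small_sp,
                          vapply(set$dbs[small], function(d)
                            length(d$members), integer(1))),
                  collapse = "; "))
  }
  set
}

#' Deduplicate database designs
#'
#' Designs whose member accession sets are equal (as unordered sets) share
#' one stored database; the retained design is the one whose source species
#' is lexicographically least, and its fill order defines the stored member
#' order.  Every species maps to exactly one database.
#'
#' @param designs Named list of `"db_design"` objects keyed by species.
#' @param config The [design_config()] used.
#' @param release Release label.
#' @return A `"design_set"`.
#' @export
deduplicate <- function(designs, config = NULL, release = "release") {
  if (length(designs) == 0L) {
    return(structure(list(release = release, config = config, dbs = list(),
                          species_map = character(),
                          counts = .design_counts(list(), character())),
                     class = "design_set"))
  }
  keys <- vapply(designs, function(d) paste(sort(d$members), collapse = ","),
                 character(1))
  ukeys <- unique(keys)
  keep <- character(length(ukeys))
  names(keep) <- ukeys
  for (k in ukeys) {
    sources <- names(designs)[keys == k]
    keep[k] <- min(sources)
  }
  retained_sources <- sort(unname(keep))
  db_ids <- sprintf("DB%06d", seq_along(retained_sources))
  names(db_ids) <- keys[retained_sources]
  dbs <- setNames(designs[retained_sources], db_ids)
  species_map <- setNames(unname(db_ids[keys]), names(designs))
  species_map <- species_map[sort(names(species_map))]
  structure(list(release = release, config = config, dbs = dbs,
                 species_map = species_map,
                 counts = .design_counts(dbs, species_map,
                                         threshold = config$small_db_threshold %||% 5)),
            class = "design_set")
}

.design_counts <- function(dbs, species_map, threshold = 5) {
  sizes <- vapply(dbs, function(d) length(d$members), integer(1))
  list(n_species = length(species_map),
       unique_dbs = length(dbs),
       submaximal_dbs = sum(vapply(dbs, function(d) d$submaximal, logical(1))),
       small_dbs = sum(sizes < threshold),
       unique_genomes = length(unique(unlist(lapply(dbs, function(d)
         d$members), use.names = FALSE))))
}

#' @export
print.design_set <- function(x, ...) {
  cat(sprintf(paste0("design_set '%s' (cap %s): %d species, %d unique DBs, ",
                     "%d submaximal, %d below size %s, %d unique genomes\n"),
              x$release, x$config$cap %||% "?", x$counts$n_species,
              x$counts$unique_dbs, x$counts$submaximal_dbs,
              x$counts$small_dbs, x$config$small_db_threshold %||% 5,
              x$counts$unique_genomes))
  if (length(x$errors)) cat(length(x$errors), "species failed design\n")
  invisible(x)
}

#' Summarise a design set
#'
#' One row with the design-set bookkeeping: species covered, cap, unique
#' databases, submaximal databases, databases below the small threshold,
#' and the number of distinct genomes across all databases.
#'
#' @param design_set A `"design_set"`.
#' @return A one-row data frame.
#' @export
summarize_design_set <- function(design_set) {
  c0 <- design_set$counts
  data.frame(species = c0$n_species,
             cap = design_set$config$cap %||% NA_integer_,
             unique_dbs = c0$unique_dbs,
             submaximal_dbs = c0$submaximal_dbs,
             small_dbs = c0$small_dbs,
             unique_genomes = c0$unique_genomes)
}
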