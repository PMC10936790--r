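#' Double quality sort of a species' genomes
#'
#' Sorts genome records first by MIMAG quality tier (high, medium, low,
#' then missing), then by contig count ascending (unknown counts after
#' known), then by accession for a deterministic total order.  The species
#' representative is expected to have been removed by the caller.
#'
#' @param genomes Metadata data frame (rows for a single species), see
#'   [parse_metadata_table()].
#' @return Accessions in sorted order.
#' @export
quality_sort <- function(genomes) {
  if (nrow(genomes) == 0L) return(character())
  q <- match(genomes$mimag_quality, .quality_levels)
  q[is.na(q)] <- length(.quality_levels)
  contig <- as.numeric(genomes$contig_count)
  contig[is.na(contig)] <- Inf
  genomes$accession[order(q, contig, genomes$accession)]
}

#' Greedy maximum-diversity reordering
#'
#' Farthest-point-style greedy ordering seeded by the species
#' representative: position 1 is the representative; each subsequent
#' position holds the unselected genome with the highest summed sketch
#' distance to all previously selected genomes.  Ties are broken by
#' position in `pool` (the quality order), earlier first.  Pairs with no
#' recorded distance score 0 in the sum, so a genome whose sketch failed is
#' deprioritised but never dropped.
#'
#' @param pool Ordered candidate accessions (quality order), excluding the
#'   representative.
#' @param representative Accession placed first.
#' @param distances Distance table (see [pairwise_within_species()]) or
#'   `NULL`.
#' @return Accessions: `representative` followed by the greedy order of
#'   `pool`.
#' @export
diversity_reorder <- function(pool, representative, distances = NULL) {
  if (length(pool) == 0L) return(representative)
  d <- dist_lookup(distances)
  remaining <- pool
  selected <- representative
  sums <- vapply(remaining, function(g) d(g, representative), numeric(1))
  out <- character(length(pool))
  for (i in seq_along(pool)) {
    best <- which(sums == max(sums))[1]  # first index = earliest in pool order
    g <- remaining[best]
    out[i] <- g
    remaining <- remaining[-best]
    sums <- sums[-best]
    if (length(remaining)) {
      sums <- sums + vapply(remaining, function(x) d(x, g), numeric(1))
    }
  }
  c(representative, out)
}

#' Rank a species' genomes for database filling
#'
#' Produces the final within-species genome order: the species
#' representative first, then the top 90% of the quality-sorted remainder
#' reordered by greedy diversity, then the lowest-quality 10% kept in
#' quality order at the bottom.  The tail size is `floor(0.1 * (N - 1))`
#' with `N` the total number of genomes including the representative.  If
#' the representative was never collected, the quality leader seeds the
#' diversity ordering instead and a warning is issued.
#'
#' @param genomes Metadata rows for one species.
#' @param distances Within-species distance table, or `NULL`.
#' @return A `"ranked_list"`: list with `species`, `accessions`,
#'   `provenance` (per genome: `"representative"`, `"diversity_block"` or
#'   `"quality_tail"`), `protocol = "ranked"` and `seed = NA`.
#' @export
rank_species <- function(genomes, distances = NULL) {
  if (nrow(genomes) == 0L) stop("no genomes collected for species")
  sp <- unique(genomes$species)
  if (length(sp) != 1L) stop("genomes must all belong to one species, got: ",
                             paste(sp, collapse = ", "))
  n <- nrow(genomes)
  rep_acc <- genomes$accession[genomes$is_representative]
  if (length(rep_acc) > 1L) stop("species '", sp, "' has ", length(rep_acc),
                                 " representative genomes; expected at most 1")
  rest <- genomes[!genomes$is_representative, , drop = FALSE]
  qs <- quality_sort(rest)
  tail_n <- floor(0.1 * (n - 1))
  tail_accs <- if (tail_n > 0) qs[(length(qs) - tail_n + 1L):length(qs)] else character()
  top <- if (tail_n > 0) qs[seq_len(length(qs) - tail_n)] else qs
  if (length(rep_acc) == 1L) {
    div <- diversity_reorder(top, rep_acc, distances)
    prov_head <- c("representative", rep("diversity_block", length(top)))
  } else {
    warning("species '", sp, "' has no collected representative; ",
            "seeding diversity order with the quality leader")
    div <- diversity_reorder(top[-1], top[1], distances)
    prov_head <- rep("diversity_block", length(top))
  }
  structure(list(species = sp,
                 accessions = c(div, tail_accs),
                 provenance = c(prov_head, rep("quality_tail", length(tail_accs))),
                 protocol = "ranked", seed = NA_integer_),
            class = "ranked_list")
}

#' Random genome order (control protocol)
#'
#' Uniform random permutation of a species' genomes from R's seeded
#' Mersenne-Twister stream; reproducible for a fixed seed and independent
#' of the caller's RNG state.
#'
#' @param genomes Metadata rows for one species.
#' @param seed Integer seed.
#' @return A `"ranked_list"` with `protocol = "random"`.
#' @export
random_order <- function(genomes, seed) {
  if (nrow(genomes) == 0L) stop("no genomes collected for species")
  sp <- unique(genomes$species)
  accs <- with_seed(seed, sample(genomes$accession))
  structure(list(species = sp[1], accessions = accs,
                 provenance = rep("random", length(accs)),
                 protocol = "random", seed = as.integer(seed)),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list for %s (%s): %d genomes\n", x$species, x$protocol,
              length(x$accessions)))
  invisible(x)
}

#' Rank every species of a release
#'
#' Convenience driver: splits a metadata table by species and applies
#' [rank_species()] (or [random_order()]) to each.
#'
#' @param metadata Full metadata table.
#' @param distances Named list (species to distance table), or `NULL`.
#' @param protocol `"ranked"` or `"random"`.
#' @param seed Seed for the random protocol.
#' @return Named list of `"ranked_list"` objects keyed by species.
#' @export
rank_all_species <- function(metadata, distances = NULL,
                             protocol = c("ranked", "random"), seed = 1L) {
  protocol <- match.arg(protocol)
  out <- list()
  for (sp in sort(unique(metadata$species))) {
    rows <- metadata[metadata$species == sp, , drop = FALSE]
    out[[sp]] <- if (protocol == "ranked") {
      rank_species(rows, distances[[sp]])
    } else {
      random_order(rows, seed + match(sp, sort(unique(metadata$species))))
    }
  }
  out
}

#' Read and write ranked lists
#'
#' Tab format with `#key value` header lines (species, protocol, seed)
#' followed by `rank`, `accession`, `provenance` columns.
#'
#' @param x A `"ranked_list"`.
#' @param file Path.
#' @export
write_ranked_list <- function(x, file) {
  header <- c(paste0("#species\t", x$species),
              paste0("#protocol\t", x$protocol),
              paste0("#seed\t", ifelse(is.na(x$seed), "NA", x$seed)))
  rows <- sprintf("%d\t%s\t%s", seq_along(x$accessions), x$accessions,
                  x$provenance)
  writeLines(c(header, "rank\taccession\tprovenance", rows), file)
  invisible(file)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t"))
  meta <- setNames(kv[, 2], kv[, 1])
  body <- lines[!startsWith(lines, "#")][-1]
  parts <- if (length(body)) do.call(rbind, strsplit(body, "\t")) else
    matrix(character(), ncol = 3)
  seed <- if (identical(unname(meta["seed"]), "NA")) NA_integer_ else
    as.integer(meta["seed"])
  structure(list(species = unname(meta["species"]),
                 accessions = as.character(parts[, 2]),
                 provenance = as.character(parts[, 3]),
                 protocol = unname(meta["protocol"]), seed = seed),
            class = "ranked_list")
}
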