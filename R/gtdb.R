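#' Parse a seven-rank taxonomy string
#'
#' Splits a GTDB-style taxonomy string
#' (`"d__...;p__...;c__...;o__...;f__...;g__...;s__..."`) into a named
#' lineage.  Exactly seven fields are required, in rank order from domain to
#' species, each carrying its standard rank prefix.
#'
#' @param x A single taxonomy string.
#' @return A named character vector of class `"lineage"` with elements
#'   `domain`, `phylum`, `class`, `order`, `family`, `genus`, `species`
#'   (prefixes stripped, whitespace trimmed).
#' @examples
#' lin <- parse_lineage(paste0(
#'   "d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;",
#'   "o__Enterobacterales;f__Enterobacteriaceae;g__Escherichia;",
#'   "s__Escherichia flexneri"))
#' lin[["species"]]
#' @export
parse_lineage <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  if (length(parts) != 7L) {
    stop("taxonomy string must have exactly 7 ';'-separated fields, got ",
         length(parts), ": ", x)
  }
  parts <- trimws(parts)
  out <- character(7)
  for (i in seq_len(7)) {
    pre <- .rank_prefixes[i]
    if (!startsWith(parts[i], pre)) {
      stop("field ", i, " (", .ranks[i], ") must start with '", pre,
           "', got: '", parts[i], "'")
    }
    out[i] <- trimws(substring(parts[i], nchar(pre) + 1L))
  }
  structure(setNames(out, .ranks), class = "lineage")
}

#' @rdname parse_lineage
#' @param lineage A lineage as returned by [parse_lineage()] (any named
#'   vector/list with the seven rank names works).
#' @export
format_lineage <- function(lineage) {
  paste0(.rank_prefixes, unlist(lineage)[.ranks], collapse = ";")
}

#' @export
format.lineage <- function(x, ...) format_lineage(x)

#' @export
print.lineage <- function(x, ...) {
  cat(format_lineage(x), "\n")
  invisible(x)
}

#' Read a genome metadata table
#'
#' Parses a GTDB-style metadata TSV into one record per assembly: accession,
#' the seven taxonomy ranks, MIMAG quality tier, contig count, the
#' species-representative flag and genome size.  Column names are
#' configurable through `col_map`; missing quality cells map to
#' `"missing"`.  Rows without a parseable accession are dropped and their
#' count reported via the `"n_rejected"` attribute.
#'
#' @param file Path or connection to a tab-separated table with a header.
#' @param col_map Named character vector mapping the required logical fields
#'   (`accession`, `taxonomy`, `mimag_quality`, `contig_count`,
#'   `representative`, `genome_size`) to column names in the file.
#' @return A data frame with columns `accession`, `domain` ... `species`,
#'   `mimag_quality`, `contig_count`, `is_representative`, `genome_size_bp`.
#' @export
parse_metadata_table <- function(file,
                                 col_map = c(accession = "accession",
                                             taxonomy = "gtdb_taxonomy",
                                             mimag_quality = "mimag_quality",
                                             contig_count = "contig_count",
                                             representative = "gtdb_representative",
                                             genome_size = "genome_size")) {
  needed <- c("accession", "taxonomy", "mimag_quality", "contig_count",
              "representative", "genome_size")
  missing_map <- setdiff(needed, names(col_map))
  if (length(missing_map)) {
    stop("col_map must name columns for: ", paste(missing_map, collapse = ", "))
  }
  raw <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(unname(col_map[needed]), names(raw))
  if (length(absent)) {
    stop("metadata table is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  acc <- trimws(as.character(raw[[col_map[["accession"]]]]))
  bad <- is.na(acc) | acc == ""
  n_rejected <- sum(bad)
  if (n_rejected) {
    message(n_rejected, " metadata row(s) rejected for unparseable accession")
    raw <- raw[!bad, , drop = FALSE]
    acc <- acc[!bad]
  }
  if (anyDuplicated(acc)) {
    dups <- unique(acc[duplicated(acc)])
    stop("duplicate accession(s) in metadata table: ",
         paste(dups, collapse = ", "))
  }
  lin <- t(vapply(raw[[col_map[["taxonomy"]]]],
                  function(s) unclass(parse_lineage(s)),
                  character(7), USE.NAMES = FALSE))
  colnames(lin) <- .ranks
  qual <- tolower(trimws(as.character(raw[[col_map[["mimag_quality"]]]])))
  qual[is.na(qual) | qual == "" | !(qual %in% .quality_levels)] <- "missing"
  contig <- suppressWarnings(as.integer(raw[[col_map[["contig_count"]]]]))
  rep_raw <- tolower(trimws(as.character(raw[[col_map[["representative"]]]])))
  is_rep <- rep_raw %in% c("t", "true", "1", "yes")
  gsize <- suppressWarnings(as.numeric(raw[[col_map[["genome_size"]]]]))
  gsize[is.na(gsize)] <- 0
  out <- data.frame(accession = acc, lin,
                    mimag_quality = qual,
                    contig_count = contig,
                    is_representative = is_rep,
                    genome_size_bp = gsize,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Parse a Newick species tree
#'
#' Thin wrapper around [ape::read.tree()] that checks parenthesis balance
#' (reporting the character position of the first imbalance), defaults
#' absent or missing branch lengths to 0 with a warning, and tags the tree
#' with an optional domain label.  Leaves are species labels.
#'
#' @param text Newick text, or a path to a file containing it.
#' @param domain Optional domain tag (`"Bacteria"` or `"Archaea"`) stored as
#'   the `"domain"` attribute.
#' @return An [ape::phylo] object.
#' @export
parse_newick <- function(text, domain = NULL) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- paste(text, collapse = "")
  if (!nzchar(trimws(text))) stop("empty Newick string")
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at position ", i, " in Newick string")
  }
  if (depth != 0L) stop("unbalanced '(' in Newick string (", depth,
                        " unclosed at end)")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  n_edge <- nrow(tree$edge)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all ", n_edge, " set to 0")
    tree$edge.length <- rep(0, n_edge)
  } else if (anyNA(tree$edge.length)) {
    n_na <- sum(is.na(tree$edge.length))
    warning(n_na, " branch length(s) absent; set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (!is.null(domain)) attr(tree, "domain") <- domain
  tree
}

.check_leaf <- function(tree, label) {
  if (!(label %in% tree$tip.label)) {
    stop("leaf '", label, "' not found in tree")
  }
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path between two leaves of a
#' species tree, in the tree's branch-length units (substitutions per site
#' for GTDB trees).  Zero iff the two labels are identical.
#'
#' @param tree An [ape::phylo] tree.
#' @param a,b Leaf labels.
#' @export
patristic_distance <- function(tree, a, b) {
  .check_leaf(tree, a)
  .check_leaf(tree, b)
  if (a == b) return(0)
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  len <- 0
  for (i in seq_len(length(path) - 1L)) {
    k1 <- paste(path[i], path[i + 1L])
    k2 <- paste(path[i + 1L], path[i])
    j <- match(k1, edge_key)
    if (is.na(j)) j <- match(k2, edge_key)
    len <- len + tree$edge.length[j]
  }
  len
}

#' All-pairs leaf distance matrix
#'
#' Patristic distances between every pair of leaves, as a symmetric matrix
#' with leaf labels as dimnames.  Used internally wherever many distances
#' are needed at once.
#'
#' @param tree An [ape::phylo] tree.
#' @export
species_distance_matrix <- function(tree) {
  if (length(tree$tip.label) == 1L) {
    m <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(m)
  }
  stats::cophenetic(tree)
}

#' Neighbouring species within the taxonomic order
#'
#' All other species sharing the target species' order, sorted by ascending
#' patristic distance on the species tree.  Ties are broken first in favour
#' of species in the target's family, then lexicographically, so designs
#' built from the result are reproducible.  Species from outside the order
#' are never returned.
#'
#' @param tree Species tree whose leaves are species labels.
#' @param lineages A lineage table: data frame with one row per species and
#'   columns `species`, `genus`, `family`, `order` (a metadata table from
#'   [parse_metadata_table()] also works).
#' @param target Target species label.
#' @param dist_matrix Optional precomputed [species_distance_matrix()].
#' @return Data frame with columns `species` and `distance`, nearest first.
#' @export
neighbor_species <- function(tree, lineages, target, dist_matrix = NULL) {
  .check_leaf(tree, target)
  lineages <- unique(lineages[, intersect(c("species", "genus", "family",
                                            "order"), names(lineages))])
  row <- lineages[lineages$species == target, , drop = FALSE]
  if (nrow(row) == 0L) stop("species '", target, "' not in lineage table")
  same_order <- lineages$species[lineages$order == row$order[1]]
  cand <- setdiff(intersect(same_order, tree$tip.label), target)
  if (length(cand) == 0L) {
    return(data.frame(species = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(dist_matrix)) dist_matrix <- species_distance_matrix(tree)
  d <- dist_matrix[target, cand]
  fam <- lineages$family[match(cand, lineages$species)]
  same_family <- fam == row$family[1]
  ord <- order(d, !same_family, cand)
  data.frame(species = cand[ord], distance = unname(d[ord]),
             stringsAsFactors = FALSE)
}

#' Prune a species tree to a set of leaves
#'
#' Drops all leaves not in `keep`, collapsing unary nodes and summing their
#' branch lengths, so patristic distances among the kept leaves are
#' preserved exactly.
#'
#' @param tree An [ape::phylo] tree.
#' @param keep Character vector of leaf labels to retain (subset of the
#'   tree's leaves).
#' @export
pare_tree <- function(tree, keep) {
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(keep) == 0L) stop("keep must contain at least one leaf")
  dom <- attr(tree, "domain")
  if (length(keep) == 1L) {
    out <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = keep, edge.length = 0, Nnode = 1L),
                     class = "phylo")
  } else {
    out <- ape::keep.tip(tree, keep)
  }
  if (!is.null(dom)) attr(out, "domain") <- dom
  out
}

#' Deepest shared taxonomic rank of two lineages
#'
#' Returns the deepest rank at which two seven-rank lineages agree,
#' requiring agreement at all shallower ranks as well (a lineage-prefix
#' match).  `"none"` if even the domains differ.
#'
#' @param a,b Lineages ([parse_lineage()] results, or any named vectors with
#'   the seven rank names).
#' @return One of `"species"`, `"genus"`, `"family"`, `"order"`, `"class"`,
#'   `"phylum"`, `"domain"`, `"none"`.
#' @export
shared_rank <- function(a, b) {
  av <- unlist(a)[.ranks]
  bv <- unlist(b)[.ranks]
  deepest <- "none"
  for (i in seq_along(.ranks)) {
    if (identical(unname(av[i]), unname(bv[i]))) deepest <- .ranks[i] else break
  }
  deepest
}

# Lineage table (one row per species) from a per-genome metadata table.
lineage_table <- function(metadata) {
  unique(metadata[, .ranks, drop = FALSE])
}
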