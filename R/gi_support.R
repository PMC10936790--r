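#' Read and write genomic-island call tables
#'
#' Tab-separated with a header; one row per GI call with columns `gi_id`,
#' `query_accession`, `query_species`, `contig`, `start`, `end`
#' (1-based inclusive), `length_bp`, `type`,
#' `has_ser_or_tyr_integrase`, `flank_identity_block_bp`, `is_tandem` and
#' `supporters` (comma-joined accessions; empty for unsupported calls).
#' In memory, `supporters` is a list column of character vectors.
#'
#' @param gis GI table (data frame as above).
#' @param file Path.
#' @export
write_gi_table <- function(gis, file) {
  out <- gis
  out$supporters <- vapply(gis$supporters, paste, character(1), collapse = ",")
  out$has_ser_or_tyr_integrase <- ifelse(gis$has_ser_or_tyr_integrase, "T", "F")
  out$is_tandem <- ifelse(gis$is_tandem, "T", "F")
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_gi_table
#' @export
read_gi_table <- function(file) {
  raw <- read.delim(file, stringsAsFactors = FALSE,
                    colClasses = c(supporters = "character",
                                   contig = "character"))
  raw$has_ser_or_tyr_integrase <- raw$has_ser_or_tyr_integrase %in% c("T", "TRUE", "t", "true")
  raw$is_tandem <- raw$is_tandem %in% c("T", "TRUE", "t", "true")
  raw$supporters[is.na(raw$supporters)] <- ""
  raw$supporters <- lapply(strsplit(raw$supporters, ",", fixed = TRUE),
                           function(x) x[nzchar(x)])
  bad <- !is.na(raw$start) & !is.na(raw$end) &
    raw$length_bp != raw$end - raw$start + 1L
  if (any(bad)) {
    stop("length_bp inconsistent with end - start + 1 for: ",
         paste(raw$gi_id[bad], collapse = ", "))
  }
  raw
}

#' Classify GI calls as Rejects
#'
#' A call is a Reject — a putative false positive — if any of three
#' clauses holds: size below 5 kbp, no serine or tyrosine integrase
#' candidate, or an identity block longer than 300 bp between its left
#' and right integration sites.
#'
#' @param gis GI table (or any data frame with `length_bp`,
#'   `has_ser_or_tyr_integrase`, `flank_identity_block_bp`).
#' @return Logical vector, one per call.
#' @export
classify_reject <- function(gis) {
  gis$length_bp < 5000 |
    !gis$has_ser_or_tyr_integrase |
    gis$flank_identity_block_bp > 300
}

#' Filter GI calls for support analysis
#'
#' Drops calls in tandem arrays (their support values are depressed by the
#' abutting island) and calls with no support at all, reporting the number
#' dropped for each reason.
#'
#' @param gis GI table.
#' @return List with `retained` (the filtered table) and `dropped`
#'   (named counts: `tandem`, `no_support`).
#' @export
filter_calls <- function(gis) {
  n_support <- lengths(gis$supporters)
  tandem <- gis$is_tandem
  no_support <- !tandem & n_support == 0L
  retained <- gis[!tandem & n_support > 0L, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       dropped = c(tandem = sum(tandem), no_support = sum(no_support)))
}

#' Select large island-rich species
#'
#' Species qualifying for large-species analyses: more than 300 genomes,
#' more than 100 calls of each of the three main island types (Phage1,
#' NonPI, Reject), and more than 1000 calls total over those three types.
#' All four thresholds are strict.
#'
#' @param counts Data frame with columns `species`, `n_genomes`,
#'   `n_phage1`, `n_nonpi`, `n_reject`.
#' @return Character vector of qualifying species.
#' @export
select_large_species <- function(counts) {
  ok <- counts$n_genomes > 300 &
    counts$n_phage1 > 100 & counts$n_nonpi > 100 & counts$n_reject > 100 &
    (counts$n_phage1 + counts$n_nonpi + counts$n_reject) > 1000
  counts$species[ok]
}

#' Tally per-species GI and genome counts
#'
#' Helper producing the input of [select_large_species()] from a filtered
#' GI table and a metadata table.
#'
#' @param gis Filtered GI table.
#' @param metadata Metadata table.
#' @export
tally_species_counts <- function(gis, metadata) {
  sp <- sort(unique(metadata$species))
  cnt <- function(s, type) sum(gis$query_species == s & gis$type == type)
  data.frame(species = sp,
             n_genomes = vapply(sp, function(s)
               sum(metadata$species == s), integer(1)),
             n_phage1 = vapply(sp, cnt, integer(1), type = "Phage1"),
             n_nonpi = vapply(sp, cnt, integer(1), type = "NonPI"),
             n_reject = vapply(sp, cnt, integer(1), type = "Reject"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' GI recovery over nested database sizes
#'
#' For each database size `n`, the test database is the first `n` genomes
#' of an ordered list (ranked or random protocol); a GI is recovered iff at
#' least one of its supporters is in the test database.  Reports the mean
#' recovered GI count per query genome, by type.  Nested test databases
#' make the curve non-decreasing, saturating at the per-genome retained
#' count when the full list is used.
#'
#' @param gis Filtered GI table.
#' @param genome_list Ordered accessions (a `"ranked_list"` or character
#'   vector).
#' @param sizes Ascending database sizes, each at most the list length.
#' @return Data frame with columns `size`, `type`, `mean_recovered`;
#'   protocol and seed (when `genome_list` is a `"ranked_list"`) in
#'   attributes.
#' @export
recovery_curve <- function(gis, genome_list, sizes) {
  protocol <- if (inherits(genome_list, "ranked_list")) genome_list$protocol
              else NA_character_
  seed <- if (inherits(genome_list, "ranked_list")) genome_list$seed
          else NA_integer_
  accs <- .ranked_accessions(genome_list)
  sizes <- sort(as.integer(sizes))
  if (any(sizes > length(accs))) {
    stop("requested DB size exceeds genome list length (",
         length(accs), ")")
  }
  n_query <- length(unique(gis$query_accession))
  # earliest list position among each GI's supporters; Inf if none present
  minpos <- vapply(gis$supporters, function(s) {
    p <- match(s, accs)
    if (all(is.na(p))) Inf else min(p, na.rm = TRUE)
  }, numeric(1))
  types <- sort(unique(gis$type))
  out <- expand.grid(size = sizes, type = types, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$mean_recovered <- mapply(function(sz, ty)
    sum(minpos <= sz & gis$type == ty) / n_query, out$size, out$type)
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- seed
  out
}

.rank_depth <- setNames(seq_along(.ranks), .ranks)  # domain=1 .. species=7

# depth of the deepest shared rank between a query lineage row and
# supporter species, via species-level lineage prefix comparison
.shared_depth <- function(lin_a, lin_b) {
  agree <- unlist(lin_a)[.ranks] == unlist(lin_b)[.ranks]
  if (!agree[1]) return(0L)
  w <- which(!agree)
  if (length(w) == 0L) 7L else w[1] - 1L
}

#' Fractional GI yields under taxonomic omission
#'
#' Simulates small species by removing, for each GI, all supporters from
#' the same species as the query, or the same genus, family or order; the
#' GI survives an omission rank if at least one supporter remains.  GIs
#' evaluated against databases whose own taxonomic scope is at or within
#' the omitted rank are excluded from that rank's denominator (e.g. GIs
#' from family-limited databases lose all supporters trivially at family
#' omission, so they are excluded from the family- and order-omission
#' denominators).
#'
#' @param gis Filtered GI table.
#' @param lineages Lineage table (one row per species, seven ranks).
#' @param genome_species Named character vector: accession to species, for
#'   supporters.
#' @param db_scopes Taxonomic scope of each GI's evaluation database: a
#'   single rank name recycled for all GIs, or a named vector keyed by
#'   `gi_id` (values among `genus`, `family`, `order`, `class`, `phylum`,
#'   `domain`).
#' @return Data frame with columns `rank`, `type`, `numerator`,
#'   `denominator`, `yield`.
#' @export
omission_yields <- function(gis, lineages, genome_species,
                            db_scopes = "domain") {
  lineages <- unique(lineages[, .ranks, drop = FALSE])
  lin_of <- function(sp) lineages[match(sp, lineages$species), , drop = FALSE]
  scopes <- if (length(db_scopes) == 1L && is.null(names(db_scopes))) {
    setNames(rep(db_scopes, nrow(gis)), gis$gi_id)
  } else db_scopes
  scope_depth <- .rank_depth[unname(scopes[gis$gi_id])]
  omit_ranks <- c("species", "genus", "family", "order")
  n_warned <- 0L
  # deepest shared depth between query species and each supporter
  deepest <- lapply(seq_len(nrow(gis)), function(i) {
    ql <- lin_of(gis$query_species[i])
    supp_sp <- unname(genome_species[gis$supporters[[i]]])
    vapply(supp_sp, function(sp) {
      if (is.na(sp) || is.na(match(sp, lineages$species))) {
        n_warned <<- n_warned + 1L
        return(0L)  # unknown lineage: treated as out-of-rank, kept
      }
      .shared_depth(ql, lin_of(sp))
    }, integer(1))
  })
  if (n_warned > 0L) {
    warning(n_warned, " supporter(s) with unknown lineage treated as ",
            "outside every omitted rank")
  }
  types <- sort(unique(gis$type))
  rows <- list()
  for (r in omit_ranks) {
    rd <- .rank_depth[[r]]
    in_denom <- scope_depth < rd  # DB scope strictly broader than omitted rank
    survives <- vapply(deepest, function(d) any(d < rd), logical(1))
    for (ty in types) {
      sel <- gis$type == ty & in_denom
      rows[[length(rows) + 1L]] <- data.frame(
        rank = r, type = ty,
        numerator = sum(sel & survives),
        denominator = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$yield <- ifelse(out$denominator > 0, out$numerator / out$denominator,
                      NA_real_)
  out
}

#' Support-origin fractions by GI type
#'
#' Partitions each GI by where its supporters come from relative to the
#' query genome's species: only outside the species, only inside, or
#' mixed.  Per type, the three fractions sum to 1.
#'
#' @param gis Filtered GI table (every call has at least one supporter).
#' @param genome_species Named character vector: accession to species.
#' @return Data frame with columns `type`, `n`, `only_outside`,
#'   `only_inside`, `mixed`.
#' @export
support_origin_fractions <- function(gis, genome_species) {
  cls <- vapply(seq_len(nrow(gis)), function(i) {
    supp_sp <- unname(genome_species[gis$supporters[[i]]])
    inside <- supp_sp == gis$query_species[i]
    inside[is.na(inside)] <- FALSE
    if (all(inside)) "only_inside"
    else if (!any(inside)) "only_outside"
    else "mixed"
  }, character(1))
  types <- sort(unique(gis$type))
  out <- data.frame(type = types,
                    n = vapply(types, function(ty) sum(gis$type == ty),
                               integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (k in c("only_outside", "only_inside", "mixed")) {
    out[[k]] <- vapply(types, function(ty) {
      n <- sum(gis$type == ty)
      if (n == 0) NA_real_ else sum(cls == k & gis$type == ty) / n
    }, numeric(1))
  }
  out
}

.profile_breaks <- function(n_bins = 50, upper = 3.7) {
  seq(0, upper, length.out = n_bins + 1L)
}

# vectorised genome-to-genome species distance: 0 within a species,
# patristic distance between species representatives otherwise
.genome_distances <- function(query_sp, other_sp, dmat) {
  d <- numeric(length(other_sp))
  same <- other_sp == query_sp
  d[same] <- 0
  if (any(!same)) d[!same] <- dmat[query_sp, other_sp[!same]]
  d
}

#' Actual/possible support decay over tree distance
#'
#' For each GI, every genome of its evaluation database is a possible
#' supporter; the distance from the query genome to each is 0 within the
#' species and otherwise the patristic distance between the two species on
#' the species tree.  Possible and actual supporter counts are summed by
#' type into 50 bins spanning \[0, 3.7) substitutions per site, and each
#' bin's ratio actual/possible is reported (`NA` where a bin holds no
#' possible pairs).  Distances at or beyond 3.7 are dropped, with the
#' dropped count reported in the `"n_dropped"` attribute.
#'
#' @param gis Filtered GI table.
#' @param tree Species tree covering every involved species.
#' @param genome_species Named character vector: accession to species.
#' @param possible Possible-supporter sets: a character vector of
#'   accessions applying to every GI, or a named list keyed by `gi_id`.
#' @return Data frame with columns `type`, `bin`, `lo`, `hi`,
#'   `possible`, `actual`, `ratio`.
#' @export
support_decay_profile <- function(gis, tree, genome_species, possible) {
  breaks <- .profile_breaks()
  width <- breaks[2]
  n_bins <- length(breaks) - 1L
  dmat <- species_distance_matrix(tree)
  types <- sort(unique(gis$type))
  poss_tab <- matrix(0, nrow = n_bins, ncol = length(types),
                     dimnames = list(NULL, types))
  act_tab <- poss_tab
  n_dropped <- 0
  for (i in seq_len(nrow(gis))) {
    poss <- if (is.list(possible)) possible[[gis$gi_id[i]]] else possible
    poss <- setdiff(poss, gis$query_accession[i])
    supp <- gis$supporters[[i]]
    extra <- setdiff(supp, poss)
    if (length(extra)) {
      stop("GI '", gis$gi_id[i], "' has supporter(s) outside its possible ",
           "set: ", paste(extra, collapse = ", "))
    }
    qsp <- gis$query_species[i]
    d_poss <- .genome_distances(qsp, unname(genome_species[poss]), dmat)
    d_act <- .genome_distances(qsp, unname(genome_species[supp]), dmat)
    keep_p <- d_poss < breaks[length(breaks)]
    keep_a <- d_act < breaks[length(breaks)]
    n_dropped <- n_dropped + sum(!keep_p) + sum(!keep_a)
    ty <- gis$type[i]
    bp <- pmin(floor(d_poss[keep_p] / width) + 1L, n_bins)
    ba <- pmin(floor(d_act[keep_a] / width) + 1L, n_bins)
    if (length(bp)) {
      tb <- tabulate(bp, nbins = n_bins)
      poss_tab[, ty] <- poss_tab[, ty] + tb
    }
    if (length(ba)) {
      tb <- tabulate(ba, nbins = n_bins)
      act_tab[, ty] <- act_tab[, ty] + tb
    }
  }
  out <- expand.grid(bin = seq_len(n_bins), type = types,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("type", "bin")]
  out$lo <- breaks[out$bin]
  out$hi <- breaks[out$bin + 1L]
  out$possible <- poss_tab[cbind(out$bin, match(out$type, types))]
  out$actual <- act_tab[cbind(out$bin, match(out$type, types))]
  out$ratio <- ifelse(out$possible > 0, out$actual / out$possible, NA_real_)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Shared-rank distance histograms for database genome pairs
#'
#' For each genome pair, takes the deepest shared taxonomic rank and the
#' species distance (0 within a species), then tallies distances per rank
#' over the same 50 bins used by [support_decay_profile()]; each rank's
#' trace is normalised to its own maximum count.
#'
#' @param pairs Data frame with columns `accession_a`, `accession_b`.
#' @param tree Species tree.
#' @param lineages Lineage table.
#' @param genome_species Named character vector: accession to species.
#' @return Data frame with columns `rank`, `bin`, `lo`, `hi`, `count`,
#'   `norm`.
#' @export
shared_rank_profile <- function(pairs, tree, lineages, genome_species) {
  breaks <- .profile_breaks()
  width <- breaks[2]
  n_bins <- length(breaks) - 1L
  lineages <- unique(lineages[, .ranks, drop = FALSE])
  dmat <- species_distance_matrix(tree)
  sp_a <- unname(genome_species[pairs$accession_a])
  sp_b <- unname(genome_species[pairs$accession_b])
  ranks_shared <- vapply(seq_len(nrow(pairs)), function(i) {
    la <- lineages[match(sp_a[i], lineages$species), , drop = FALSE]
    lb <- lineages[match(sp_b[i], lineages$species), , drop = FALSE]
    shared_rank(la, lb)
  }, character(1))
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    if (sp_a[i] == sp_b[i]) 0 else dmat[sp_a[i], sp_b[i]]
  }, numeric(1))
  keep <- d < breaks[length(breaks)]
  d <- d[keep]; ranks_shared <- ranks_shared[keep]
  bins <- pmin(floor(d / width) + 1L, n_bins)
  out <- list()
  for (r in unique(ranks_shared)) {
    cnt <- tabulate(bins[ranks_shared == r], nbins = n_bins)
    out[[r]] <- data.frame(rank = r, bin = seq_len(n_bins),
                           lo = breaks[-length(breaks)], hi = breaks[-1],
                           count = cnt,
                           norm = if (max(cnt) > 0) cnt / max(cnt) else NA_real_,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sketch distance versus tree distance
#'
#' Bins genome pairs by species distance (same 50-bin grid) and reports,
#' per bin, the mean sketch distance over pairs within the estimator's
#' reliable range (sketch distance at or below 0.2) and the percentage of
#' pairs that are measurable at all.  Reporting cuts off after tree
#' distance 0.5, beyond which sketch distances have saturated.
#'
#' @param pairs Data frame with columns `accession_a`, `accession_b`,
#'   `sketch_distance`.
#' @param tree Species tree.
#' @param genome_species Named character vector: accession to species.
#' @param reliability_threshold Maximum reliable sketch distance
#'   (default 0.2).
#' @param report_cutoff Suppress bins whose lower edge is at or beyond this
#'   tree distance (default 0.5).
#' @return Data frame with columns `bin`, `lo`, `hi`, `n_pairs`,
#'   `pct_measurable`, `mean_sketch_distance`.
#' @export
sketch_vs_tree_profile <- function(pairs, tree, genome_species,
                                   reliability_threshold = 0.2,
                                   report_cutoff = 0.5) {
  breaks <- .profile_breaks()
  width <- breaks[2]
  n_bins <- length(breaks) - 1L
  dmat <- species_distance_matrix(tree)
  sp_a <- unname(genome_species[pairs$accession_a])
  sp_b <- unname(genome_species[pairs$accession_b])
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    if (sp_a[i] == sp_b[i]) 0 else dmat[sp_a[i], sp_b[i]]
  }, numeric(1))
  keep <- d < breaks[length(breaks)]
  d <- d[keep]
  sk <- pairs$sketch_distance[keep]
  bins <- pmin(floor(d / width) + 1L, n_bins)
  measurable <- sk <= reliability_threshold
  rows <- lapply(seq_len(n_bins), function(b) {
    if (breaks[b] >= report_cutoff) return(NULL)
    sel <- bins == b
    if (!any(sel)) return(NULL)
    data.frame(bin = b, lo = breaks[b], hi = breaks[b + 1L],
               n_pairs = sum(sel),
               pct_measurable = 100 * mean(measurable[sel]),
               mean_sketch_distance = if (any(sel & measurable))
                 mean(sk[sel & measurable]) else NA_real_)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(bin = integer(), lo = numeric(), hi = numeric(),
                      n_pairs = integer(), pct_measurable = numeric(),
                      mean_sketch_distance = numeric())
  }
  rownames(res) <- NULL
  res
}
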