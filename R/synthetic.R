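#' Configuration for synthetic releases
#'
#' Parameters of the synthetic release generator.  Defaults describe a
#' desk-scale release mirroring the shape of real prokaryotic taxonomy
#' releases: a handful of orders per domain, a heavy-tailed genome count
#' per species (most species contribute a single genome, a few contribute
#' many), branch lengths spanning the within-genus to between-order range,
#' and per-type GI support probabilities separated by a 7-fold gap between
#' the reliable prophage-like type and the Reject-like type.
#'
#' @param seed Integer seed; generation is fully determined by it.
#' @param n_orders Bacterial orders.
#' @param n_archaea_orders Archaeal orders.
#' @param mean_species_per_order Mean species per order (at least 1 each).
#' @param p_multi Probability a species has more than one genome.
#' @param mean_extra_genomes Mean extra genomes for multi-genome species
#'   (geometric tail).
#' @param seq_len Genome sequence length in bp (sketch math is
#'   length-agnostic; short genomes keep tests fast).
#' @param within_mut_rate Per-site substitution rate applied per genome on
#'   top of its species sequence.
#' @param gi GI generation parameters: list with `types`, `mean_calls`,
#'   `p0` (support probability at distance 0, per type), `decay`
#'   (exponential decay rate of support probability with tree distance)
#'   and `tandem_frac`.
#' @return A `"fixture_config"` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_orders = 8L,
                           n_archaea_orders = 1L,
                           mean_species_per_order = 12,
                           p_multi = 0.4,
                           mean_extra_genomes = 6,
                           seq_len = 20000L,
                           within_mut_rate = 0.002,
                           gi = list(types = c("Phage1", "NonPI", "Reject"),
                                     mean_calls = c(Phage1 = 2, NonPI = 3,
                                                    Reject = 2),
                                     p0 = c(Phage1 = 0.7, NonPI = 0.35,
                                            Reject = 0.1),
                                     decay = 1.5,
                                     tandem_frac = 0.08)) {
  stopifnot(n_orders >= 1, n_archaea_orders >= 0,
            mean_species_per_order >= 1, p_multi >= 0, p_multi <= 1,
            seq_len >= 100, all(gi$p0 >= 0), all(gi$p0 <= 1),
            gi$tandem_frac >= 0, gi$tandem_frac <= 1)
  structure(list(seed = as.integer(seed), n_orders = as.integer(n_orders),
                 n_archaea_orders = as.integer(n_archaea_orders),
                 mean_species_per_order = mean_species_per_order,
                 p_multi = p_multi, mean_extra_genomes = mean_extra_genomes,
                 seq_len = as.integer(seq_len),
                 within_mut_rate = within_mut_rate, gi = gi),
            class = "fixture_config")
}

.bases <- c("A", "C", "G", "T")

# point-mutate a base vector at the given per-site rate
.mutate <- function(bases, rate) {
  n <- rbinom(1L, length(bases), rate)
  if (n == 0L) return(bases)
  pos <- sample.int(length(bases), n)
  for (p in pos) {
    bases[p] <- sample(setdiff(.bases, bases[p]), 1L)
  }
  bases
}

# taxonomy skeleton for one domain: orders -> families -> genera -> species
.domain_taxonomy <- function(domain_short, domain_name, n_orders,
                             mean_species_per_order) {
  rows <- list()
  for (o in seq_len(n_orders)) {
    ns <- max(1L, rpois(1L, mean_species_per_order - 1) + 1L)
    order_lab <- sprintf("%s-O%02d", domain_short, o)
    n_fam <- sample.int(max(1L, min(4L, ns)), 1L)
    fam_of <- sort(sample.int(n_fam, ns, replace = TRUE))
    for (s in seq_len(ns)) {
      fam_lab <- sprintf("%s-F%d", order_lab, fam_of[s])
      # genera nest inside families: up to 2 per family
      gen_idx <- 1L + (s %% 2L)
      gen_lab <- sprintf("%s-G%d", fam_lab, gen_idx)
      sp_lab <- sprintf("%s-S%02d", gen_lab, s)
      rows[[length(rows) + 1L]] <- data.frame(
        domain = domain_name,
        phylum = sprintf("%s-P%02d", domain_short, ceiling(o / 4)),
        class = sprintf("%s-C%02d", domain_short, ceiling(o / 2)),
        order = order_lab, family = fam_lab, genus = gen_lab,
        species = sp_lab, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# recursive Newick for a monophyletic taxonomy: species tips grouped by
# genus, genera by family, families by order, orders at the root.  Each
# level returns a clade WITHOUT a stem length; the parent join attaches
# stems, so single-child levels collapse cleanly.
.domain_newick <- function(lin) {
  order_clades <- vapply(unique(lin$order), function(o) {
    lo <- lin[lin$order == o, , drop = FALSE]
    fam_clades <- vapply(unique(lo$family), function(f) {
      lf <- lo[lo$family == f, , drop = FALSE]
      gen_clades <- vapply(unique(lf$genus), function(g) {
        sp <- lf$species[lf$genus == g]
        if (length(sp) == 1L) sp
        else clade_txt(sp, runif(length(sp), 0.01, 0.06))
      }, character(1))
      if (length(gen_clades) == 1L) gen_clades
      else clade_txt(gen_clades, runif(length(gen_clades), 0.08, 0.2))
    }, character(1))
    if (length(fam_clades) == 1L) fam_clades
    else clade_txt(fam_clades, runif(length(fam_clades), 0.25, 0.5))
  }, character(1))
  paste0(clade_txt(order_clades, runif(length(order_clades), 0.7, 1.4)), ";")
}

# join already-formatted subclade strings with stem lengths
clade_txt <- function(clades, lens) {
  paste0("(", paste(sprintf("%s:%.6f", clades, lens), collapse = ","), ")")
}

#' Generate a synthetic release
#'
#' Builds, fully determined by the seed: per-domain species trees whose
#' taxonomy is monophyletic at every rank, a lineage table, genome
#' metadata (one designated representative per species, heavy-tailed
#' genome counts, sampled quality tiers and contig counts) and — unless
#' `with_sequences = FALSE` — genome sequences evolved from a per-domain
#' root sequence along the taxonomy with additional within-species point
#' mutations, so that sketch distances correlate with planted divergence.
#'
#' @param config A [fixture_config()].
#' @param with_sequences Generate genome sequences (set `FALSE` for
#'   design-only tests; sequence evolution dominates the run time).
#' @return A `"smartdb_release"`: list with `trees` (named by domain),
#'   `lineages`, `metadata`, `sequences` (named list of character vectors,
#'   or `NULL`), `config`.
#' @export
generate_release <- function(config = fixture_config(),
                             with_sequences = TRUE) {
  with_seed(config$seed, {
    doms <- list()
    if (config$n_orders >= 1) {
      doms[["Bacteria"]] <- list(short = "B", n_orders = config$n_orders)
    }
    if (config$n_archaea_orders >= 1) {
      doms[["Archaea"]] <- list(short = "A",
                                n_orders = config$n_archaea_orders)
    }
    lineages <- list()
    trees <- list()
    for (dn in names(doms)) {
      lin <- .domain_taxonomy(doms[[dn]]$short, dn, doms[[dn]]$n_orders,
                              config$mean_species_per_order)
      # a domain tree needs at least two leaves
      if (nrow(lin) < 2L) {
        lin <- rbind(lin, within(lin[1, ], {
          species <- paste0(species, "b")
        }))
      }
      lineages[[dn]] <- lin
      trees[[dn]] <- parse_newick(.domain_newick(lin), domain = dn)
    }
    lineages <- do.call(rbind, lineages)
    rownames(lineages) <- NULL

    meta <- list()
    for (i in seq_len(nrow(lineages))) {
      sp <- lineages$species[i]
      n_extra <- if (runif(1) < config$p_multi)
        rgeom(1L, 1 / config$mean_extra_genomes) + 1L else 0L
      n <- 1L + n_extra
      accs <- sprintf("GCA_%s_%03d", sp, seq_len(n))
      meta[[sp]] <- data.frame(
        accession = accs,
        lineages[rep(i, n), , drop = FALSE],
        mimag_quality = sample(.quality_levels, n, replace = TRUE,
                               prob = c(0.45, 0.3, 0.2, 0.05)),
        contig_count = sample.int(300L, n, replace = TRUE),
        is_representative = seq_len(n) == 1L,
        genome_size_bp = as.numeric(config$seq_len),
        stringsAsFactors = FALSE)
    }
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL

    sequences <- NULL
    if (with_sequences) {
      sequences <- list()
      for (dn in names(doms)) {
        root <- sample(.bases, config$seq_len, replace = TRUE)
        lin <- lineages[lineages$domain == dn, , drop = FALSE]
        for (o in unique(lin$order)) {
          o_seq <- .mutate(root, 0.10)
          lo <- lin[lin$order == o, , drop = FALSE]
          for (f in unique(lo$family)) {
            f_seq <- .mutate(o_seq, 0.05)
            lf <- lo[lo$family == f, , drop = FALSE]
            for (g in unique(lf$genus)) {
              g_seq <- .mutate(f_seq, 0.025)
              for (sp in lf$species[lf$genus == g]) {
                sp_seq <- .mutate(g_seq, 0.012)
                for (acc in metadata$accession[metadata$species == sp]) {
                  scale <- 1 + rpois(1L, 2L)
                  gseq <- .mutate(sp_seq, config$within_mut_rate * scale)
                  sequences[[acc]] <- setNames(paste(gseq, collapse = ""),
                                               acc)
                }
              }
            }
          }
        }
      }
    }
    structure(list(trees = trees, lineages = lineages, metadata = metadata,
                   sequences = sequences, config = config),
              class = "smartdb_release")
  })
}

#' @export
print.smartdb_release <- function(x, ...) {
  cat(sprintf("smartdb_release (seed %d): %d species, %d genomes, %d domain(s)%s\n",
              x$config$seed, nrow(x$lineages), nrow(x$metadata),
              length(x$trees),
              if (is.null(x$sequences)) ", no sequences" else ""))
  invisible(x)
}

#' Accession-to-species map of a release
#'
#' @param release A `"smartdb_release"` (or any metadata table).
#' @export
genome_species_map <- function(release) {
  md <- if (inherits(release, "smartdb_release")) release$metadata else release
  setNames(md$species, md$accession)
}

#' Generate synthetic GI calls for a release
#'
#' For each query genome, draws a Poisson number of GI calls per type.
#' Each call's supporters are drawn from all other genomes of the query's
#' domain, with per-genome probability `p0[type] * exp(-decay * d)` where
#' `d` is the species tree distance to the query's species (0 within the
#' species), planting the configured decay and per-type mean-support gaps.
#' Reject-type calls receive attributes violating at least one Reject
#' clause; all other types receive compliant attributes.  A configurable
#' fraction is flagged tandem.
#'
#' @param release A `"smartdb_release"`.
#' @param seed Seed (defaults to the release seed + 1).
#' @param queries Accessions to use as query genomes (default: all).
#' @return A GI table (see [read_gi_table()]) with list-column
#'   `supporters`.
#' @export
generate_gi_calls <- function(release, seed = release$config$seed + 1L,
                              queries = release$metadata$accession) {
  gi_cfg <- release$config$gi
  md <- release$metadata
  gsp <- genome_species_map(release)
  dmats <- lapply(release$trees, species_distance_matrix)
  with_seed(seed, {
    rows <- list()
    idx <- 0L
    for (q in queries) {
      qi <- match(q, md$accession)
      qsp <- md$species[qi]
      qdom <- md$domain[qi]
      pool_acc <- md$accession[md$domain == qdom & md$accession != q]
      pool_sp <- gsp[pool_acc]
      d <- .genome_distances(qsp, unname(pool_sp), dmats[[qdom]])
      for (ty in gi_cfg$types) {
        n_calls <- rpois(1L, gi_cfg$mean_calls[[ty]])
        if (n_calls == 0L) next
        p <- pmin(1, gi_cfg$p0[[ty]] * exp(-gi_cfg$decay * d))
        for (k in seq_len(n_calls)) {
          idx <- idx + 1L
          supp <- pool_acc[runif(length(p)) < p]
          if (identical(ty, "Reject")) {
            v <- sample.int(3L, 1L)
            len <- if (v == 1L) sample(500:4999, 1L) else sample(8000:60000, 1L)
            integrase <- v != 2L
            flank <- if (v == 3L) sample(301:2000, 1L) else sample(0:300, 1L)
          } else {
            len <- sample(8000:60000, 1L)
            integrase <- TRUE
            flank <- sample(0:300, 1L)
          }
          start <- sample.int(1000000L, 1L)
          rows[[idx]] <- data.frame(
            gi_id = sprintf("GI%06d", idx),
            query_accession = q, query_species = qsp, contig = "c1",
            start = start, end = start + len - 1L, length_bp = len,
            type = ty, has_ser_or_tyr_integrase = integrase,
            flank_identity_block_bp = flank,
            is_tandem = runif(1) < gi_cfg$tandem_frac,
            stringsAsFactors = FALSE)
          rows[[idx]]$supporters <- list(supp)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write and read a release on disk
#'
#' Writes a release in the formats the pipeline reads — per-domain Newick
#' trees (`tree_<domain>.nwk`), a metadata TSV with GTDB-style taxonomy
#' strings, and one FASTA per genome under `genomes/` — and reads it back
#' through the package's own parsers.
#'
#' @param release A `"smartdb_release"`.
#' @param dir Directory to write into (created if needed).
#' @export
write_release <- function(release, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (dn in names(release$trees)) {
    ape::write.tree(release$trees[[dn]],
                    file.path(dir, paste0("tree_", dn, ".nwk")))
  }
  md <- release$metadata
  tax <- vapply(seq_len(nrow(md)), function(i)
    paste0(.rank_prefixes, unlist(md[i, .ranks]), collapse = ";"),
    character(1))
  tab <- data.frame(accession = md$accession, gtdb_taxonomy = tax,
                    mimag_quality = md$mimag_quality,
                    contig_count = md$contig_count,
                    gtdb_representative = ifelse(md$is_representative, "t", "f"),
                    genome_size = md$genome_size_bp,
                    stringsAsFactors = FALSE)
  write.table(tab, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(release$sequences)) {
    gdir <- file.path(dir, "genomes")
    dir.create(gdir, showWarnings = FALSE)
    for (acc in names(release$sequences)) {
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(release$sequences[[acc]]),
        file.path(gdir, paste0(acc, ".fna")))
    }
  }
  invisible(dir)
}

#' @rdname write_release
#' @export
read_release <- function(dir) {
  tree_files <- list.files(dir, pattern = "^tree_.*\\.nwk$", full.names = TRUE)
  trees <- list()
  for (f in tree_files) {
    dn <- sub("^tree_(.*)\\.nwk$", "\\1", basename(f))
    trees[[dn]] <- parse_newick(f, domain = dn)
  }
  metadata <- parse_metadata_table(file.path(dir, "metadata.tsv"))
  gdir <- file.path(dir, "genomes")
  sequences <- NULL
  if (dir.exists(gdir)) {
    files <- list.files(gdir, pattern = "\\.fna$", full.names = TRUE)
    sequences <- lapply(files, function(f)
      as.character(Biostrings::readDNAStringSet(f)))
    names(sequences) <- sub("\\.fna$", "", basename(files))
  }
  structure(list(trees = trees, lineages = lineage_table(metadata),
                 metadata = metadata, sequences = sequences, config = NULL),
            class = "smartdb_release")
}

#' Deterministic test scenarios
#'
#' Hand-constructed presets with verifiable expected outputs:
#' \describe{
#'   \item{`tiny-order`}{A species alone in a 3-genome order, whose
#'     database cannot grow: triggers the very-small-DB report.}
#'   \item{`shared-composition`}{Two small species exhausting the same
#'     order: both provably map to the same database.}
#'   \item{`big-species`}{A species with more genomes than the cap: its
#'     database is its own ranked prefix, no donors.}
#'   \item{`decay-demo`}{A seeded release plus GI calls with strongly
#'     distance-decaying planted support, for profiling.}
#' }
#'
#' @param name Scenario name.
#' @return List with `release`, `gis` (or `NULL`), `expected` and `cap`.
#' @export
scenario <- function(name = c("tiny-order", "shared-composition",
                              "big-species", "decay-demo")) {
  name <- match.arg(name)
  hand_release <- function(sp_orders, n_genomes, newick) {
    lin <- do.call(rbind, lapply(seq_along(sp_orders), function(i) {
      sp <- names(sp_orders)[i]
      data.frame(domain = "Bacteria", phylum = "P01", class = "C01",
                 order = sp_orders[[i]], family = paste0(sp_orders[[i]], "-F1"),
                 genus = paste0(sp_orders[[i]], "-G1"), species = sp,
                 stringsAsFactors = FALSE)
    }))
    md <- do.call(rbind, lapply(names(n_genomes), function(sp) {
      n <- n_genomes[[sp]]
      data.frame(accession = sprintf("GCA_%s_%03d", sp, seq_len(n)),
                 lin[rep(match(sp, lin$species), n), , drop = FALSE],
                 mimag_quality = rep_len(c("high", "medium", "low"), n),
                 contig_count = seq_len(n) * 3L,
                 is_representative = seq_len(n) == 1L,
                 genome_size_bp = 1e6, stringsAsFactors = FALSE)
    }))
    rownames(md) <- NULL
    structure(list(trees = list(Bacteria = parse_newick(newick,
                                                        domain = "Bacteria")),
                   lineages = lin, metadata = md, sequences = NULL,
                   config = NULL),
              class = "smartdb_release")
  }
  switch(name,
    "tiny-order" = {
      rel <- hand_release(
        sp_orders = list(spA = "O1", spB = "O1", spC = "O2"),
        n_genomes = list(spA = 6L, spB = 4L, spC = 3L),
        newick = "((spA:0.1,spB:0.1):1.0,spC:1.5);")
      list(release = rel, gis = NULL, cap = 5L,
           expected = list(small_db_species = "spC", small_db_size = 3L))
    },
    "shared-composition" = {
      rel <- hand_release(
        sp_orders = list(spA = "O1", spB = "O1", spC = "O2", spD = "O2"),
        n_genomes = list(spA = 2L, spB = 2L, spC = 8L, spD = 9L),
        newick = "((spA:0.1,spB:0.1):1.0,(spC:0.2,spD:0.2):1.0);")
      list(release = rel, gis = NULL, cap = 10L,
           expected = list(shared_species = c("spA", "spB"),
                           shared_db_size = 4L))
    },
    "big-species" = {
      rel <- hand_release(
        sp_orders = list(spA = "O1", spB = "O1"),
        n_genomes = list(spA = 30L, spB = 5L),
        newick = "(spA:0.2,spB:0.2);")
      list(release = rel, gis = NULL, cap = 20L,
           expected = list(db_size = 20L, n_donors = 0L))
    },
    "decay-demo" = {
      cfg <- fixture_config(seed = 424L, n_orders = 3L,
                            n_archaea_orders = 0L,
                            mean_species_per_order = 4,
                            p_multi = 0.8, mean_extra_genomes = 5,
                            gi = list(types = c("Phage1", "NonPI", "Reject"),
                                      mean_calls = c(Phage1 = 9, NonPI = 9,
                                                     Reject = 9),
                                      p0 = c(Phage1 = 0.95, NonPI = 0.5,
                                             Reject = 0.95 / 7),
                                      decay = 2.0, tandem_frac = 0.05))
      rel <- generate_release(cfg, with_sequences = FALSE)
      gis <- generate_gi_calls(rel)
      list(release = rel, gis = gis, cap = 20L,
           expected = list(decay = 2.0, p0_gap = 7))
    })
}
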