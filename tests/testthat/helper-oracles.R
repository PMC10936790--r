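# Independent straight-line oracles. These deliberately avoid the package's
# internal code paths: ranking recomputes greedy sums from scratch each step,
# the k-mer oracle works on strings, and the design oracle re-sorts
# neighbours with its own loop over an ape distance matrix.

# exact canonical k-mer set of one or more sequences, as strings
oracle_kmer_set <- function(seqs, k) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  out <- character()
  for (s in seqs) {
    s <- toupper(s)
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- revcomp(km)
      out <- c(out, if (km <= rc) km else rc)
    }
  }
  unique(out)
}

oracle_jaccard <- function(seq_a, seq_b, k) {
  a <- oracle_kmer_set(seq_a, k)
  b <- oracle_kmer_set(seq_b, k)
  length(intersect(a, b)) / length(union(a, b))
}

# within-species ranking per the four-step procedure, recomputed naively
oracle_rank <- function(meta, dist_fun) {
  rep_acc <- meta$accession[meta$is_representative]
  rest <- meta[!meta$is_representative, , drop = FALSE]
  qkey <- match(rest$mimag_quality, c("high", "medium", "low", "missing"))
  qkey[is.na(qkey)] <- 4L
  ckey <- rest$contig_count
  ckey[is.na(ckey)] <- Inf
  qs <- rest$accession[order(qkey, ckey, rest$accession)]
  n <- nrow(meta)
  tail_n <- floor(0.1 * (n - 1))
  tail_accs <- if (tail_n > 0) qs[(length(qs) - tail_n + 1):length(qs)] else character()
  top <- setdiff(qs, tail_accs)
  seed <- if (length(rep_acc) == 1) rep_acc else top[1]
  pool <- if (length(rep_acc) == 1) top else top[-1]
  chosen <- seed
  while (length(pool) > 0) {
    sums <- sapply(pool, function(g) sum(sapply(chosen, function(h) dist_fun(g, h))))
    best <- pool[which(sums == max(sums))[1]]  # earliest in quality order
    chosen <- c(chosen, best)
    pool <- setdiff(pool, best)
  }
  c(chosen, tail_accs)
}

# DB design for one species: own ranked prefix, then same-order neighbours
# by ascending tree distance (same-family first, then name, on ties)
oracle_design <- function(sp, ranked, lineages, dmat, cap) {
  members <- ranked[[sp]]
  members <- members[seq_len(min(cap, length(members)))]
  row <- lineages[lineages$species == sp, ]
  others <- lineages[lineages$order == row$order & lineages$species != sp, ]
  others <- others[others$species %in% rownames(dmat), , drop = FALSE]
  if (nrow(others) > 0) {
    d <- dmat[sp, others$species]
    ord <- order(d, !(others$family == row$family), others$species)
    for (nb in others$species[ord]) {
      if (length(members) >= cap) break
      contrib <- ranked[[nb]]
      if (is.null(contrib)) next
      take <- min(cap - length(members), length(contrib))
      members <- c(members, contrib[seq_len(take)])
    }
  }
  members
}

# all-pairs patristic distances by explicit path enumeration on small trees
oracle_patristic <- function(tree, a, b) {
  if (a == b) return(0)
  # parent map
  par <- integer(max(tree$edge))
  par[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- setNames(tree$edge.length, tree$edge[, 2])
  path_to_root <- function(node) {
    p <- node
    while (par[p[length(p)]] != 0) p <- c(p, par[p[length(p)]])
    p
  }
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  pa <- path_to_root(ia)
  pb <- path_to_root(ib)
  lca <- intersect(pa, pb)[1]
  up <- function(path) {
    d <- 0
    for (n in path) {
      if (n == lca) break
      d <- d + elen[[as.character(n)]]
    }
    d
  }
  up(pa) + up(pb)
}

# random metadata for one species (used by ranking-oracle instances)
random_species_meta <- function(sp, n, with_rep = TRUE) {
  data.frame(accession = sprintf("GCA_%s_%02d", sp, seq_len(n)),
             domain = "Bacteria", phylum = "P", class = "C", order = "O",
             family = "F", genus = "G", species = sp,
             mimag_quality = sample(c("high", "medium", "low", "missing"),
                                    n, replace = TRUE),
             contig_count = sample.int(50L, n, replace = TRUE),
             is_representative = if (with_rep) seq_len(n) == 1 else rep(FALSE, n),
             genome_size_bp = 1e6, stringsAsFactors = FALSE)
}

# random symmetric distance table over a set of accessions
random_distance_table <- function(accs) {
  if (length(accs) < 2) {
    return(data.frame(ref_id = character(), query_id = character(),
                      distance = numeric(), p_value = numeric(),
                      shared_hashes = character(), stringsAsFactors = FALSE))
  }
  pr <- combn(sort(accs), 2)
  data.frame(ref_id = pr[1, ], query_id = pr[2, ],
             distance = round(runif(ncol(pr)), 3), p_value = 0,
             shared_hashes = "0/0", stringsAsFactors = FALSE)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive pair-distance lookup over a distance table (test-side counterpart)
dist_lookup_test <- function(dt) {
  function(a, b) {
    if (a == b) return(0)
    hit <- dt[(dt$ref_id == a & dt$query_id == b) |
                (dt$ref_id == b & dt$query_id == a), ]
    if (nrow(hit) == 0) 0 else hit$distance[1]
  }
}
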