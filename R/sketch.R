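#' Build a bottom-s MinHash sketch of a genome
#'
#' Enumerates canonical k-mers (the lexicographic minimum of each k-mer and
#' its reverse complement), hashes each with a seeded, platform-independent
#' 64-bit mix truncated to 53 bits (so hash values are exact in R doubles),
#' and keeps the `s` smallest distinct values.  K-mers containing non-ACGT
#' characters are skipped.  Multi-record input (e.g. a draft assembly's
#' contigs) is pooled into one sketch.
#'
#' Defaults (`k = 21`, `s = 1000`) follow the standard genome-sketching
#' convention so distances are comparable with common sketching tools run at
#' their default settings.
#'
#' @param sequences Character vector of nucleotide sequences, a
#'   [Biostrings::DNAStringSet], or a path to a (possibly gzipped) FASTA
#'   file.
#' @param k K-mer length, 1--31.
#' @param s Sketch capacity (number of hashes retained).
#' @param hash_seed Integer seed XORed into the k-mer code before hashing;
#'   sketches are only comparable at equal `k`, `s` and `hash_seed`.
#' @param accession Optional genome identifier stored in the sketch.
#' @return An object of class `"genome_sketch"`: a list with elements
#'   `accession`, `k`, `s`, `hash_seed`, `hashes` (ascending) and `n_kmers`
#'   (distinct canonical k-mers seen).
#' @export
build_sketch <- function(sequences, k = 21, s = 1000, hash_seed = 42,
                         accession = NA_character_) {
  sequences <- .as_sequence_chr(sequences)
  res <- sketch_kmers_cpp(sequences, as.integer(k), as.integer(s),
                          as.numeric(hash_seed))
  if (res$n_kmers == 0) {
    if (!res$any_long_enough) {
      stop("empty sketch: all sequences shorter than k = ", k)
    }
    stop("empty sketch: no valid (ACGT-only) k-mers of length ", k)
  }
  structure(list(accession = accession, k = as.integer(k), s = as.integer(s),
                 hash_seed = as.numeric(hash_seed), hashes = res$hashes,
                 n_kmers = as.numeric(res$n_kmers)),
            class = "genome_sketch")
}

.as_sequence_chr <- function(x) {
  if (inherits(x, "XStringSet")) {
    return(as.character(x))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(as.character(Biostrings::readDNAStringSet(x)))
  }
  if (is.character(x)) return(x)
  stop("sequences must be a character vector, DNAStringSet or FASTA path")
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat("genome_sketch", if (!is.na(x$accession)) x$accession else "",
      sprintf("(k=%d, s=%d, seed=%g): %d/%g hashes\n",
              x$k, x$s, x$hash_seed, length(x$hashes), x$n_kmers))
  invisible(x)
}

.check_compatible <- function(a, b) {
  stopifnot(inherits(a, "genome_sketch"), inherits(b, "genome_sketch"))
  if (a$k != b$k || a$s != b$s || a$hash_seed != b$hash_seed) {
    stop("incompatible sketches: k/s/hash_seed must match (",
         sprintf("k %d vs %d, s %d vs %d, seed %g vs %g",
                 a$k, b$k, a$s, b$s, a$hash_seed, b$hash_seed), ")")
  }
}

#' Jaccard index estimate from two bottom sketches
#'
#' Bottom-s union estimator: with `X` the `s` smallest values of the merged
#' hash sets (or all of them, if fewer), the estimate is
#' `|X ∩ S(a) ∩ S(b)| / |X|`.  Exact when the sketch capacity exceeds the
#' union cardinality.
#'
#' @param a,b Sketches from [build_sketch()] with equal `k`, `s` and seed.
#' @return Estimated Jaccard index in \[0, 1\].
#' @export
jaccard_estimate <- function(a, b) {
  .check_compatible(a, b)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  x <- merged[seq_len(min(a$s, length(merged)))]
  sum(x %in% a$hashes & x %in% b$hashes) / length(x)
}

# shared/total counts behind the estimator, for "x/y" reporting
.shared_hashes <- function(a, b) {
  merged <- sort(unique(c(a$hashes, b$hashes)))
  x <- merged[seq_len(min(a$s, length(merged)))]
  c(shared = sum(x %in% a$hashes & x %in% b$hashes), total = length(x))
}

#' Sketch distance between two genomes
#'
#' Transforms the estimated Jaccard index `j` into a distance
#' `D = -(1/k) * log(2j / (1 + j))`, clamped to \[0, 1\].  `j = 0` maps to
#' the saturation value 1 (the transform diverges), `j = 1` to 0.
#' Distances above 0.2 are outside the estimator's reliable range and
#' should be treated with caution (see [sketch_vs_tree_profile()]).
#'
#' @inheritParams jaccard_estimate
#' @return Distance in \[0, 1\].
#' @export
sketch_distance <- function(a, b) {
  j <- jaccard_estimate(a, b)
  if (j <= 0) return(1)
  d <- -(1 / a$k) * log(2 * j / (1 + j))
  min(max(d, 0), 1)
}

#' All pairwise sketch distances within a species
#'
#' Sketches every genome and computes the distance for every unordered pair
#' once, in lexicographic pair order.  Genomes whose sequences cannot be
#' read are recorded as failures and contribute no pair rows.
#'
#' @param genomes Named list: accession to sequences (character vector,
#'   `DNAStringSet`, or FASTA path).
#' @param k,s,hash_seed Sketch parameters, see [build_sketch()].
#' @return A distance table: data frame with columns `ref_id`, `query_id`,
#'   `distance`, `p_value` (always 0) and `shared_hashes` (`"x/y"`),
#'   one row per unordered pair, with failed accessions in the
#'   `"failures"` attribute.
#' @export
pairwise_within_species <- function(genomes, k = 21, s = 1000, hash_seed = 42) {
  stopifnot(length(genomes) >= 1L, !is.null(names(genomes)))
  accs <- sort(names(genomes))
  sketches <- list()
  failures <- character()
  for (acc in accs) {
    sk <- tryCatch(build_sketch(genomes[[acc]], k = k, s = s,
                                hash_seed = hash_seed, accession = acc),
                   error = function(e) e)
    if (inherits(sk, "error")) failures <- c(failures, acc)
    else sketches[[acc]] <- sk
  }
  ok <- names(sketches)
  if (length(ok) < 2L) {
    out <- data.frame(ref_id = character(), query_id = character(),
                      distance = numeric(), p_value = numeric(),
                      shared_hashes = character(), stringsAsFactors = FALSE)
    attr(out, "failures") <- failures
    return(out)
  }
  pairs <- combn(ok, 2L)
  n <- ncol(pairs)
  dist <- numeric(n)
  shared <- character(n)
  for (i in seq_len(n)) {
    a <- sketches[[pairs[1, i]]]
    b <- sketches[[pairs[2, i]]]
    dist[i] <- sketch_distance(a, b)
    sh <- .shared_hashes(a, b)
    shared[i] <- paste0(sh[["shared"]], "/", sh[["total"]])
  }
  out <- data.frame(ref_id = pairs[1, ], query_id = pairs[2, ],
                    distance = dist, p_value = 0, shared_hashes = shared,
                    stringsAsFactors = FALSE)
  attr(out, "failures") <- failures
  out
}

#' Read and write distance tables
#'
#' Five-column, header-less tab format (`ref_id`, `query_id`, `distance`,
#' `p_value`, `shared_hashes`), column-compatible with the pairwise output
#' of common sketching tools, so precomputed tables can be ingested in
#' place of sketching.
#'
#' @param x A distance table (see [pairwise_within_species()]).
#' @param file Path to write to / read from.
#' @export
write_distance_table <- function(x, file) {
  lines <- sprintf("%s\t%s\t%s\t%s\t%s", x$ref_id, x$query_id,
                   sprintf("%.17g", x$distance), sprintf("%.17g", x$p_value),
                   x$shared_hashes)
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(file) {
  raw <- read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("ref_id", "query_id", "distance",
                                  "p_value", "shared_hashes"),
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "character"))
  if (any(raw$distance < 0 | raw$distance > 1)) {
    stop("distance table contains values outside [0, 1]")
  }
  raw
}

# O(1) pair-distance lookup closure over a distance table (or NULL).
# Unknown pairs score the default (0: deprioritised, not excluded).
dist_lookup <- function(table, default = 0) {
  env <- new.env(parent = emptyenv())
  if (!is.null(table) && nrow(table) > 0) {
    key <- paste0(pmin(table$ref_id, table$query_id), "\r",
                  pmax(table$ref_id, table$query_id))
    for (i in seq_along(key)) assign(key[i], table$distance[i], envir = env)
  }
  function(a, b) {
    if (a == b) return(0)
    v <- get0(paste0(min(a, b), "\r", max(a, b)), envir = env)
    if (is.null(v)) default else v
  }
}
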