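#' Quick-setup build plan from a precalculated design file
#'
#' Given a design file (or an in-memory design set) and an optional list of
#' wanted species, returns the minimal set of unique databases covering
#' those species and the deduplicated accession list to collect — skipping
#' distance measurement and design computation entirely.
#'
#' @param design A path to a design file, or a `"design_set"`.
#' @param wanted_species Optional character vector of species to prepare;
#'   default: every species in the design file.
#' @return List with `species`, `db_ids`, `dbs` (the covering designs) and
#'   `accessions` (sorted, duplicate-free union of their members).
#' @export
quick_setup_plan <- function(design, wanted_species = NULL) {
  if (is.character(design) && length(design) == 1L) {
    design <- read_design_file(design)
  }
  stopifnot(inherits(design, "design_set"))
  all_sp <- names(design$species_map)
  if (is.null(wanted_species) || length(wanted_species) == 0L) {
    wanted_species <- all_sp
  }
  absent <- setdiff(wanted_species, all_sp)
  if (length(absent)) {
    stop("species absent from design file: ", paste(absent, collapse = ", "))
  }
  ids <- sort(unique(unname(design$species_map[wanted_species])))
  dbs <- design$dbs[ids]
  accs <- sort(unique(unlist(lapply(dbs, function(d) d$members),
                             use.names = FALSE)))
  list(species = sort(wanted_species), db_ids = ids, dbs = dbs,
       accessions = accs)
}

#' Collect genome assemblies with retry
#'
#' Repeatedly invokes an injectable fetcher on the missing accession set
#' until either nothing is missing or a round makes no progress (the count
#' of missing genomes stops decreasing) — the latter typically means the
#' remaining assemblies are suppressed or absent at the source.  The
#' pipeline proceeds without persistent failures; they are reported so the
#' user may supply them manually.
#'
#' @param accessions Accessions to obtain.
#' @param fetcher Function taking a character vector of accessions and
#'   returning the subset successfully obtained in that round.
#' @return List with `obtained`, `missing` and `rounds`.
#' @export
collect_genomes <- function(accessions, fetcher) {
  accessions <- unique(accessions)
  obtained <- character()
  missing <- accessions
  rounds <- 0L
  while (length(missing) > 0L) {
    rounds <- rounds + 1L
    got <- intersect(as.character(fetcher(missing)), missing)
    obtained <- c(obtained, got)
    new_missing <- setdiff(missing, got)
    no_progress <- length(new_missing) >= length(missing)
    missing <- new_missing
    if (no_progress) break
  }
  list(obtained = obtained, missing = missing, rounds = rounds)
}

#' Re-design against a new release and diff
#'
#' Runs a full design against the new release inputs (sketches and
#' distances are keyed by accession, so cached within-species distance
#' tables carry over unchanged) and reports which species were added,
#' removed, or had their database composition change.
#'
#' @param old_design_set Previous `"design_set"`.
#' @param species,ranked_lists,trees,lineages,config,release As in
#'   [design_all()], for the new release.
#' @return List with `design_set` (the new set) and `diff` (lists
#'   `added`, `removed`, `changed`).
#' @export
plan_updates <- function(old_design_set, species, ranked_lists, trees,
                         lineages, config, release = "update") {
  new_set <- design_all(species, ranked_lists, trees, lineages, config,
                        release = release)
  old_sp <- names(old_design_set$species_map)
  new_sp <- names(new_set$species_map)
  member_set <- function(set, sp) {
    sort(set$dbs[[set$species_map[[sp]]]]$members)
  }
  common <- intersect(old_sp, new_sp)
  changed <- common[vapply(common, function(sp)
    !identical(member_set(old_design_set, sp), member_set(new_set, sp)),
    logical(1))]
  list(design_set = new_set,
       diff = list(added = setdiff(new_sp, old_sp),
                   removed = setdiff(old_sp, new_sp),
                   changed = changed))
}

#' Emit a database as multi-FASTA
#'
#' Concatenates member genome sequences in rank order into one FASTA file,
#' prefixing every record header with the genome accession.  Missing
#' members are skipped with a warning; an optional post-hook runs a
#' configurable external indexing command (e.g. a BLASTN `makeblastdb`
#' template) on the emitted file.
#'
#' @param db A `"db_design"`.
#' @param genome_source Function mapping an accession to sequences
#'   (character vector or `DNAStringSet`), or a named list; return `NULL`
#'   for unavailable genomes.
#' @param file Output FASTA path.
#' @param index_cmd Optional `sprintf` template with one `%s` (the FASTA
#'   path); executed with [system()] after writing.  `NULL` (default)
#'   skips indexing, for when only the design information is desired.
#' @return Invisibly, the output path; the number of genomes written is in
#'   the `"n_written"` attribute.
#' @export
emit_db <- function(db, genome_source, file, index_cmd = NULL) {
  getter <- if (is.function(genome_source)) genome_source else
    function(acc) genome_source[[acc]]
  seqs <- character()
  n_written <- 0L
  for (acc in db$members) {
    g <- getter(acc)
    if (is.null(g)) {
      warning("member genome '", acc, "' unavailable; skipped")
      next
    }
    g <- .as_sequence_chr(g)
    nm <- names(g) %||% paste0("contig", seq_along(g))
    if (is.null(names(g))) names(g) <- nm
    names(g) <- paste0(acc, "|", names(g))
    seqs <- c(seqs, g)
    n_written <- n_written + 1L
  }
  if (n_written == 0L) stop("no member genomes available for DB of '",
                            db$source_species, "'")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  if (!is.null(index_cmd)) system(sprintf(index_cmd, file))
  out <- file
  attr(out, "n_written") <- n_written
  invisible(out)
}

#' Sketch database of species representatives
#'
#' Builds one sketch per collected species-representative genome, in
#' support of fast species placement of new query genomes.  Genomes below
#' `min_genome_size_bp` are excluded with a warning.
#'
#' @param metadata Metadata table ([parse_metadata_table()]).
#' @param genome_source As in [emit_db()].
#' @param k,s,hash_seed Sketch parameters.
#' @param min_genome_size_bp Minimum total genome size (default 200 kbp).
#' @return Named list of `"genome_sketch"` objects keyed by accession.
#' @export
build_representative_sketch_db <- function(metadata, genome_source,
                                           k = 21, s = 1000, hash_seed = 42,
                                           min_genome_size_bp = 200000) {
  getter <- if (is.function(genome_source)) genome_source else
    function(acc) genome_source[[acc]]
  reps <- metadata$accession[metadata$is_representative]
  out <- list()
  for (acc in sort(reps)) {
    g <- getter(acc)
    if (is.null(g)) next  # representative not collected
    g <- .as_sequence_chr(g)
    if (sum(nchar(g)) < min_genome_size_bp) {
      warning("representative '", acc, "' below ", min_genome_size_bp,
              " bp; excluded from sketch database")
      next
    }
    out[[acc]] <- build_sketch(g, k = k, s = s, hash_seed = hash_seed,
                               accession = acc)
  }
  out
}

#' Read and write sketch collections
#'
#' Plain-text serialisation of a list of sketches: one `#params` header
#' and one row per sketch (`accession`, `n_kmers`, comma-joined hash
#' values).  Hashes are 53-bit integers, exact in doubles.
#'
#' @param sketches Named list of `"genome_sketch"` objects.
#' @param file Path.
#' @export
write_sketch_db <- function(sketches, file) {
  if (length(sketches) == 0L) {
    writeLines("#smartdb_sketches\tv1\t21\t1000\t42", file)
    return(invisible(file))
  }
  s1 <- sketches[[1]]
  header <- sprintf("#smartdb_sketches\tv1\t%d\t%d\t%.17g", s1$k, s1$s,
                    s1$hash_seed)
  rows <- vapply(sketches, function(sk)
    sprintf("%s\t%.17g\t%s", sk$accession, sk$n_kmers,
            paste(sprintf("%.0f", sk$hashes), collapse = ",")),
    character(1))
  writeLines(c(header, unname(rows)), file)
  invisible(file)
}

#' @rdname write_sketch_db
#' @export
read_sketch_db <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "#smartdb_sketches") stop("not a sketch database file")
  k <- as.integer(hdr[3]); s <- as.integer(hdr[4]); seed <- as.numeric(hdr[5])
  out <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    out[[parts[1]]] <- structure(
      list(accession = parts[1], k = k, s = s, hash_seed = seed,
           hashes = as.numeric(strsplit(parts[3], ",", fixed = TRUE)[[1]]),
           n_kmers = as.numeric(parts[2])),
      class = "genome_sketch")
  }
  out
}
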