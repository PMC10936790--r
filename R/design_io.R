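#' Read and write database design files
#'
#' A design set is serialised as a plain tab-separated text file with three
#' sections: `#key value` header lines (format version, release, cap, rank
#' limit, small-DB threshold), `DB` rows (db id, source species,
#' comma-joined member accessions in fill order, comma-joined
#' `species:count` donor records) and `MAP` rows (species, db id).  The
#' format round-trips exactly: writing a read-back file reproduces the
#' original bytes.
#'
#' @param design_set A `"design_set"` from [design_all()] or
#'   [deduplicate()].
#' @param file Path to write to / read from.
#' @export
write_design_file <- function(design_set, file) {
  cfg <- design_set$config
  header <- c("#smartdb_design\tv1",
              paste0("#release\t", design_set$release),
              paste0("#cap\t", cfg$cap %||% "NA"),
              paste0("#rank_limit\t", cfg$rank_limit %||% "order"),
              paste0("#small_db_threshold\t", cfg$small_db_threshold %||% 5),
              paste0("#min_genome_size_bp\t",
                     format(cfg$min_genome_size_bp %||% 200000,
                            scientific = FALSE)))
  db_rows <- vapply(names(design_set$dbs), function(id) {
    d <- design_set$dbs[[id]]
    donors <- if (nrow(d$donors)) {
      paste(sprintf("%s:%d", d$donors$species, d$donors$genomes_contributed),
            collapse = ",")
    } else ""
    sprintf("DB\t%s\t%s\t%s\t%s", id, d$source_species,
            paste(d$members, collapse = ","), donors)
  }, character(1))
  map_rows <- sprintf("MAP\t%s\t%s", names(design_set$species_map),
                      unname(design_set$species_map))
  writeLines(c(header, db_rows, map_rows), file)
  invisible(file)
}

#' @rdname write_design_file
#' @export
read_design_file <- function(file) {
  lines <- readLines(file)
  if (length(lines) == 0L || !identical(lines[1], "#smartdb_design\tv1")) {
    stop("not a v1 design file: ", file)
  }
  meta <- list()
  dbs <- list()
  map_sp <- character()
  map_id <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (startsWith(ln, "#")) {
      meta[[sub("^#", "", parts[1])]] <- if (length(parts) > 1) parts[2] else ""
    } else if (parts[1] == "DB") {
      if (length(parts) < 4) stop("malformed DB row at line ", i)
      donors <- if (length(parts) >= 5 && nzchar(parts[5])) {
        dd <- do.call(rbind, strsplit(strsplit(parts[5], ",", fixed = TRUE)[[1]],
                                      ":", fixed = TRUE))
        data.frame(species = dd[, 1],
                   genomes_contributed = as.integer(dd[, 2]),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(species = character(), genomes_contributed = integer(),
                   stringsAsFactors = FALSE)
      }
      cap <- suppressWarnings(as.integer(meta$cap))
      members <- strsplit(parts[4], ",", fixed = TRUE)[[1]]
      dbs[[parts[2]]] <- structure(
        list(source_species = parts[3], members = members, donors = donors,
             submaximal = if (is.na(cap)) NA else length(members) < cap,
             cap = cap),
        class = "db_design")
    } else if (parts[1] == "MAP") {
      if (length(parts) != 3) stop("malformed MAP row at line ", i)
      map_sp <- c(map_sp, parts[2])
      map_id <- c(map_id, parts[3])
    } else {
      stop("unrecognised row type '", parts[1], "' at line ", i)
    }
  }
  unknown <- setdiff(unique(map_id), names(dbs))
  if (length(unknown)) {
    stop("species map references unknown db id(s): ",
         paste(unknown, collapse = ", "))
  }
  cap_read <- suppressWarnings(as.integer(meta$cap))
  cfg <- design_config(cap = if (is.na(cap_read)) 1L else cap_read,
                       small_db_threshold = as.integer(meta$small_db_threshold %||% 5),
                       min_genome_size_bp = as.numeric(meta$min_genome_size_bp %||% 200000))
  structure(list(release = meta$release %||% "release", config = cfg,
                 dbs = dbs, species_map = setNames(map_id, map_sp),
                 counts = .design_counts(dbs, setNames(map_id, map_sp),
                                         threshold = cfg$small_db_threshold),
                 errors = character()),
            class = "design_set")
}
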