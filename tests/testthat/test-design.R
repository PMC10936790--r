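# small fixed release used across design tests
design_fixture <- function() {
  lin <- data.frame(
    domain = "Bacteria", phylum = "P", class = "C",
    order = c("O1", "O1", "O1", "O2"),
    family = c("F1", "F1", "F2", "F3"),
    genus = paste0("G", 1:4),
    species = c("spA", "spB", "spC", "spD"),
    stringsAsFactors = FALSE)
  tree <- parse_newick("(((spA:0.1,spB:0.3):0.2,spC:0.6):1.0,spD:1.0);",
                       domain = "Bacteria")
  ranked <- list(spA = sprintf("A%02d", 1:50), spB = sprintf("B%02d", 1:30),
                 spC = sprintf("C%02d", 1:40), spD = sprintf("D%02d", 1:3))
  list(lin = lin, tree = tree, ranked = ranked)
}

test_that("a species over the cap keeps its own top-ranked prefix", {
  fx <- design_fixture()
  nb <- neighbor_species(fx$tree, fx$lin, "spA")
  d <- design_for_species("spA", fx$ranked, nb, design_config(cap = 20))
  expect_identical(d$members, fx$ranked$spA[1:20])
  expect_false(d$submaximal)
  expect_identical(nrow(d$donors), 0L)
})

test_that("phylogenetic filling appends neighbours by distance, truncating the last donor", {
  fx <- design_fixture()
  nb <- neighbor_species(fx$tree, fx$lin, "spA")
  # spB at 0.4 closer than spC at 0.9
  expect_identical(nb$species, c("spB", "spC"))
  d <- design_for_species("spA", fx$ranked, nb, design_config(cap = 100))
  expect_identical(d$members,
                   c(fx$ranked$spA, fx$ranked$spB, fx$ranked$spC[1:20]))
  expect_identical(d$donors$species, c("spB", "spC"))
  expect_identical(d$donors$genomes_contributed, c(30L, 20L))
  expect_false(d$submaximal)
})

test_that("order exhaustion leaves a submaximal, small-flagged database", {
  fx <- design_fixture()
  nb <- neighbor_species(fx$tree, fx$lin, "spD")
  expect_identical(nrow(nb), 0L)   # alone in its order
  d <- design_for_species("spD", fx$ranked, nb, design_config(cap = 200))
  expect_identical(d$members, fx$ranked$spD)
  expect_true(d$submaximal)
  expect_lt(length(d$members), 5)

  expect_error(design_for_species("spE", fx$ranked, nb, design_config(cap = 5)),
               "spE")
})

test_that("design_all is order-closed, covering, and flags small DBs by name", {
  fx <- design_fixture()
  expect_warning(
    set <- design_all(fx$lin$species, fx$ranked, fx$tree, fx$lin,
                      design_config(cap = 60)),
    "spD")
  expect_identical(sort(names(set$species_map)), sort(fx$lin$species))
  # order closure: every member's species shares the source's order
  acc_species <- c(setNames(rep("spA", 50), fx$ranked$spA),
                   setNames(rep("spB", 30), fx$ranked$spB),
                   setNames(rep("spC", 40), fx$ranked$spC),
                   setNames(rep("spD", 3), fx$ranked$spD))
  for (id in names(set$dbs)) {
    db <- set$dbs[[id]]
    src_order <- fx$lin$order[fx$lin$species == db$source_species]
    member_orders <- fx$lin$order[match(acc_species[db$members], fx$lin$species)]
    expect_true(all(member_orders == src_order))
    expect_lte(length(db$members), 60)
    expect_identical(db$submaximal, length(db$members) < 60)
  }
  expect_identical(set$counts$unique_genomes,
                   length(unique(unlist(lapply(set$dbs, `[[`, "members")))))
})

test_that("species with no collected genomes go to the error manifest", {
  fx <- design_fixture()
  ranked <- fx$ranked
  ranked$spD <- NULL
  set <- design_all(fx$lin$species, ranked, fx$tree, fx$lin,
                    design_config(cap = 60))
  expect_named(set$errors, "spD")
  expect_false("spD" %in% names(set$species_map))
  expect_identical(set$counts$n_species, 3L)
})

test_that("deduplication stores one DB per composition, keyed to the least source", {
  # two sibling 2-genome species alone in one order share a 4-genome DB
  lin <- data.frame(domain = "Bacteria", phylum = "P", class = "C",
                    order = "O1", family = "F1", genus = c("G1", "G2"),
                    species = c("spX", "spY"), stringsAsFactors = FALSE)
  tree <- parse_newick("(spX:0.2,spY:0.2);")
  ranked <- list(spX = c("X1", "X2"), spY = c("Y1", "Y2"))
  expect_warning(
    set <- design_all(lin$species, ranked, tree, lin, design_config(cap = 10)),
    "small")
  expect_identical(set$counts$unique_dbs, 1L)
  expect_identical(unname(set$species_map[["spX"]]),
                   unname(set$species_map[["spY"]]))
  db <- set$dbs[[set$species_map[["spX"]]]]
  expect_identical(db$source_species, "spX")   # lexicographically least
  expect_setequal(db$members, c("X1", "X2", "Y1", "Y2"))
  # members follow the retained source's fill order
  expect_identical(db$members, c("X1", "X2", "Y1", "Y2"))

  # idempotence
  set2 <- deduplicate(set$dbs, config = set$config)
  expect_identical(set2$counts$unique_dbs, 1L)
})

test_that("distinct compositions are never merged and counting is exact", {
  designs <- list(
    a = structure(list(source_species = "a", members = c("g1", "g2"),
                       donors = data.frame(), submaximal = TRUE, cap = 5),
                  class = "db_design"),
    b = structure(list(source_species = "b", members = c("g2", "g1"),
                       donors = data.frame(), submaximal = TRUE, cap = 5),
                  class = "db_design"),
    c = structure(list(source_species = "c", members = c("g3"),
                       donors = data.frame(), submaximal = TRUE, cap = 5),
                  class = "db_design"))
  set <- deduplicate(designs, config = design_config(cap = 5))
  expect_identical(set$counts$unique_dbs, 2L)   # {g1,g2} shared; {g3} alone
  expect_identical(set$counts$n_species, 3L)
})

test_that("summaries report the design-set bookkeeping columns", {
  fx <- design_fixture()
  set <- suppressWarnings(design_all(fx$lin$species, fx$ranked, fx$tree,
                                     fx$lin, design_config(cap = 60)))
  s <- summarize_design_set(set)
  expect_identical(names(s), c("species", "cap", "unique_dbs",
                               "submaximal_dbs", "small_dbs",
                               "unique_genomes"))
  expect_identical(s$species, 4L)
  expect_identical(s$cap, 60L)
  expect_identical(s$small_dbs, 1L)      # spD's 3-genome DB
  total_sizes <- sum(sapply(set$dbs, function(d) length(d$members)))
  expect_lte(s$unique_genomes, total_sizes)

  empty <- deduplicate(list(), config = design_config(cap = 5))
  se <- summarize_design_set(empty)
  expect_true(all(se[, c("species", "unique_dbs", "submaximal_dbs",
                         "small_dbs", "unique_genomes")] == 0))
})

test_that("design files round-trip byte-for-byte on re-write", {
  fx <- design_fixture()
  set <- suppressWarnings(design_all(fx$lin$species, fx$ranked, fx$tree,
                                     fx$lin, design_config(cap = 60),
                                     release = "r1"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_design_file(set, f1)
  back <- read_design_file(f1)
  write_design_file(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(names(back$dbs), names(set$dbs))
  for (id in names(set$dbs)) {
    expect_identical(back$dbs[[id]]$members, set$dbs[[id]]$members)
  }
  expect_identical(back$species_map, set$species_map)

  # unknown db id in the species map is an error
  lines <- readLines(f1)
  lines <- c(lines, "MAP\tghost\tDB999999")
  writeLines(lines, f1)
  expect_error(read_design_file(f1), "DB999999")

  # empty design set still round-trips
  empty <- deduplicate(list(), config = design_config(cap = 5))
  empty$release <- "r0"
  write_design_file(empty, f2)
  back0 <- read_design_file(f2)
  expect_identical(length(back0$dbs), 0L)
})
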