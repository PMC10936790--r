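# hand-built GI table constructor
gi_row <- function(id, query, qsp, supporters, type = "Phage1", len = 10000,
                   integrase = TRUE, flank = 0, tandem = FALSE) {
  out <- data.frame(gi_id = id, query_accession = query, query_species = qsp,
                    contig = "c1", start = 100L, end = 100L + len - 1L,
                    length_bp = len, type = type,
                    has_ser_or_tyr_integrase = integrase,
                    flank_identity_block_bp = flank, is_tandem = tandem,
                    stringsAsFactors = FALSE)
  out$supporters <- list(supporters)
  out
}

test_that("the Reject rule fires on any of its three clauses", {
  expect_true(classify_reject(gi_row("g", "q", "s", "x", len = 4000,
                                     integrase = TRUE, flank = 0)))
  expect_false(classify_reject(gi_row("g", "q", "s", "x", len = 10000,
                                      integrase = TRUE, flank = 100)))
  expect_true(classify_reject(gi_row("g", "q", "s", "x", len = 10000,
                                     integrase = TRUE, flank = 400)))
  expect_true(classify_reject(gi_row("g", "q", "s", "x", len = 10000,
                                     integrase = FALSE, flank = 0)))
  # boundary: exactly 5 kbp and exactly 300 bp pass
  expect_false(classify_reject(gi_row("g", "q", "s", "x", len = 5000,
                                      integrase = TRUE, flank = 300)))
})

test_that("filtering drops tandem and unsupported calls with reason counts", {
  gis <- rbind(gi_row("g1", "q", "s", "x", tandem = TRUE),
               gi_row("g2", "q", "s", character(0)),
               gi_row("g3", "q", "s", c("x", "y")))
  f <- filter_calls(gis)
  expect_identical(f$retained$gi_id, "g3")
  expect_identical(f$dropped, c(tandem = 1L, no_support = 1L))
})

test_that("large-species selection applies all four strict thresholds", {
  counts <- data.frame(
    species = c("a", "b", "c", "d"),
    n_genomes = c(300, 301, 301, 500),
    n_phage1 = c(400, 101, 400, 400),
    n_nonpi = c(400, 101, 400, 100),
    n_reject = c(400, 101, 400, 400),
    stringsAsFactors = FALSE)
  # a: 300 genomes exactly -> excluded; b: total 303 <= 1000 -> excluded;
  # c: passes; d: n_nonpi not > 100 -> excluded
  expect_identical(select_large_species(counts), "c")
})

test_that("recovery curves match exhaustive intersection, rise, and saturate", {
  genome_list <- c("g1", "g2", "g3")
  gis <- rbind(gi_row("a", "q1", "s", "g3"),
               gi_row("b", "q1", "s", c("g1", "g3")),
               gi_row("c", "q2", "s", "g2", type = "Reject"),
               gi_row("d", "q2", "s", c("g2", "g3")),
               gi_row("e", "q2", "s", "g1", type = "Reject"))
  rc <- recovery_curve(gis, genome_list, c(1, 2, 3))
  # exhaustive check at each size per type, over 2 query genomes
  get <- function(sz, ty) rc$mean_recovered[rc$size == sz & rc$type == ty]
  expect_equal(get(1, "Phage1"), 1 / 2)   # only b (supporter g1)
  expect_equal(get(2, "Phage1"), 2 / 2)   # b and d
  expect_equal(get(3, "Phage1"), 3 / 2)   # all three Phage1 calls
  expect_equal(get(1, "Reject"), 1 / 2)   # e
  expect_equal(get(3, "Reject"), 2 / 2)
  # monotone, and saturation equals per-genome retained counts
  for (ty in unique(rc$type)) {
    v <- rc$mean_recovered[rc$type == ty][order(rc$size[rc$type == ty])]
    expect_false(is.unsorted(v))
    expect_equal(v[length(v)], sum(gis$type == ty) / 2)
  }
  expect_error(recovery_curve(gis, genome_list, 4), "exceeds")
})

omission_fixture <- function() {
  lin <- data.frame(
    domain = "Bacteria", phylum = "P", class = "C",
    order = c("O1", "O1", "O1", "O1"),
    family = c("F1", "F1", "F1", "F2"),
    genus = c("G1", "G1", "G2", "G3"),
    species = c("s1", "s2", "s3", "s4"),
    stringsAsFactors = FALSE)
  gsp <- c(q1 = "s1", a = "s1", b = "s2", c = "s3", d = "s4")
  list(lin = lin, gsp = gsp)
}

test_that("omission yields follow the hand-traced rank filters", {
  fx <- omission_fixture()
  # one same-genus (b) and one same-order-different-family (d) supporter
  gis <- gi_row("g1", "q1", "s1", c("b", "d"))
  y <- omission_yields(gis, fx$lin, fx$gsp, db_scopes = "domain")
  yy <- setNames(y$yield, y$rank)
  expect_identical(unname(yy[c("species", "genus", "family", "order")]),
                   c(1, 1, 1, 0))

  # supported only within its species: falls at species omission
  gis2 <- gi_row("g2", "q1", "s1", "a")
  y2 <- omission_yields(gis2, fx$lin, fx$gsp)
  expect_identical(unname(setNames(y2$yield, y2$rank)["species"]), 0)
})

test_that("omission yields are nested-monotone and honour DB-scope exclusions", {
  fx <- omission_fixture()
  set.seed(51)
  pool <- names(fx$gsp)[-1]
  gis <- do.call(rbind, lapply(1:30, function(i)
    gi_row(paste0("g", i), "q1", "s1",
           sample(pool, sample(3, 1)),
           type = sample(c("Phage1", "Reject"), 1))))
  y <- omission_yields(gis, fx$lin, fx$gsp, db_scopes = "domain")
  for (ty in unique(y$type)) {
    v <- y$yield[y$type == ty][match(c("species", "genus", "family", "order"),
                                     y$rank[y$type == ty])]
    expect_false(is.unsorted(rev(v)))   # non-increasing with coarser omission
  }

  # family-scoped GIs leave the family- and order-omission denominators
  gis_sc <- rbind(gi_row("h1", "q1", "s1", c("b", "d")),
                  gi_row("h2", "q1", "s1", "b"))
  scopes <- c(h1 = "domain", h2 = "family")
  ys <- omission_yields(gis_sc, fx$lin, fx$gsp, db_scopes = scopes)
  den <- setNames(ys$denominator, ys$rank)
  expect_identical(unname(den[c("species", "genus", "family", "order")]),
                   c(2L, 2L, 1L, 1L))
})

test_that("support origin partitions each type into three summing fractions", {
  fx <- omission_fixture()
  gis <- rbind(gi_row("g1", "q1", "s1", "a"),              # only inside
               gi_row("g2", "q1", "s1", c("c", "d")),      # only outside
               gi_row("g3", "q1", "s1", c("a", "c")),      # mixed
               gi_row("g4", "q1", "s1", "c", type = "Reject"))
  so <- support_origin_fractions(gis, fx$gsp)
  p1 <- so[so$type == "Phage1", ]
  expect_equal(p1$only_inside + p1$only_outside + p1$mixed, 1)
  expect_equal(p1$only_inside, 1 / 3)
  expect_equal(p1$only_outside, 1 / 3)
  expect_equal(so$only_outside[so$type == "Reject"], 1)
})

decay_fixture <- function() {
  lin <- data.frame(domain = "Bacteria", phylum = "P", class = "C",
                    order = "O1", family = "F1",
                    genus = c("G1", "G1", "G2", "G2"),
                    species = c("s1", "s2", "s3", "s4"),
                    stringsAsFactors = FALSE)
  tree <- parse_newick("((s1:0.05,s2:0.05):0.5,(s3:0.05,s4:0.05):0.5);")
  gsp <- c(q1 = "s1", a = "s1", b = "s2", c = "s3", d = "s4")
  list(lin = lin, tree = tree, gsp = gsp)
}

test_that("support decay bins distances with the intra-species zero convention", {
  fx <- decay_fixture()
  gis <- gi_row("g1", "q1", "s1", c("a", "b"))
  prof <- support_decay_profile(gis, fx$tree, fx$gsp,
                                possible = c("a", "b", "c", "d"))
  width <- 3.7 / 50
  # a at distance 0 (same species), b at 0.1, c and d at 1.1
  b_of <- function(d) floor(d / width) + 1
  p <- prof[prof$type == "Phage1", ]
  expect_equal(p$possible[p$bin == 1], 1)          # a
  expect_equal(p$actual[p$bin == 1], 1)
  expect_equal(p$possible[p$bin == b_of(0.1)], 1)  # b
  expect_equal(p$possible[p$bin == b_of(1.1)], 2)  # c, d
  expect_equal(p$actual[p$bin == b_of(1.1)], 0)
  expect_equal(sum(p$possible), 4)                 # conservation
  expect_true(all(p$ratio[!is.na(p$ratio)] >= 0 &
                    p$ratio[!is.na(p$ratio)] <= 1))

  # all supporters intra-species: all actual mass in bin 1
  gis2 <- gi_row("g2", "q1", "s1", "a")
  prof2 <- support_decay_profile(gis2, fx$tree, fx$gsp,
                                 possible = c("a", "b", "c", "d"))
  expect_equal(sum(prof2$actual[prof2$bin > 1]), 0)

  # a supporter outside the possible set is a data-consistency error
  expect_error(support_decay_profile(gis, fx$tree, fx$gsp, possible = "a"),
               "outside its possible")
})

test_that("out-of-range distances are dropped with a tally, not clamped", {
  lin <- data.frame(domain = "Bacteria", phylum = "P", class = "C",
                    order = "O1", family = "F1", genus = "G1",
                    species = c("s1", "s2"), stringsAsFactors = FALSE)
  tree <- parse_newick("(s1:2,s2:2);")   # distance 4 > 3.7
  gsp <- c(q1 = "s1", far = "s2", near = "s1")
  gis <- gi_row("g1", "q1", "s1", "far")
  prof <- support_decay_profile(gis, tree, gsp, possible = c("far", "near"))
  expect_equal(sum(prof$possible), 1)     # only the intra-species pair
  expect_identical(attr(prof, "n_dropped"), 2)  # far: possible + actual
})

test_that("shared-rank histograms normalise each trace to its own max", {
  fx <- decay_fixture()
  pairs <- data.frame(accession_a = c("a", "a", "a", "c"),
                      accession_b = c("a", "b", "c", "c"),
                      stringsAsFactors = FALSE)
  pr <- shared_rank_profile(pairs, fx$tree, fx$lin, fx$gsp)
  sp_trace <- pr[pr$rank == "species", ]
  expect_equal(sp_trace$count[sp_trace$bin == 1], 2)  # (a,a) and (c,c)
  expect_equal(max(sp_trace$norm), 1)
  for (r in unique(pr$rank)) expect_equal(max(pr$norm[pr$rank == r]), 1)
  # brute-force recount of the genus trace: (a,b) at distance 0.1
  gen <- pr[pr$rank == "genus", ]
  expect_equal(sum(gen$count), 1)
  expect_equal(gen$bin[gen$count == 1], floor(0.1 / (3.7 / 50)) + 1)
})

test_that("sketch-vs-tree profiles respect reliability and reporting cutoffs", {
  fx <- decay_fixture()
  pairs <- data.frame(
    accession_a = c("a", "a", "a"),
    accession_b = c("a", "b", "c"),
    sketch_distance = c(0, 0.1, 0.3),
    stringsAsFactors = FALSE)
  pr <- sketch_vs_tree_profile(pairs, fx$tree, fx$gsp)
  expect_true(all(pr$lo < 0.5))                 # reporting cutoff
  b1 <- pr[pr$bin == 1, ]
  expect_equal(b1$mean_sketch_distance, 0)      # identical genomes
  # the (a,c) pair at tree distance 1.1 is beyond the cutoff: absent
  expect_false(any(pr$lo > 1))
  # the 0.3 sketch distance would be unmeasurable if within range
  pairs2 <- data.frame(accession_a = "a", accession_b = "b",
                       sketch_distance = 0.3, stringsAsFactors = FALSE)
  pr2 <- sketch_vs_tree_profile(pairs2, fx$tree, fx$gsp)
  expect_equal(pr2$pct_measurable, 0)
  expect_true(is.na(pr2$mean_sketch_distance))
})

test_that("GI tables round-trip with list-column supporters", {
  gis <- rbind(gi_row("g1", "q1", "s1", c("a", "b")),
               gi_row("g2", "q2", "s2", character(0), type = "Reject",
                      len = 4000, integrase = FALSE, flank = 400,
                      tandem = TRUE))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_gi_table(gis, tf)
  back <- read_gi_table(tf)
  expect_identical(back$gi_id, gis$gi_id)
  expect_identical(back$supporters, gis$supporters)
  expect_identical(back$is_tandem, gis$is_tandem)
  expect_identical(back$has_ser_or_tyr_integrase, gis$has_ser_or_tyr_integrase)
  # inconsistent coordinates are rejected
  bad <- gis
  bad$end[1] <- bad$end[1] + 5L
  write_gi_table(bad, tf)
  expect_error(read_gi_table(tf), "length_bp")
})
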