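write_pair_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("curated-dialect files parse with location, evidence and source", {
  f <- write_pair_file(c(
    "Ligand\tReceptor\tLigand location\tPubMed ID\tSource",
    "TGFB1\tTGFBR1\tsecreted\t123;456\tliterature",
    "DLL1\tNOTCH1\tplasma membrane\t789\tliterature",
    "VEGFA\tFLT1\tboth\t\tliterature"
  ))
  db <- suppressMessages(read_lr_pairs(f, dialect = "connectomedb"))
  expect_equal(nrow(db), 3L)
  expect_equal(db$location, c("secreted", "plasma_membrane", "both"))
  expect_equal(db$evidence[[1]], c("123", "456"))
  # comma-delimited variant parses identically
  f2 <- write_pair_file(c("Ligand,Receptor,Ligand location",
                          "TGFB1,TGFBR1,secreted"), ".csv")
  db2 <- suppressMessages(read_lr_pairs(f2, dialect = "connectomedb"))
  expect_equal(db2$ligand, "TGFB1")
})

test_that("duplicated pairs merge with evidence unioned, not rejected", {
  f <- write_pair_file(c(
    "Ligand\tReceptor\tLigand location\tPubMed ID\tSource",
    "TGFB1\tTGFBR1\tsecreted\t111\tsrcA",
    "TGFB1\tTGFBR1\tsecreted\t222\tsrcB"
  ))
  expect_warning(db <- suppressMessages(read_lr_pairs(f)), "merged")
  expect_equal(nrow(db), 1L)
  expect_setequal(db$evidence[[1]], c("111", "222"))
})

test_that("two-column user lists default to location 'both' and dedupe", {
  f <- write_pair_file(c("Ligand\tReceptor", "L1\tR1", "L1\tR1"))
  db <- suppressMessages(suppressWarnings(
    read_lr_pairs(f, dialect = "two_column")))
  expect_equal(nrow(db), 1L)
  expect_equal(db$location, "both")
  expect_equal(db$evidence[[1]], character())
})

test_that("malformed or empty pair files are rejected", {
  no_receptor <- write_pair_file(c("Ligand\tPartner", "L1\tR1"))
  expect_error(suppressMessages(read_lr_pairs(no_receptor)),
               class = "lrnet_format_error")
  empty <- write_pair_file("Ligand\tReceptor")
  expect_error(suppressMessages(read_lr_pairs(empty)), "empty")
  expect_error(read_lr_pairs(tempfile()), "not found")
})

test_that("an exclusion table is parsed but never enters the database", {
  f <- write_pair_file(c("Ligand\tReceptor\tLigand location",
                         "TGFB1\tTGFBR1\tsecreted"))
  exc <- write_pair_file(c("Ligand\tReceptor\tReason",
                           "BADL\tBADR\tno primary literature support"))
  db <- suppressMessages(read_lr_pairs(f, exclusion_path = exc))
  expect_equal(nrow(db), 1L)
  expect_false("BADL" %in% db$ligand)
  excluded <- attr(db, "excluded")
  expect_equal(nrow(excluded), 1L)
  expect_equal(excluded[[1]], "BADL")
})

test_that("write/read round trip reproduces the pair set exactly", {
  db <- lr_pairs(c("TGFB1", "DLL1", "VEGFA"),
                 c("TGFBR1", "NOTCH1", "FLT1"),
                 location = c("secreted", "plasma_membrane", "both"),
                 evidence = list("11", c("22", "33"), character()))
  f <- tempfile(fileext = ".tsv")
  write_lr_pairs(db, f)
  back <- suppressMessages(read_lr_pairs(f, dialect = "connectomedb"))
  expect_equal(back$ligand, db$ligand)
  expect_equal(back$receptor, db$receptor)
  expect_equal(back$location, db$location)
  expect_equal(back$evidence[1:2], db$evidence[1:2])
})

test_that("location filtering keeps 'both' ligands in either analysis", {
  db <- lr_pairs(c("S1", "P1", "B1"), c("R1", "R2", "R3"),
                 location = c("secreted", "plasma_membrane", "both"))
  sec <- filter_by_location(db, "secreted")
  pm <- filter_by_location(db, "plasma_membrane")
  expect_setequal(sec$ligand, c("S1", "B1"))
  expect_setequal(pm$ligand, c("P1", "B1"))

  # all-plasma-membrane database yields an empty but valid secreted subset
  db_pm <- lr_pairs(c("P1", "P2"), c("R1", "R2"),
                    location = "plasma_membrane")
  expect_equal(nrow(filter_by_location(db_pm, "secreted")), 0L)

  # union of the two analyses covers every pair of a mixed database
  set.seed(11)
  locs <- sample(c("secreted", "plasma_membrane", "both"), 10, TRUE)
  db10 <- lr_pairs(paste0("L", 1:10), paste0("R", 1:10), location = locs)
  union_ligs <- union(filter_by_location(db10, "secreted")$ligand,
                      filter_by_location(db10, "plasma_membrane")$ligand)
  expect_setequal(union_ligs, db10$ligand)
})

toy_homology <- function() {
  tibble::tibble(
    group = c("1", "1", "2", "2", "2", "3", "3"),
    taxon = c(9606L, 10090L, 9606L, 10090L, 10090L, 9606L, 9606L),
    symbol = c("THPO", "Thpo", "MPL", "Mpl", "Mpl2", "ORPHAN", "ORPHANR")
  )
}

test_that("ortholog projection maps 1:1 pairs and expands 1:many", {
  hom <- toy_homology()
  db <- lr_pairs("THPO", "MPL", location = "secreted")
  mouse <- suppressMessages(map_orthologs(db, hom, 10090L))
  # brute-force cross product on the toy table: THPO -> {Thpo},
  # MPL -> {Mpl, Mpl2} => 1 x 2 = 2 mouse pairs
  expect_equal(nrow(mouse), 2L)
  expect_setequal(mouse$receptor, c("Mpl", "Mpl2"))
  expect_equal(unique(mouse$ligand), "Thpo")
  expect_equal(unique(mouse$location), "secreted")
  expect_equal(attr(mouse, "species_taxon"), 10090L)
  # no symbol in the output is absent from the target-taxon rows
  tgt_syms <- hom$symbol[hom$taxon == 10090L]
  expect_true(all(c(mouse$ligand, mouse$receptor) %in% tgt_syms))
})

test_that("pairs with an unmappable partner are dropped and counted", {
  hom <- toy_homology()
  db <- lr_pairs(c("THPO", "ORPHAN"), c("MPL", "MPL"))
  mapped <- suppressMessages(map_orthologs(db, hom, 10090L))
  expect_equal(attr(mapped, "n_dropped"), 1L)
  expect_false("Orphan" %in% mapped$ligand)
  expect_error(map_orthologs(db, hom, 7955L), "absent")
})

test_that("randomised pairings preserve degree multisets and are uniform", {
  db <- lr_pairs(c("L1", "L2"), c("R1", "R2"))
  draws <- randomise_pairs(db, 10000, seed = 99)
  expect_length(draws, 10000)
  expect_true(all(vapply(draws, nrow, 0L) == 2L))
  # the exact enumeration oracle: 2 pairs admit 2 assignments, each with
  # probability 1/2
  identity_frac <- mean(vapply(draws, function(d) {
    all(d$receptor == db$receptor)
  }, logical(1)))
  expect_gt(identity_frac, 0.47)
  expect_lt(identity_frac, 0.53)
  # degree multisets preserved on a database with repeated symbols
  db2 <- lr_pairs(c("A", "A", "B", "C"), c("X", "Y", "X", "Z"))
  r <- randomise_pairs(db2, 5, seed = 1)[[3]]
  expect_equal(sort(r$ligand), sort(db2$ligand))
  expect_equal(sort(r$receptor), sort(db2$receptor))
  # deterministic given seed
  expect_identical(randomise_pairs(db2, 3, seed = 7),
                   randomise_pairs(db2, 3, seed = 7))
  expect_error(randomise_pairs(lr_pairs("L", "R"), 2, seed = 1),
               "at least 2")
})
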