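# Means matrix used by the point-weight tests: genes x cell types.
calib_means <- function() {
  means <- rbind(
    EXL = c(A = 8, B = 0, C = 0, D = 0),   # ligand exclusive to A
    EXR = c(A = 0, B = 12, C = 0, D = 0),  # receptor exclusive to B
    UNIL = c(A = 5, B = 5, C = 5, D = 5),  # uniform ligand
    UNIR = c(A = 2, B = 2, C = 2, D = 2),  # uniform receptor
    SILENT = c(A = 0, B = 0, C = 0, D = 0)
  )
  profile_from_means(means)
}

test_that("specificity weight is 1 for exclusive pairs and 1/k^2 uniform", {
  prof <- calib_means()
  expect_equal(specificity_weight(prof, "EXL", "EXR", "A", "B"), 1)
  expect_equal(specificity_weight(prof, "UNIL", "UNIR", "A", "C"),
               1 / 16)
  # a gene silent in every cell type contributes 0, not NaN
  expect_equal(specificity_weight(prof, "SILENT", "EXR", "A", "B"), 0)
  expect_error(specificity_weight(prof, "EXL", "EXR", "A", "NOPE"),
               class = "lrnet_value_error")
})

test_that("mean and total weights are the stated products", {
  means <- rbind(LIG = c(A = 10, B = 0), REC = c(A = 0, B = 20))
  prof <- profile_from_means(means, n_cells = 4L)
  expect_equal(mean_expression_weight(prof, "LIG", "REC", "A", "B"), 200)
  expect_equal(mean_expression_weight(prof, "LIG", "REC", "B", "A"), 0)
  # totals are mean x n_cells, so the edge total weight carries abundance
  expect_equal(total_expression_weight(prof, "LIG", "REC", "A", "B"),
               (10 * 4) * (20 * 4))
  expect_equal(total_expression_weight(prof, "LIG", "REC", "A", "B"),
               mean_expression_weight(prof, "LIG", "REC", "A", "B") * 4 * 4)
  # genes absent from the profile count as mean 0
  expect_equal(mean_expression_weight(prof, "GHOST", "REC", "A", "B"), 0)
})

test_that("abundance worked example: 500 cells at 10 CPM vs 10 at 80 CPM", {
  cells <- c(paste0("a", 1:500), paste0("b", 1:10))
  vals <- matrix(0, 2, 510, dimnames = list(c("LIG", "REC"), cells))
  vals["LIG", 1:500] <- 10
  vals["REC", 501:510] <- 80
  m <- as_expression_matrix(vals, scale = "cpm")
  ann <- cell_annotation(cells, c(rep("A", 500), rep("B", 10)))
  prof <- summarise_cell_types(m, ann, c("LIG", "REC"))
  expect_equal(prof$total_expr[prof$gene == "LIG" & prof$cell_type == "A"],
               5000)
  expect_equal(prof$total_expr[prof$gene == "REC" & prof$cell_type == "B"],
               800)
  expect_equal(total_expression_weight(prof, "LIG", "REC", "A", "B"),
               5000 * 800)
})

test_that("edges appear only where ligand and receptor pass the filters", {
  # ligand detected in A only; receptor in both A and B
  means <- rbind(LIG = c(A = 6, B = 0), REC = c(A = 3, B = 3))
  prof <- profile_from_means(means)
  db <- lr_pairs("LIG", "REC")
  edges <- extract_edges(prof, db)
  expect_equal(nrow(edges), 2L)
  expect_setequal(paste(edges$sender, edges$receiver), c("A A", "A B"))
  expect_error(extract_edges(prof, db[0, ]), "empty")
})

test_that("extraction equals exhaustive brute-force enumeration", {
  for (seed in c(21, 22)) {
    fx <- random_fixture(seed, n_cell_types = 4, cells_per_type = 25,
                         n_genes = 40, n_pairs = 6)
    m <- normalise_cpm(fx$expression)
    prof <- summarise_cell_types(m, fx$annotation,
                                 unique(c(fx$pairs$ligand,
                                          fx$pairs$receptor)))
    edges <- extract_edges(prof, fx$pairs)
    oe <- oracle_edges(m, fx$annotation, fx$pairs)
    o1 <- edges[order(edge_key_str(edges)), ]
    o2 <- oe[order(edge_key_str(oe)), ]
    expect_equal(nrow(o1), nrow(o2))
    expect_equal(o1$mean_weight, o2$mean_weight, tolerance = 1e-12)
    expect_equal(o1$specificity_weight, o2$specificity_weight,
                 tolerance = 1e-12)
    expect_equal(o1$total_weight, o2$total_weight, tolerance = 1e-12)
  }
})

test_that("specificity components of an expressed gene sum to one", {
  fx <- random_fixture(30, n_cell_types = 5, cells_per_type = 20,
                       n_genes = 40, n_pairs = 6)
  prof <- fixture_profile(fx)
  sums <- tapply(prof$mean_expr, prof$gene, sum)
  expressed <- names(sums)[sums > 0]
  for (g in expressed[1:5]) {
    sub <- prof[prof$gene == g, ]
    expect_equal(sum(sub$mean_expr) / sums[[g]], 1)
  }
  # via the exported weight: uniform receptor against itself
  edges <- extract_edges(prof, fx$pairs)
  expect_true(all(edges$specificity_weight >= 0 &
                    edges$specificity_weight <= 1))
  expect_true(all(abs(edges$mean_weight -
                        edges$ligand_mean * edges$receptor_mean) < 1e-12))
})

test_that("raising thresholds never adds edges; scaling behaves as stated", {
  fx <- random_fixture(31)
  prof <- fixture_profile(fx)
  loose <- extract_edges(prof, fx$pairs, filter_settings(0.1))
  tight <- extract_edges(prof, fx$pairs, filter_settings(0.4, 5, 0.001))
  expect_true(all(edge_key_str(tight) %in% edge_key_str(loose)))

  # specificity is scale-invariant; mean weight scales quadratically
  m <- normalise_cpm(fx$expression)
  m2 <- m * 3
  attr(m2, "scale") <- "other_normalised"
  genes <- unique(c(fx$pairs$ligand, fx$pairs$receptor))
  prof2 <- summarise_cell_types(m2, fx$annotation, genes)
  e1 <- extract_edges(prof, fx$pairs)
  e2 <- extract_edges(prof2, fx$pairs)
  expect_equal(edge_key_str(e1), edge_key_str(e2))
  expect_equal(e2$specificity_weight, e1$specificity_weight,
               tolerance = 1e-12)
  expect_equal(e2$mean_weight, 9 * e1$mean_weight, tolerance = 1e-12)
})

test_that("strict detection mode excludes genes at exactly the threshold", {
  # 1 of 5 cells positive: detection exactly 0.2
  cells <- paste0("c", 1:5)
  vals <- matrix(0, 2, 5, dimnames = list(c("LIG", "REC"), cells))
  vals["LIG", 1] <- 10
  vals["REC", ] <- 5
  m <- as_expression_matrix(vals, scale = "cpm")
  ann <- cell_annotation(cells, rep("T", 5))
  prof <- summarise_cell_types(m, ann, c("LIG", "REC"))
  db <- lr_pairs("LIG", "REC")
  at_boundary <- extract_edges(prof, db, filter_settings(0.20))
  expect_equal(nrow(at_boundary), 1L)
  strict <- extract_edges(prof, db,
                          filter_settings(0.20, strict_detection = TRUE))
  expect_equal(nrow(strict), 0L)
})

test_that("co-detection demands both genes above threshold in one cell", {
  cells <- paste0("c", 1:10)
  vals <- matrix(0, 4, 10,
                 dimnames = list(c("L1", "R1", "L2", "R2"), cells))
  vals["L1", 1:3] <- 50   # jointly detected in 3/10 cells
  vals["R1", 1:3] <- 50
  vals["L2", 1:5] <- 50   # 50% each but in disjoint cells
  vals["R2", 6:10] <- 50
  m <- as_expression_matrix(vals, scale = "cpm")
  ann <- cell_annotation(cells, rep("T", 10))
  db <- lr_pairs(c("L1", "L2"), c("R1", "R2"))
  got <- codetect_pairs(m, ann, db, expr_threshold = 10,
                        codetect_fraction = 0.2)
  expect_equal(nrow(got), 1L)
  expect_equal(got$ligand, "L1")
  expect_equal(got$co_detection_fraction, 0.3)
})

test_that("co-detection matches the brute-force per-cell AND mask", {
  fx <- random_fixture(33, n_cell_types = 3, cells_per_type = 20,
                       n_genes = 30, n_pairs = 5)
  m <- normalise_cpm(fx$expression)
  got <- codetect_pairs(m, fx$annotation, fx$pairs, 10, 0.2)
  oracle <- oracle_codetect(m, fx$annotation, fx$pairs, 10, 0.2)
  if (is.null(oracle)) {
    expect_equal(nrow(got), 0L)
  } else {
    key <- function(d) paste(d$cell_type, d$ligand, d$receptor)
    expect_setequal(key(got), key(oracle))
    merged <- merge(got, oracle, by = c("cell_type", "ligand", "receptor"))
    expect_equal(merged$co_detection_fraction.x,
                 merged$co_detection_fraction.y)
  }
})
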