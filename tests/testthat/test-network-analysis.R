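test_that("autocrine fractions count ligands with a same-type receptor", {
  # type T expresses ligands L1, L2 and receptor R1 only;
  # pairs (L1,R1), (L2,R2): L1 has its receptor at home, L2 does not
  means <- rbind(
    L1 = c(T = 5, U = 5), L2 = c(T = 5, U = 0),
    R1 = c(T = 5, U = 0), R2 = c(T = 0, U = 5)
  )
  prof <- profile_from_means(means)
  db <- lr_pairs(c("L1", "L2"), c("R1", "R2"))
  af <- autocrine_fractions(prof, db)
  t_row <- af[af$cell_type == "T", ]
  expect_equal(t_row$ligand_fraction, 0.5)
  expect_equal(t_row$n_ligands, 2L)
  # receptors of T: {R1}; its ligand L1 is expressed in T -> fraction 1
  expect_equal(t_row$receptor_fraction, 1)
  # U expresses L1 and R2; neither partner at home
  u_row <- af[af$cell_type == "U", ]
  expect_equal(u_row$ligand_fraction, 0)
  expect_equal(u_row$receptor_fraction, 0)
  expect_true(is.finite(attr(af, "mean_ligand_fraction")))
})

test_that("autocrine fractions match a set-intersection oracle", {
  fx <- random_fixture(61, n_cell_types = 5, cells_per_type = 25,
                       n_genes = 50, n_pairs = 8)
  prof <- fixture_profile(fx)
  settings <- filter_settings()
  af <- autocrine_fractions(prof, fx$pairs, settings)
  # oracle: expressed = detection >= 0.2 (and mean > 0), straight loops
  expressed_in <- function(ct) {
    sub <- prof[prof$cell_type == ct &
                  prof$detection_fraction >= 0.2 & prof$mean_expr > 0, ]
    toupper(sub$gene)
  }
  for (ct in unique(af$cell_type)) {
    ex <- expressed_in(ct)
    ligs <- intersect(toupper(unique(fx$pairs$ligand)), ex)
    hits <- 0
    for (l in ligs) {
      partners <- toupper(fx$pairs$receptor[toupper(fx$pairs$ligand) == l])
      if (length(intersect(partners, ex)) > 0) hits <- hits + 1
    }
    want <- if (length(ligs) > 0) hits / length(ligs) else NA_real_
    expect_equal(af$ligand_fraction[af$cell_type == ct], want)
  }
  # invariant to gene and row order of the inputs
  prof_shuffled <- prof[rev(seq_len(nrow(prof))), ]
  attr(prof_shuffled, "cell_types") <- attr(prof, "cell_types")
  af2 <- autocrine_fractions(prof_shuffled, fx$pairs, settings)
  expect_equal(af, af2, ignore_attr = TRUE)
})

organ_map_abc <- tibble::tibble(
  cell_type = c("A", "B", "C"),
  organ = c("heart", "heart", "liver")
)

test_that("summary edges classify into autocrine/intra/inter-organ", {
  adj <- diag(3)
  dimnames(adj) <- list(c("A", "B", "C"), c("A", "B", "C"))
  net <- lrnet:::new_summary_network(adj, "edge_count")
  cls <- classify_summary_edges(net, organ_map_abc)
  lk <- function(s, r) cls$class[cls$sender == s & cls$receiver == r]
  expect_equal(lk("A", "A"), "autocrine")
  expect_equal(lk("A", "B"), "intra_organ")
  expect_equal(lk("A", "C"), "inter_organ")
  expect_error(classify_summary_edges(net, organ_map_abc[1:2, ]),
               class = "lrnet_value_error")
})

test_that("rank distributions put dominant autocrine entries at rank 1", {
  adj <- matrix(c(9, 1, 2, 1, 8, 2, 3, 1, 9), 3, 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  net <- lrnet:::new_summary_network(adj, "summed_specificity")
  rd <- rank_distributions(net, organ_map_abc, "outgoing")
  expect_equal(rd$mean_rank[rd$class == "autocrine"], 1)
  # all weights equal: every class shares the tied mean rank (n+1)/2
  flat <- lrnet:::new_summary_network(
    matrix(1, 3, 3, dimnames = dimnames(adj)), "summed_specificity")
  rdf <- rank_distributions(flat, organ_map_abc, "outgoing")
  expect_true(all(rdf$mean_rank == 2))
})

test_that("ranks match a brute-force sort and partition each row", {
  set.seed(8)
  types <- paste0("T", 1:8)
  adj <- matrix(stats::runif(64), 8, 8, dimnames = list(types, types))
  om <- tibble::tibble(cell_type = types,
                       organ = rep(c("o1", "o2"), each = 4))
  net <- lrnet:::new_summary_network(adj, "summed_specificity")
  for (direction in c("outgoing", "incoming")) {
    rd <- rank_distributions(net, om, direction)
    per_edge <- attr(rd, "per_edge")
    # class rank sets partition {1..8} within each cell type
    for (ct in types) {
      rks <- sort(per_edge$rank[per_edge$cell_type == ct])
      expect_equal(rks, 1:8)
    }
    # brute-force: recompute one cell type's ranks via order()
    w <- if (direction == "outgoing") adj["T3", ] else adj[, "T3"]
    expect_equal(per_edge$rank[per_edge$cell_type == "T3"],
                 unname(rank(-w)))
    expect_equal(sum(rd$n), 64)
  }
})

planted_autocrine_fixture <- function(seed = 71) {
  # four exclusive autocrine plants: ligand and receptor of pair i both
  # exclusive to CTi, so every planted edge is CTi -> CTi with top rank
  generate_fixture(fixture_config(
    n_cell_types = 4, cells_per_type = 30, n_genes = 60, n_pairs = 10,
    planted_edges = tibble::tibble(
      sender = paste0("CT", 1:4), receiver = paste0("CT", 1:4),
      effect_size = 10),
    seed = seed))
}

test_that("permutation null separates from planted autocrine structure", {
  fx <- planted_autocrine_fixture()
  prof <- fixture_profile(fx)
  edges <- extract_edges(prof, fx$pairs)
  net <- summed_weight_network(edges, "summed_specificity")
  obs <- rank_distributions(net, fx$organ_map, "outgoing")
  null <- permutation_rank_null(prof, fx$pairs, fx$organ_map,
                                n_perm = 30, seed = 72)
  obs_auto <- obs$mean_rank[obs$class == "autocrine"]
  null_auto <- null$mean_rank[null$class == "autocrine"]
  expect_lt(obs_auto, null_auto)
  # reproducible bitwise at fixed seed, even with one permutation
  n1 <- permutation_rank_null(prof, fx$pairs, fx$organ_map,
                              n_perm = 1, seed = 5)
  n2 <- permutation_rank_null(prof, fx$pairs, fx$organ_map,
                              n_perm = 1, seed = 5)
  expect_identical(n1, n2)
})

test_that("without planted structure the null matches the observed ranks", {
  fx <- random_fixture(73, n_cell_types = 4, cells_per_type = 30,
                       n_genes = 60, n_pairs = 10)
  prof <- fixture_profile(fx)
  edges <- extract_edges(prof, fx$pairs)
  net <- summed_weight_network(edges, "summed_specificity")
  obs <- rank_distributions(net, fx$organ_map, "outgoing")
  null <- permutation_rank_null(prof, fx$pairs, fx$organ_map,
                                n_perm = 30, seed = 74)
  gap <- abs(obs$mean_rank[obs$class == "autocrine"] -
               null$mean_rank[null$class == "autocrine"])
  spread <- max(null$sd_mean_rank[null$class == "autocrine"], 0.05)
  expect_lt(gap, 4 * spread)
})

test_that("clustering merges identical connectivity profiles first", {
  types <- c("A", "B", "C", "D")
  adj <- matrix(stats::runif(16, 1, 2), 4, 4,
                dimnames = list(types, types))
  adj["B", ] <- adj["A", ]
  adj[, "B"] <- adj[, "A"]
  net <- lrnet:::new_summary_network(adj, "summed_specificity")
  hc <- cluster_cell_types(net)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("A", "B"))
  expect_equal(hc$height[1], 0)
  expect_error(
    cluster_cell_types(lrnet:::new_summary_network(
      adj[1:2, 1:2], "summed_specificity")),
    class = "lrnet_value_error")
})

test_that("block-structured networks cluster into their two communities", {
  types <- paste0("T", 1:6)
  set.seed(9)
  adj <- matrix(stats::runif(36, 0, 0.05), 6, 6,
                dimnames = list(types, types))
  adj[1:3, 1:3] <- adj[1:3, 1:3] + 1   # community one
  adj[4:6, 4:6] <- adj[4:6, 4:6] + 1   # community two
  net <- lrnet:::new_summary_network(adj, "summed_specificity")
  hc <- cluster_cell_types(net)
  groups <- stats::cutree(hc, k = 2)
  expect_length(unique(groups[1:3]), 1L)
  expect_length(unique(groups[4:6]), 1L)
  expect_true(groups[1] != groups[4])
  # permuting input type order leaves the memberships unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  net_p <- lrnet:::new_summary_network(adj[perm, perm],
                                       "summed_specificity")
  gp <- stats::cutree(cluster_cell_types(net_p), k = 2)
  expect_equal(unname(gp[types] == gp["T1"]),
               unname(groups == groups["T1"]))
})
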