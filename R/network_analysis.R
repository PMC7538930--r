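#' Fraction of a cell type's ligands with a cognate receptor in the same type
#'
#' For each cell type, among the ligands it expresses (under the detection
#' and expression filters), what share have at least one cognate receptor
#' expressed by the same cell type -- and the reciprocal share for
#' receptors. High fractions indicate pervasive potential for autocrine
#' signalling. Cell types expressing no ligands (or receptors) get an `NA`
#' fraction rather than a 0/0. Across-type means are attached as the
#' `"mean_ligand_fraction"` and `"mean_receptor_fraction"` attributes.
#'
#' @param profile Cell-type profile from [summarise_cell_types()].
#' @param db Pair tibble.
#' @param settings [filter_settings()] deciding when a gene counts as
#'   expressed.
#' @return Tibble with one row per cell type: `cell_type`, `n_ligands`,
#'   `ligand_fraction`, `n_receptors`, `receptor_fraction`.
#' @export
autocrine_fractions <- function(profile, db, settings = filter_settings()) {
  pm <- profile_matrices(profile)
  pass <- pass_matrix(pm, settings)
  lig_key <- norm_symbol(db$ligand)
  rec_key <- norm_symbol(db$receptor)
  partners_of_ligand <- split(rec_key, lig_key)
  partners_of_receptor <- split(lig_key, rec_key)

  per_type <- lapply(pm$types, function(ct) {
    expressed <- pm$gene_key[pass[, ct]]
    ligs <- intersect(unique(lig_key), expressed)
    recs <- intersect(unique(rec_key), expressed)
    lig_hit <- vapply(ligs, function(l) {
      any(partners_of_ligand[[l]] %in% expressed)
    }, logical(1))
    rec_hit <- vapply(recs, function(r) {
      any(partners_of_receptor[[r]] %in% expressed)
    }, logical(1))
    tibble::tibble(
      cell_type = ct,
      n_ligands = length(ligs),
      ligand_fraction = if (length(ligs) > 0) mean(lig_hit) else NA_real_,
      n_receptors = length(recs),
      receptor_fraction = if (length(recs) > 0) mean(rec_hit) else NA_real_
    )
  })
  out <- dplyr::bind_rows(per_type)
  attr(out, "mean_ligand_fraction") <- mean(out$ligand_fraction, na.rm = TRUE)
  attr(out, "mean_receptor_fraction") <-
    mean(out$receptor_fraction, na.rm = TRUE)
  out
}

#' Read a cell-type to organ map
#'
#' Two tab-delimited columns: cell-type label, organ label.
#'
#' @param path Path to the table.
#' @return Tibble with columns `cell_type`, `organ`.
#' @export
read_organ_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) {
    lr_abort("organ map needs cell-type and organ columns",
             "lrnet_format_error")
  }
  tibble::tibble(cell_type = as.character(tab[[1L]]),
                 organ = as.character(tab[[2L]]))
}

organ_lookup <- function(organ_map, types) {
  o <- organ_map$organ[match(types, organ_map$cell_type)]
  if (anyNA(o)) {
    lr_abort(paste0("organ map missing cell type(s): ",
                    paste(utils::head(types[is.na(o)], 5L), collapse = ", ")),
             "lrnet_value_error")
  }
  stats::setNames(o, types)
}

#' Classify summary edges as autocrine, intra-organ or inter-organ
#'
#' An edge with sender equal to receiver is autocrine; otherwise it is
#' intra-organ when both cell types belong to the same organ and inter-organ
#' when they do not.
#'
#' @param net A `summary_network` (or anything with `cell_types`).
#' @param organ_map Tibble mapping `cell_type` to `organ`; must cover every
#'   cell type in the network.
#' @return Tibble with `sender`, `receiver`, `class` for every ordered
#'   cell-type pair.
#' @export
classify_summary_edges <- function(net, organ_map) {
  types <- net$cell_types
  organ <- organ_lookup(organ_map, types)
  grid <- expand.grid(sender = types, receiver = types,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cls <- ifelse(grid$sender == grid$receiver, "autocrine",
                ifelse(organ[grid$sender] == organ[grid$receiver],
                       "intra_organ", "inter_organ"))
  tibble::tibble(sender = grid$sender, receiver = grid$receiver,
                 class = cls)
}

#' Rank distributions of summary edges by class
#'
#' Within each cell type, its outgoing (row of the adjacency) or incoming
#' (column) summary edges are ranked descending by weight -- rank 1 is the
#' most specific partner, so an enriched class shows a numerically smaller
#' mean rank -- with ties given average ranks. Ranks are pooled across cell
#' types by edge class (autocrine / intra-organ / inter-organ) and
#' summarised. Ranks are pooled raw (not percentile-normalised): every cell
#' type faces the same candidate partner set, so rank ranges coincide.
#'
#' @param net A `summary_network`, conventionally summed-specificity.
#' @param organ_map Cell-type to organ tibble covering the network.
#' @param direction `"outgoing"` (rank each sender's receivers) or
#'   `"incoming"` (rank each receiver's senders).
#' @return Tibble with `class`, `direction`, `mean_rank`, `sd_rank`, `n`.
#' @export
rank_distributions <- function(net, organ_map,
                               direction = c("outgoing", "incoming")) {
  direction <- match.arg(direction)
  types <- net$cell_types
  organ <- organ_lookup(organ_map, types)
  adj <- net$adjacency
  rows <- lapply(types, function(ct) {
    w <- if (direction == "outgoing") adj[ct, ] else adj[, ct]
    partner <- names(w)
    rk <- rank(-w, ties.method = "average")
    cls <- ifelse(partner == ct, "autocrine",
                  ifelse(organ[partner] == organ[ct],
                         "intra_organ", "inter_organ"))
    tibble::tibble(cell_type = ct, partner = partner, rank = unname(rk),
                   class = cls)
  })
  pooled <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(pooled, .data$class),
    direction = direction,
    mean_rank = mean(.data$rank),
    sd_rank = stats::sd(.data$rank),
    n = dplyr::n(),
    .groups = "drop"
  )
  attr(out, "per_edge") <- pooled
  out
}

#' Permutation null for class rank distributions
#'
#' Rebuilds the summed-specificity summary network under `n_perm`
#' degree-preserving randomisations of the ligand-receptor assignment
#' ([randomise_pairs()]) and recomputes the class rank distributions each
#' time. If the specificity advantage of (say) autocrine edges depends on
#' which ligand actually binds which receptor, randomising the pairing
#' abolishes it, and the observed mean rank separates from this null.
#'
#' @param profile Cell-type profile.
#' @param db Pair tibble (>= 2 pairs).
#' @param organ_map Cell-type to organ tibble.
#' @param n_perm Number of randomised databases (the reference analysis uses
#'   100).
#' @param seed Integer seed; results are deterministic given it.
#' @param direction `"outgoing"` or `"incoming"`.
#' @param settings [filter_settings()] used for each rebuilt network.
#' @return Tibble with one row per class: `class`, `direction`,
#'   `mean_rank` (mean over permutations of the per-permutation mean rank),
#'   `sd_mean_rank` (sd of those means across permutations), `n_perm`.
#' @export
permutation_rank_null <- function(profile, db, organ_map, n_perm = 100,
                                  seed = 1L,
                                  direction = c("outgoing", "incoming"),
                                  settings = filter_settings()) {
  direction <- match.arg(direction)
  dbs <- randomise_pairs(db, n_perm, seed)
  per_perm <- lapply(seq_along(dbs), function(i) {
    edges <- extract_edges(profile, dbs[[i]], settings)
    net <- summed_weight_network(edges, "summed_specificity")
    rd <- rank_distributions(net, organ_map, direction)
    rd$perm <- i
    rd
  })
  all_rd <- dplyr::bind_rows(per_perm)
  out <- dplyr::summarise(
    dplyr::group_by(all_rd, .data$class),
    null_mean = mean(.data$mean_rank),
    sd_mean_rank = stats::sd(.data$mean_rank),
    .groups = "drop"
  )
  tibble::tibble(class = out$class, direction = direction,
                 mean_rank = out$null_mean,
                 sd_mean_rank = out$sd_mean_rank, n_perm = length(dbs))
}

#' Hierarchically cluster cell types by their connectivity vectors
#'
#' Represents each cell type by the concatenation of its outgoing row and
#' incoming column of summary weights and clusters the types
#' hierarchically. Default distance is 1 minus the Pearson correlation
#' between vectors (so types communicating with the same partners in the
#' same proportions merge early regardless of overall signal strength),
#' with average linkage; both are exposed as options. Identical vectors are
#' assigned distance exactly 0.
#'
#' @param net A `summary_network`, conventionally summed-specificity.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()];
#'   default `"average"`.
#' @return An [stats::hclust] object with cell-type labels.
#' @export
cluster_cell_types <- function(net, distance = c("correlation", "euclidean"),
                               linkage = "average") {
  distance <- match.arg(distance)
  types <- net$cell_types
  if (length(types) < 3L) {
    lr_abort("need at least 3 cell types to cluster", "lrnet_value_error")
  }
  x <- cbind(net$adjacency, t(net$adjacency))
  rownames(x) <- types
  if (distance == "euclidean") {
    d <- stats::dist(x)
  } else {
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[is.na(cc)] <- 0  # zero-variance vectors: no linear association
    dmat <- 1 - cc
    # identical vectors are distance 0 even when constant
    for (i in seq_len(nrow(x))) {
      same <- which(colSums(abs(t(x) - x[i, ])) == 0)
      dmat[i, same] <- 0
    }
    d <- stats::as.dist(dmat)
  }
  stats::hclust(d, method = linkage)
}
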