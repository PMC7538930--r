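#' Configuration for a synthetic single-cell communication fixture
#'
#' Describes a sparse genes x cells count matrix with cell-type structure and
#' optional planted communication signal. Background counts follow a
#' negative binomial with independent dropout (the minimal model giving
#' realistic sparsity and controllable detection fractions). A planted edge
#' dedicates one ligand-receptor pair: the ligand is expressed exclusively
#' in the sending cell type and the receptor exclusively in the receiving
#' one, at `effect_size` times the baseline mean, so the planted edge's
#' specificity weight is maximal for that pair. A planted co-detection
#' forces the pair's two genes jointly above threshold in an exact fraction
#' of one cell type's cells.
#'
#' @param n_cell_types Number of cell types (labelled `CT1`, `CT2`, ...).
#' @param cells_per_type Cells per type (scalar, recycled).
#' @param n_genes Total genes including background genes.
#' @param n_pairs Ligand-receptor pairs in the fixture database (ligands
#'   `LG01`..., receptors `RC01`..., pair i links `LGi` to `RCi`).
#' @param baseline_mean Negative-binomial mean of background expression.
#' @param dispersion Negative-binomial size parameter.
#' @param dropout_rate Probability an observed count is zeroed,
#'   independently per entry.
#' @param lr_dropout_rate Dropout applied to ligand/receptor genes
#'   (defaults to `dropout_rate`); lets tests silence the whole database
#'   without emptying cell libraries.
#' @param planted_edges `NULL` or a tibble with columns `sender`,
#'   `receiver`, `effect_size` (and optionally `ligand`, `receptor` naming
#'   the dedicated pair; otherwise pair i is assigned to planted row i).
#' @param planted_codetection `NULL` or a tibble with columns `cell_type`,
#'   `target_fraction` (and optionally `ligand`, `receptor`).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(n_cell_types = 4, cells_per_type = 50,
                           n_genes = 120, n_pairs = 12,
                           baseline_mean = 5, dispersion = 2,
                           dropout_rate = 0.3, lr_dropout_rate = NULL,
                           planted_edges = NULL,
                           planted_codetection = NULL, seed = 1L) {
  stopifnot(n_cell_types >= 1, cells_per_type >= 1, n_pairs >= 1,
            n_genes >= 2 * n_pairs, baseline_mean > 0, dispersion > 0,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type = as.integer(cells_per_type),
    n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
    baseline_mean = baseline_mean, dispersion = dispersion,
    dropout_rate = dropout_rate,
    lr_dropout_rate = lr_dropout_rate %||% dropout_rate,
    planted_edges = planted_edges,
    planted_codetection = planted_codetection,
    seed = as.integer(seed)
  ), class = "fixture_config")
}

pad_id <- function(prefix, i, width = 2) {
  sprintf(paste0(prefix, "%0", width, "d"), i)
}

#' Generate a synthetic fixture with known communication structure
#'
#' Draws the count matrix described by a [fixture_config()] and returns it
#' together with the annotation, the fixture pair database, a two-organ map
#' over the cell types, and a ground-truth manifest that
#' [fixture_truth_report()] converts into assertable expectations.
#'
#' Planted edges occupy dedicated pairs whose genes are silent outside their
#' home cell type, so at exclusivity the pair's only surviving edge is
#' sender to receiver with specificity weight 1. A gene cannot be planted
#' exclusively into two different home types; that contradiction raises an
#' error. Planted co-detections set a fixed positive count in exactly
#' `round(target_fraction * n_cells)` cells of the stated type (and zero
#' elsewhere), which stays far above any reasonable CPM threshold in these
#' small synthetic libraries.
#'
#' @param cfg A [fixture_config()].
#' @return A list with elements `expression` (raw-count matrix with gene
#'   rownames and cell colnames), `annotation`, `pairs`, `organ_map`, and
#'   `truth` (list of `planted_edges`, `planted_codetection`, `config`).
#' @export
generate_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  types <- paste0("CT", seq_len(cfg$n_cell_types))
  cells <- unlist(lapply(types, function(ct) {
    paste0(ct, "_c", sprintf("%03d", seq_len(cfg$cells_per_type)))
  }))
  ann <- cell_annotation(cells, rep(types, each = cfg$cells_per_type))

  ligands <- pad_id("LG", seq_len(cfg$n_pairs))
  receptors <- pad_id("RC", seq_len(cfg$n_pairs))
  n_bg <- cfg$n_genes - 2L * cfg$n_pairs
  background <- if (n_bg > 0L) pad_id("BG", seq_len(n_bg), 3) else character()
  genes <- c(ligands, receptors, background)
  db <- lr_pairs(ligands, receptors, location = "both", source = "fixture")

  planted <- cfg$planted_edges
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    if (nrow(planted) > cfg$n_pairs) {
      lr_abort("more planted edges than pairs in the fixture database")
    }
    if (!"ligand" %in% names(planted)) {
      planted$ligand <- ligands[seq_len(nrow(planted))]
      planted$receptor <- receptors[seq_len(nrow(planted))]
    }
    if (!"effect_size" %in% names(planted)) planted$effect_size <- 10
    bad <- setdiff(c(planted$sender, planted$receiver), types)
    if (length(bad) > 0L) {
      lr_abort(paste0("planted edge references unknown cell type: ",
                      paste(bad, collapse = ", ")))
    }
    # contradiction: one gene exclusive to two different home types
    homes <- rbind(
      data.frame(gene = planted$ligand, home = planted$sender),
      data.frame(gene = planted$receptor, home = planted$receiver)
    )
    homes <- unique(homes)
    if (anyDuplicated(homes$gene)) {
      lr_abort(paste0("gene(s) planted exclusively into two cell types: ",
                      paste(unique(homes$gene[duplicated(homes$gene)]),
                            collapse = ", ")))
    }
  }
  codet <- cfg$planted_codetection
  if (!is.null(codet)) {
    codet <- tibble::as_tibble(codet)
    if (!"ligand" %in% names(codet)) {
      # dedicate the last pairs, leaving early pairs for planted edges
      idx <- cfg$n_pairs - seq_len(nrow(codet)) + 1L
      codet$ligand <- ligands[idx]
      codet$receptor <- receptors[idx]
    }
  }

  # mean matrix gene x type: baseline everywhere, planted genes exclusive
  mu <- matrix(cfg$baseline_mean, length(genes), length(types),
               dimnames = list(genes, types))
  exclusive <- character()
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      for (side in list(c(planted$ligand[i], planted$sender[i]),
                        c(planted$receptor[i], planted$receiver[i]))) {
        mu[side[1L], ] <- 0
        mu[side[1L], side[2L]] <- cfg$baseline_mean * planted$effect_size[i]
      }
    }
    exclusive <- c(planted$ligand, planted$receptor)
  }
  codet_genes <- if (!is.null(codet)) unique(c(codet$ligand, codet$receptor))
                 else character()
  mu[codet_genes, ] <- 0  # co-detection genes are set deterministically

  with_seed(cfg$seed, {
    counts <- matrix(
      stats::rnbinom(length(genes) * length(cells),
                     mu = mu[, ann$cell_type, drop = FALSE],
                     size = cfg$dispersion),
      nrow = length(genes),
      dimnames = list(genes, cells)
    )
    is_lr <- rownames(counts) %in% c(ligands, receptors)
    drop_p <- ifelse(is_lr, cfg$lr_dropout_rate, cfg$dropout_rate)
    keep <- matrix(
      stats::rbinom(length(counts), 1L, 1 - rep(drop_p, length(cells))),
      nrow = length(genes)
    )
    counts <- counts * keep
  })
  if (!is.null(codet)) {
    for (i in seq_len(nrow(codet))) {
      ct_cells <- ann$cell[ann$cell_type == codet$cell_type[i]]
      k <- round(codet$target_fraction[i] * length(ct_cells))
      on_cells <- ct_cells[seq_len(k)]
      counts[codet$ligand[i], ct_cells] <- 0L
      counts[codet$receptor[i], ct_cells] <- 0L
      counts[codet$ligand[i], on_cells] <- 50L
      counts[codet$receptor[i], on_cells] <- 50L
    }
  }
  m <- as_expression_matrix(counts, scale = "raw_counts")

  organ_map <- tibble::tibble(
    cell_type = types,
    organ = paste0("ORG", 1L + (seq_along(types) - 1L) %/%
                     max(1L, ceiling(length(types) / 2)))
  )
  list(
    expression = m, annotation = ann, pairs = db, organ_map = organ_map,
    truth = list(planted_edges = planted, planted_codetection = codet,
                 exclusive_genes = exclusive, config = cfg)
  )
}

#' Translate a fixture's ground truth into assertable expectations
#'
#' @param fixture A [generate_fixture()] result.
#' @param settings The [filter_settings()] an analysis will use.
#' @param codetect_fraction Co-detection reporting threshold the analysis
#'   will use (default 0.20).
#' @return A list with `expected_edges` (tibble of sender, ligand, receptor,
#'   receiver rows that [extract_edges()] must recover for the planted
#'   pairs) and `expected_codetection` (planted co-detections whose target
#'   fraction reaches `codetect_fraction`, hence must be reported; those
#'   below it must be absent).
#' @export
fixture_truth_report <- function(fixture, settings = filter_settings(),
                                 codetect_fraction = 0.20) {
  planted <- fixture$truth$planted_edges
  expected_edges <- if (is.null(planted)) {
    tibble::tibble(sender = character(), ligand = character(),
                   receptor = character(), receiver = character())
  } else {
    tibble::tibble(sender = planted$sender, ligand = planted$ligand,
                   receptor = planted$receptor, receiver = planted$receiver)
  }
  codet <- fixture$truth$planted_codetection
  expected_codet <- if (is.null(codet)) {
    tibble::tibble(cell_type = character(), ligand = character(),
                   receptor = character(), target_fraction = numeric())
  } else {
    codet[codet$target_fraction >= codetect_fraction,
          c("cell_type", "ligand", "receptor", "target_fraction")]
  }
  list(expected_edges = expected_edges,
       expected_codetection = expected_codet)
}

#' Serialise a fixture to the plain-text formats the readers consume
#'
#' Writes the expression matrix, annotation, pair database and organ map of
#' a fixture into a directory using exactly the layouts read back by
#' [read_expression()], [read_cell_annotation()], [read_lr_pairs()] and
#' [read_organ_map()], enabling full round-trip tests of the text interface.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of the four file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, "expression.matrix.txt"),
    annotation = file.path(dir, "annotation.txt"),
    pairs = file.path(dir, "pairs.txt"),
    organ_map = file.path(dir, "organ_map.txt")
  )
  em <- tibble::as_tibble(fixture$expression, rownames = "Gene")
  readr::write_tsv(em, paths$expression, progress = FALSE)
  readr::write_tsv(
    tibble::tibble(Cell = fixture$annotation$cell,
                   Annotation = fixture$annotation$cell_type),
    paths$annotation, progress = FALSE)
  write_lr_pairs(fixture$pairs, paths$pairs)
  readr::write_tsv(
    tibble::tibble(`Cell type` = fixture$organ_map$cell_type,
                   Organ = fixture$organ_map$organ),
    paths$organ_map, progress = FALSE)
  invisible(paths)
}
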