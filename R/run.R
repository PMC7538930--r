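# End-to-end runs mirroring the shell workflow: extract -> (diff) ->
# visualise. Each run writes plain-text data files plus a JSON run log so a
# rerun on the same inputs is byte-identical apart from nothing (no
# timestamps are written into data files).

write_adjacency <- function(net, path) {
  tab <- tibble::as_tibble(signif(net$adjacency, 6),
                           rownames = "Sender")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

read_adjacency <- function(path, scheme, settings = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  new_summary_network(m, scheme, settings)
}

edge_file_columns <- c(
  "sender", "ligand", "ligand_mean", "ligand_total", "ligand_detection",
  "ligand_specificity", "receptor", "receptor_mean", "receptor_total",
  "receptor_detection", "receptor_specificity", "receiver",
  "mean_weight", "specificity_weight", "total_weight"
)

write_edge_file <- function(edges, path) {
  out <- edges[, edge_file_columns]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

read_edge_file <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  attr(edges, "cell_types") <-
    sort(unique(c(edges$sender, edges$receiver)))
  edges
}

schemes3 <- c("edge_count", "summed_specificity", "summed_expression")

#' Extract edges from expression files and write the standard output set
#'
#' The file-level entry point: reads an expression matrix, a cell
#' annotation and a ligand-receptor pair database, CPM-normalises raw
#' counts, summarises per cell type, extracts edges, and writes into
#' `out_dir`: the edge file (`Edges.tsv`), the per-cell-type
#' ligand/receptor profile (`CellTypeProfiles.tsv`), one adjacency matrix
#' per weighting scheme (`Network_<scheme>.tsv`), and a machine-readable
#' run log (`run_log.json` with settings, row counts and a database
#' checksum). For non-human data a homology table projects the database
#' into the target species first.
#'
#' @param em_file Path to the genes x cells expression matrix (TSV).
#' @param ann_file Path to the cell annotation (TSV).
#' @param out_dir Output directory, created if needed.
#' @param pairs_file Path to the pair database; either this or `pairs`.
#' @param pairs A pair tibble used directly (overrides `pairs_file`).
#' @param dialect Pair-file dialect for [read_lr_pairs()].
#' @param settings [filter_settings()].
#' @param scale Scale of the expression values on disk; raw counts are
#'   CPM-normalised, anything else is used as-is.
#' @param homology_file,target_taxon Optional homology table and taxon for
#'   cross-species projection of the pair database.
#' @return Invisibly, a list with the in-memory `profile`, `edges`,
#'   `networks` and output `paths`.
#' @export
run_extract_edges <- function(em_file, ann_file, out_dir,
                              pairs_file = NULL, pairs = NULL,
                              dialect = "connectomedb",
                              settings = filter_settings(),
                              scale = "raw_counts",
                              homology_file = NULL, target_taxon = NULL) {
  for (f in c(em_file, ann_file, pairs_file, homology_file)) {
    if (!is.null(f) && !file.exists(f)) {
      lr_abort(paste0("input file not found: ", f))
    }
  }
  if (is.null(pairs)) {
    if (is.null(pairs_file)) lr_abort("provide `pairs` or `pairs_file`")
    pairs <- read_lr_pairs(pairs_file, dialect = dialect)
  }
  if (!is.null(homology_file)) {
    if (is.null(target_taxon)) {
      lr_abort("`target_taxon` required with a homology table")
    }
    pairs <- map_orthologs(pairs, read_homology_table(homology_file),
                           target_taxon)
  }
  m <- read_expression(em_file, scale = scale)
  if (attr(m, "scale") == "raw_counts") m <- normalise_cpm(m)
  ann <- read_cell_annotation(ann_file)
  genes <- unique(c(pairs$ligand, pairs$receptor))
  profile <- summarise_cell_types(m, ann, genes)
  edges <- extract_edges(profile, pairs, settings)
  networks <- lapply(stats::setNames(schemes3, schemes3), function(s) {
    summary_network(edges, s, settings)
  })

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    edges = file.path(out_dir, "Edges.tsv"),
    profile = file.path(out_dir, "CellTypeProfiles.tsv"),
    log = file.path(out_dir, "run_log.json")
  )
  write_edge_file(edges, paths$edges)
  prof_out <- profile
  num <- vapply(prof_out, is.numeric, logical(1))
  prof_out[num] <- lapply(prof_out[num], signif, digits = 6)
  readr::write_tsv(prof_out, paths$profile, progress = FALSE)
  for (s in schemes3) {
    paths[[s]] <- file.path(out_dir, paste0("Network_", s, ".tsv"))
    write_adjacency(networks[[s]], paths[[s]])
  }
  db_file <- tempfile(fileext = ".tsv")
  write_lr_pairs(pairs, db_file)
  log <- list(
    tool = "lrnet", version = as.character(utils::packageVersion("lrnet")),
    settings = unclass(settings),
    n_pairs = nrow(pairs), n_cells = nrow(ann),
    n_cell_types = length(unique(ann$cell_type)),
    n_edges = nrow(edges),
    database_md5 = unname(tools::md5sum(db_file))
  )
  unlink(db_file)
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(profile = profile, edges = edges, networks = networks,
                 paths = paths))
}

#' Compare two extraction output folders and write delta networks
#'
#' Reads the edge files and adjacency matrices produced by
#' [run_extract_edges()] for a reference and a target condition, partitions
#' the edges into shared and condition-exclusive sets, and writes per
#' scheme both delta quantifications. Outputs in `out_dir`:
#' `Edges_shared.tsv`, `Edges_ref_only.tsv`, `Edges_target_only.tsv`, and
#' `Delta_<scheme>_<fold_change|difference>.tsv`.
#'
#' @param ref_dir,target_dir Output directories of [run_extract_edges()]
#'   for the two conditions (matching cell-type label sets).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the `delta_edges` object, the per-scheme
#'   `delta_networks`, and output `paths`.
#' @export
run_diff_edges <- function(ref_dir, target_dir, out_dir) {
  for (d in c(ref_dir, target_dir)) {
    if (!file.exists(file.path(d, "Edges.tsv"))) {
      lr_abort(paste0("no Edges.tsv under ", d,
                      " (not an extraction output folder?)"))
    }
  }
  ref_edges <- read_edge_file(file.path(ref_dir, "Edges.tsv"))
  tgt_edges <- read_edge_file(file.path(target_dir, "Edges.tsv"))
  delta <- match_edge_tables(ref_edges, tgt_edges)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    shared = file.path(out_dir, "Edges_shared.tsv"),
    ref_only = file.path(out_dir, "Edges_ref_only.tsv"),
    target_only = file.path(out_dir, "Edges_target_only.tsv")
  )
  readr::write_tsv(delta$shared, paths$shared, progress = FALSE)
  readr::write_tsv(delta$only_ref, paths$ref_only, progress = FALSE)
  readr::write_tsv(delta$only_target, paths$target_only, progress = FALSE)

  delta_networks <- list()
  for (s in schemes3) {
    ref_net <- read_adjacency(file.path(ref_dir,
                                        paste0("Network_", s, ".tsv")), s)
    tgt_net <- read_adjacency(file.path(target_dir,
                                        paste0("Network_", s, ".tsv")), s)
    for (mode in c("fold_change", "difference")) {
      dn <- delta_summary(ref_net, tgt_net, mode)
      key <- paste0(s, "_", mode)
      paths[[key]] <- file.path(out_dir, paste0("Delta_", key, ".tsv"))
      out <- tidy(dn)
      num <- vapply(out, is.numeric, logical(1))
      out[num] <- lapply(out[num], signif, digits = 6)
      readr::write_tsv(out, paths[[key]], progress = FALSE)
      delta_networks[[key]] <- dn
    }
  }
  invisible(list(delta_edges = delta, delta_networks = delta_networks,
                 paths = paths))
}

#' Render the standard visualisation set from an extraction folder
#'
#' Produces nine summary-network views (heatmap, network graph and circos
#' view for each of the three weighting schemes) and two top-k
#' ligand-receptor pair heatmaps (ranked by mean-expression weight with
#' row-max scaling, and by specificity weight). Every figure's underlying
#' numeric table is written next to it, so content is testable without
#' image comparison.
#'
#' @param source_dir Output directory of [run_extract_edges()].
#' @param out_dir Directory for figures and tables (default
#'   `<source_dir>/figures`).
#' @param top_k Pairs shown in the pair heatmaps (default 20).
#' @param device `"pdf"` (default) or `"png"`.
#' @param width,height Figure size in inches.
#' @return Invisibly, the vector of files written.
#' @export
run_visualise <- function(source_dir, out_dir = file.path(source_dir,
                                                          "figures"),
                          top_k = 20, device = c("pdf", "png"),
                          width = 6, height = 5) {
  device <- match.arg(device)
  edges_path <- file.path(source_dir, "Edges.tsv")
  if (!file.exists(edges_path)) {
    lr_abort(paste0("no Edges.tsv under ", source_dir))
  }
  edges <- read_edge_file(edges_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  save_plot <- function(p, stem) {
    f <- file.path(out_dir, paste0(stem, ".", device))
    ggplot2::ggsave(f, p, width = width, height = height, units = "in")
    written <<- c(written, f)
  }
  save_table <- function(tab, stem) {
    f <- file.path(out_dir, paste0(stem, ".tsv"))
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6)
    readr::write_tsv(tab, f, progress = FALSE)
    written <<- c(written, f)
  }

  for (s in schemes3) {
    net <- read_adjacency(file.path(source_dir,
                                    paste0("Network_", s, ".tsv")), s)
    save_plot(autoplot(net), paste0("heatmap_", s))
    save_plot(plot_network_graph(net), paste0("network_", s))
    save_plot(plot_circos(net), paste0("circos_", s))
    save_table(tidy(net, drop_zero = FALSE), paste0("heatmap_", s))
  }
  for (rb in c("mean_weight", "specificity_weight")) {
    tab <- top_pair_table(edges, rb, top_k)
    save_plot(plot_pair_heatmap(edges, rb, top_k),
              paste0("top_pairs_", rb))
    save_table(tab, paste0("top_pairs_", rb))
  }
  invisible(written)
}
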