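#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Directed heatmap of a cell-connectivity summary network
#'
#' Rows are sending cell types (ligand side), columns are receiving cell
#' types; the matrix is directed and generally asymmetric, which is the
#' point of drawing it this way.
#'
#' @param object A `summary_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot summary_network
#' @export
autoplot.summary_network <- function(object, ...) {
  long <- tidy(object, drop_zero = FALSE)
  long$sender <- factor(long$sender, levels = rev(object$cell_types))
  long$receiver <- factor(long$receiver, levels = object$cell_types)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$receiver, y = .data$sender,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$scheme) +
    ggplot2::labs(x = "receiving cell type (receptor)",
                  y = "sending cell type (ligand)",
                  title = paste0("Cell-connectivity summary (",
                                 gsub("_", " ", object$scheme), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Network-graph view of a summary network
#'
#' Cell types on a circle; each directed edge is a curve coloured by its
#' sending cell type with width proportional to the summary weight.
#' Autocrine edges are drawn as points on the node.
#'
#' @param net A `summary_network`.
#' @param top_n Draw only the `top_n` heaviest edges (default all nonzero).
#' @return A ggplot object.
#' @export
plot_network_graph <- function(net, top_n = Inf) {
  long <- tidy(net, drop_zero = TRUE)
  if (is.finite(top_n) && nrow(long) > top_n) {
    long <- long[seq_len(top_n), , drop = FALSE]
  }
  types <- net$cell_types
  theta <- seq(0, 2 * pi, length.out = length(types) + 1L)[seq_along(types)]
  pos <- tibble::tibble(cell_type = types,
                        x = cos(theta), y = sin(theta))
  long <- dplyr::left_join(long, pos, by = c(sender = "cell_type"))
  long <- dplyr::left_join(long, pos, by = c(receiver = "cell_type"),
                           suffix = c("", "_to"))
  loops <- long[long$sender == long$receiver, , drop = FALSE]
  arcs <- long[long$sender != long$receiver, , drop = FALSE]
  p <- ggplot2::ggplot() +
    ggplot2::geom_curve(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, colour = .data$sender,
                   linewidth = .data$weight),
      curvature = 0.2,
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(
      data = loops,
      ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12,
                   colour = .data$sender, size = .data$weight)) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = .data$x * 1.25, y = .data$y * 1.25,
                                    label = .data$cell_type), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal(xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Summary network (",
                                 gsub("_", " ", net$scheme), ")"))
  p
}

#' Circos-style chord view of a summary network
#'
#' Cell types as arcs around a circle, directed ribbons (drawn as tapered
#' segments) from sender to receiver with width proportional to weight.
#'
#' @param net A `summary_network`.
#' @param top_n Draw only the `top_n` heaviest edges (default all nonzero).
#' @return A ggplot object.
#' @export
plot_circos <- function(net, top_n = Inf) {
  long <- tidy(net, drop_zero = TRUE)
  if (is.finite(top_n) && nrow(long) > top_n) {
    long <- long[seq_len(top_n), , drop = FALSE]
  }
  types <- net$cell_types
  k <- length(types)
  centre <- (seq_len(k) - 1) * 2 * pi / k
  names(centre) <- types
  arc <- purrr::map_dfr(seq_len(k), function(i) {
    th <- seq(centre[i] - pi / k * 0.8, centre[i] + pi / k * 0.8,
              length.out = 20)
    tibble::tibble(cell_type = types[i], theta = th,
                   x = cos(th), y = sin(th))
  })
  chord <- dplyr::mutate(
    long,
    x = cos(centre[.data$sender]) * 0.95,
    y = sin(centre[.data$sender]) * 0.95,
    x_to = cos(centre[.data$receiver]) * 0.95,
    y_to = sin(centre[.data$receiver]) * 0.95
  )
  ggplot2::ggplot() +
    ggplot2::geom_path(data = arc,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$cell_type,
                                    colour = .data$cell_type),
                       linewidth = 3, lineend = "round") +
    ggplot2::geom_curve(
      data = chord[chord$sender != chord$receiver, , drop = FALSE],
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, colour = .data$sender,
                   linewidth = .data$weight),
      curvature = 0.4, alpha = 0.7) +
    ggplot2::geom_point(
      data = chord[chord$sender == chord$receiver, , drop = FALSE],
      ggplot2::aes(x = .data$x * 1.08, y = .data$y * 1.08,
                   colour = .data$sender, size = .data$weight)) +
    ggplot2::geom_text(
      data = dplyr::distinct(arc, .data$cell_type,
                             .keep_all = TRUE),
      ggplot2::aes(x = cos(centre[.data$cell_type]) * 1.22,
                   y = sin(centre[.data$cell_type]) * 1.22,
                   label = .data$cell_type), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2.5)) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Circos view (",
                                 gsub("_", " ", net$scheme), ")"))
}

#' Table behind a top-k ligand-receptor pair heatmap
#'
#' Ranks ligand-receptor pairs by the maximum of the chosen weight over all
#' (sender, receiver) combinations, keeps the top k, and lays their weights
#' out as pair x (sender -> receiver) columns. For the expression weighting
#' each row is scaled by its maximum (so the strongest cell-type pair reads
#' 1.0); specificity weights are already on \[0, 1\] and are left unscaled.
#'
#' @param edges Edge tibble from [extract_edges()].
#' @param rank_by `"mean_weight"` or `"specificity_weight"`.
#' @param k Number of pairs to keep (all available, with a warning, if
#'   fewer).
#' @return A long tibble with `ligand`, `receptor`, `sender`, `receiver`,
#'   `weight`, `scaled_weight`, `pair_rank`.
#' @export
top_pair_table <- function(edges, rank_by = c("mean_weight",
                                              "specificity_weight"),
                           k = 20) {
  rank_by <- match.arg(rank_by)
  if (nrow(edges) == 0L) lr_abort("empty edge table")
  pair_max <- dplyr::summarise(
    dplyr::group_by(edges, .data$ligand, .data$receptor),
    top = max(.data[[rank_by]]), .groups = "drop")
  pair_max <- dplyr::arrange(pair_max, dplyr::desc(.data$top),
                             .data$ligand, .data$receptor)
  if (k > nrow(pair_max)) {
    warning("only ", nrow(pair_max), " pair(s) available", call. = FALSE)
    k <- nrow(pair_max)
  }
  keep <- pair_max[seq_len(k), c("ligand", "receptor")]
  keep$pair_rank <- seq_len(k)
  out <- dplyr::inner_join(edges, keep, by = c("ligand", "receptor"))
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$ligand, .data$receptor),
    weight = .data[[rank_by]],
    scaled_weight = if (rank_by == "mean_weight") {
      .data$weight / max(.data$weight)
    } else {
      .data$weight
    }
  )
  dplyr::arrange(
    dplyr::ungroup(out)[, c("ligand", "receptor", "sender", "receiver",
                            "weight", "scaled_weight", "pair_rank")],
    .data$pair_rank, .data$sender, .data$receiver)
}

#' Heatmap of top-ranked ligand-receptor pairs
#'
#' @param edges Edge tibble from [extract_edges()].
#' @param rank_by `"mean_weight"` or `"specificity_weight"`.
#' @param k Number of pairs to display.
#' @return A ggplot object; the numeric table behind it comes from
#'   [top_pair_table()].
#' @export
plot_pair_heatmap <- function(edges, rank_by = c("mean_weight",
                                                 "specificity_weight"),
                              k = 20) {
  rank_by <- match.arg(rank_by)
  tab <- top_pair_table(edges, rank_by, k)
  tab$pair <- stats::reorder(paste(tab$ligand, tab$receptor, sep = " - "),
                             -tab$pair_rank)
  tab$ct_pair <- paste(tab$sender, tab$receiver, sep = " -> ")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$ct_pair, y = .data$pair,
                                    fill = .data$scaled_weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(
      name = if (rank_by == "mean_weight") "row-max scaled" else
        "specificity") +
    ggplot2::labs(x = "sender -> receiver", y = NULL,
                  title = paste0("Top ", max(tab$pair_rank),
                                 " pairs by ", gsub("_", " ", rank_by))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}

#' Heatmap of a delta network
#'
#' @param object A `delta_network` from [delta_summary()].
#' @param ... Unused.
#' @return A ggplot object showing the chosen change quantification
#'   (log2 fold change or signed difference) per (sender, receiver).
#' @method autoplot delta_network
#' @export
autoplot.delta_network <- function(object, ...) {
  s <- object$summary
  s$value <- if (object$mode == "fold_change") s$log2_fc else
    s$abs_difference
  types <- sort(unique(c(s$sender, s$receiver)))
  s$sender <- factor(s$sender, levels = rev(types))
  s$receiver <- factor(s$receiver, levels = types)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$receiver, y = .data$sender,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "white", high = "#2166ac",
      name = if (object$mode == "fold_change") "log2 FC" else "difference") +
    ggplot2::labs(x = "receiving cell type", y = "sending cell type",
                  title = paste0("Delta network (", object$scheme, ", ",
                                 gsub("_", " ", object$mode), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Observed vs permutation-null rank distributions
#'
#' @param observed Tibble from [rank_distributions()].
#' @param null Optional tibble from [permutation_rank_null()]; drawn dashed.
#' @return A ggplot object: mean rank per edge class with sd error bars
#'   (smaller rank = more specific).
#' @export
plot_rank_distributions <- function(observed, null = NULL) {
  observed$which <- "observed"
  dat <- observed
  if (!is.null(null)) {
    null$which <- "null"
    null$sd_rank <- null$sd_mean_rank
    dat <- dplyr::bind_rows(observed,
                            null[, c("class", "direction", "mean_rank",
                                     "sd_rank", "which")])
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$mean_rank,
                                    colour = .data$which,
                                    linetype = .data$which,
                                    group = .data$which)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rank - .data$sd_rank,
                   ymax = .data$mean_rank + .data$sd_rank),
      width = 0.2, position = ggplot2::position_dodge(0.3)) +
    ggplot2::scale_linetype_manual(values = c(observed = "solid",
                                              null = "dashed")) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(y = "mean rank (1 = most specific)", x = "edge class") +
    ggplot2::theme_minimal()
}
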