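new_summary_network <- function(adjacency, scheme, settings = NULL) {
  structure(
    list(adjacency = adjacency,
         cell_types = rownames(adjacency),
         scheme = scheme,
         settings = settings),
    class = "summary_network"
  )
}

#' @export
print.summary_network <- function(x, ...) {
  cat("<summary_network> scheme:", x$scheme, "|",
      length(x$cell_types), "cell types,",
      sum(x$adjacency > 0), "nonzero directed edges\n")
  invisible(x)
}

edge_cell_types <- function(edges) {
  attr(edges, "cell_types") %||%
    sort(unique(c(edges$sender, edges$receiver)))
}

#' Collapse an edge table into a directed cell-connectivity summary network
#'
#' Summarises all ligand-receptor edges between each ordered cell-type pair
#' into a single weight, yielding a directed (generally asymmetric)
#' cell-type x cell-type adjacency matrix with rows as senders (ligand side)
#' and columns as receivers. Three weighting schemes are supported:
#' `"edge_count"` counts the distinct ligand-receptor pairs whose edge
#' survives the thresholds in `settings`; `"summed_specificity"` sums the
#' specificity weights without any hard threshold; `"summed_expression"`
#' sums the mean-expression weights. Diagonal (autocrine) entries are
#' retained in all schemes.
#'
#' @param edges Edge tibble from [extract_edges()].
#' @param scheme One of `"edge_count"`, `"summed_specificity"`,
#'   `"summed_expression"`.
#' @param settings [filter_settings()] re-applied when counting edges
#'   (detection and expression thresholds on the stored per-gene columns,
#'   specificity threshold on the edge weight). Defaults to the settings the
#'   edge table was built with.
#' @return A `summary_network` object: adjacency matrix plus metadata. Use
#'   [tidy()][generics::tidy] for a long tibble and `autoplot()` for the
#'   directed heatmap.
#' @export
summary_network <- function(edges,
                            scheme = c("edge_count", "summed_specificity",
                                       "summed_expression"),
                            settings = NULL) {
  scheme <- match.arg(scheme)
  settings <- settings %||% attr(edges, "settings") %||% filter_settings()
  types <- edge_cell_types(edges)
  adj <- matrix(0, length(types), length(types),
                dimnames = list(types, types))
  if (scheme == "edge_count") {
    kept <- filter_edge_rows(edges, settings)
    if (nrow(kept) > 0L) {
      counts <- dplyr::summarise(
        dplyr::group_by(
          dplyr::distinct(kept, .data$sender, .data$receiver,
                          .data$ligand, .data$receptor),
          .data$sender, .data$receiver),
        n = dplyr::n(), .groups = "drop")
      adj[cbind(counts$sender, counts$receiver)] <- counts$n
    }
  } else {
    col <- if (scheme == "summed_specificity") "specificity_weight" else
      "mean_weight"
    if (nrow(edges) > 0L) {
      sums <- dplyr::summarise(
        dplyr::group_by(edges, .data$sender, .data$receiver),
        w = sum(.data[[col]]), .groups = "drop")
      adj[cbind(sums$sender, sums$receiver)] <- sums$w
    }
  }
  new_summary_network(adj, scheme, settings)
}

# Re-apply filter settings to already-extracted edge rows.
filter_edge_rows <- function(edges, settings) {
  det_ok <- function(d) {
    if (settings$strict_detection) d > settings$detection_threshold
    else d >= settings$detection_threshold
  }
  keep <- det_ok(edges$ligand_detection) & det_ok(edges$receptor_detection) &
    edges$ligand_mean >= settings$expression_threshold &
    edges$receptor_mean >= settings$expression_threshold &
    edges$specificity_weight >= settings$specificity_threshold
  edges[keep, , drop = FALSE]
}

#' @rdname summary_network
#' @export
edge_count_network <- function(edges, settings = NULL) {
  summary_network(edges, "edge_count", settings)
}

#' @rdname summary_network
#' @param weight_scheme `"summed_specificity"` or `"summed_expression"`.
#' @export
summed_weight_network <- function(edges,
                                  weight_scheme = c("summed_specificity",
                                                    "summed_expression")) {
  weight_scheme <- match.arg(weight_scheme)
  summary_network(edges, weight_scheme)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a summary network into a long edge tibble
#'
#' @param x A `summary_network`.
#' @param drop_zero Keep only nonzero entries (default `TRUE`).
#' @param ... Unused.
#' @return Tibble with columns `sender`, `receiver`, `weight`.
#' @method tidy summary_network
#' @export
tidy.summary_network <- function(x, drop_zero = TRUE, ...) {
  out <- tibble::tibble(
    sender = rep(rownames(x$adjacency), times = ncol(x$adjacency)),
    receiver = rep(colnames(x$adjacency), each = nrow(x$adjacency)),
    weight = as.vector(x$adjacency)
  )
  if (drop_zero) out <- out[out$weight > 0, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$weight), .data$sender,
                 .data$receiver)
}

#' One-row summary of a summary network
#'
#' @param x A `summary_network`.
#' @param ... Unused.
#' @return Tibble with the scheme, cell-type count, nonzero edge count and
#'   total weight.
#' @method glance summary_network
#' @export
glance.summary_network <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme,
    n_cell_types = length(x$cell_types),
    n_edges = sum(x$adjacency > 0),
    total_weight = sum(x$adjacency)
  )
}

#' Top-k directed summary edges
#'
#' The k highest-weight (sender, receiver) entries of a summary network,
#' autocrine entries included. Ties at the cut are broken deterministically
#' by (sender, receiver) lexicographic order.
#'
#' @param net A `summary_network`.
#' @param k Number of edges to return (`>= 1`). If fewer nonzero entries
#'   exist, all are returned with a warning.
#' @return Tibble with columns `sender`, `receiver`, `weight`, ranked.
#' @export
top_summary_edges <- function(net, k) {
  if (k < 1L) lr_abort("`k` must be >= 1")
  long <- tidy(net, drop_zero = TRUE)
  if (k > nrow(long)) {
    warning("only ", nrow(long), " nonzero summary edge(s) available",
            call. = FALSE)
    k <- nrow(long)
  }
  long[seq_len(k), , drop = FALSE]
}

#' Weakly connected communities of a directed summary edge list
#'
#' Cell types linked (in either direction) through a set of directed summary
#' edges form one community; self-loops are allowed, so a cell type whose
#' only edge is autocrine is its own community. Used to read off isolated
#' communication communities from e.g. the top-10 summed-specificity edges.
#'
#' @param edge_list Tibble/data frame with `sender` and `receiver` columns
#'   (e.g. from [top_summary_edges()]).
#' @return A list of character vectors (sorted node sets), ordered by first
#'   appearance of their smallest member.
#' @export
connected_communities <- function(edge_list) {
  if (nrow(edge_list) == 0L) lr_abort("empty edge list")
  g <- igraph::graph_from_data_frame(
    edge_list[, c("sender", "receiver")], directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, function(s) sort(unname(s)))
  names(sets) <- NULL
  sets[order(vapply(sets, `[`, "", 1L))]
}
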