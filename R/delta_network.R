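edge_key <- function(edges) {
  paste(edges$sender, norm_symbol(edges$ligand), norm_symbol(edges$receptor),
        edges$receiver, sep = "\r")
}

#' Partition two conditions' edge tables into shared and exclusive edges
#'
#' Edge identity is the (sender, ligand, receptor, receiver) 4-tuple;
#' weights play no part, matching the presence/absence reading of "detected
#' in both conditions". Both tables must have been built over the same
#' cell-type label set (the comparison assumes near-identical cellular
#' composition); otherwise an error asks for relabelling rather than
#' silently comparing incomparable networks.
#'
#' @param ref,target Edge tibbles from [extract_edges()] for the reference
#'   and target conditions.
#' @return A `delta_edges` object with elements `shared` (edges in both,
#'   reference weights plus `target_`-prefixed target weights), `only_ref`
#'   and `only_target`. `tidy()` stacks the three with a `status` column;
#'   `glance()` gives the counts.
#' @export
match_edge_tables <- function(ref, target) {
  t_ref <- edge_cell_types(ref)
  t_tgt <- edge_cell_types(target)
  if (!setequal(t_ref, t_tgt)) {
    lr_abort(paste0(
      "cell-type label sets differ between conditions (",
      paste(utils::head(setdiff(union(t_ref, t_tgt),
                                intersect(t_ref, t_tgt)), 5L),
            collapse = ", "),
      " ...); relabel the annotations so both conditions share one set"),
      "lrnet_value_error")
  }
  k_ref <- edge_key(ref)
  k_tgt <- edge_key(target)
  in_both_ref <- k_ref %in% k_tgt
  shared <- ref[in_both_ref, , drop = FALSE]
  tgt_match <- target[match(k_ref[in_both_ref], k_tgt), , drop = FALSE]
  for (col in c("mean_weight", "specificity_weight", "total_weight")) {
    shared[[paste0("target_", col)]] <- tgt_match[[col]]
  }
  structure(
    list(shared = tibble::as_tibble(shared),
         only_ref = tibble::as_tibble(ref[!in_both_ref, , drop = FALSE]),
         only_target = tibble::as_tibble(
           target[!(k_tgt %in% k_ref), , drop = FALSE]),
         cell_types = sort(t_ref)),
    class = "delta_edges"
  )
}

#' @export
print.delta_edges <- function(x, ...) {
  cat("<delta_edges>", nrow(x$shared), "shared |",
      nrow(x$only_ref), "reference-only |",
      nrow(x$only_target), "target-only\n")
  invisible(x)
}

#' @rdname match_edge_tables
#' @param x A `delta_edges` object.
#' @param ... Unused.
#' @method tidy delta_edges
#' @export
tidy.delta_edges <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$shared, status = "shared"),
    dplyr::mutate(x$only_ref, status = "only_ref"),
    dplyr::mutate(x$only_target, status = "only_target")
  )
}

#' @rdname match_edge_tables
#' @method glance delta_edges
#' @export
glance.delta_edges <- function(x, ...) {
  tibble::tibble(
    n_shared = nrow(x$shared),
    n_only_ref = nrow(x$only_ref),
    n_only_target = nrow(x$only_target),
    n_ref = nrow(x$shared) + nrow(x$only_ref),
    n_target = nrow(x$shared) + nrow(x$only_target)
  )
}

#' Delta network between two condition-matched summary networks
#'
#' Compares two summary networks of the same scheme over the same cell types
#' entry by entry, reporting both change quantifications: the signed
#' absolute difference (target minus reference) and the log2 fold change.
#' When both entries are positive the ratio is exact; a zero entry would
#' make it undefined, so those entries use a pseudocount of half the
#' smallest positive weight found in either network, giving exclusive
#' entries a large but finite, documented value. Entries at
#' least twofold higher in the reference are flagged `"up_in_ref"`
#' (log2 fold change <= -1), at least twofold higher in the target
#' `"up_in_target"`.
#'
#' Optionally, per-condition cell-population fractions are computed from the
#' two annotation tables and attached, so node-level composition shifts can
#' be reported next to the edge-level changes.
#'
#' @param ref_net,target_net `summary_network` objects with identical scheme
#'   and cell types.
#' @param mode Which quantification downstream display emphasises:
#'   `"fold_change"` (default) or `"difference"`. Both columns are always
#'   computed.
#' @param ref_annotation,target_annotation Optional annotation tibbles used
#'   to derive per-cell-type population fractions in each condition.
#' @return A `delta_network` object whose `summary` tibble has one row per
#'   (sender, receiver) with `weight_ref`, `weight_target`, `abs_difference`,
#'   `log2_fc` and `flag`; `tidy()` returns that tibble.
#' @export
delta_summary <- function(ref_net, target_net,
                          mode = c("fold_change", "difference"),
                          ref_annotation = NULL, target_annotation = NULL) {
  mode <- match.arg(mode)
  if (!identical(ref_net$scheme, target_net$scheme)) {
    lr_abort("summary networks use different weighting schemes",
             "lrnet_value_error")
  }
  if (!setequal(ref_net$cell_types, target_net$cell_types)) {
    lr_abort("summary networks cover different cell types",
             "lrnet_value_error")
  }
  types <- ref_net$cell_types
  a <- ref_net$adjacency[types, types]
  b <- target_net$adjacency[types, types]
  pos <- c(a[a > 0], b[b > 0])
  eps <- if (length(pos) > 0L) min(pos) / 2 else 1
  e <- ifelse(a > 0 & b > 0, 0, eps)  # exact ratio when defined
  lfc <- log2((b + e) / (a + e))
  flag <- ifelse(lfc <= -1, "up_in_ref",
                 ifelse(lfc >= 1, "up_in_target", "none"))
  summary <- tibble::tibble(
    sender = rep(types, times = length(types)),
    receiver = rep(types, each = length(types)),
    weight_ref = as.vector(a),
    weight_target = as.vector(b),
    abs_difference = as.vector(b - a),
    log2_fc = as.vector(lfc),
    flag = as.vector(flag)
  )
  fractions <- NULL
  if (!is.null(ref_annotation) && !is.null(target_annotation)) {
    frac <- function(ann, cond) {
      tab <- table(ann$cell_type)
      tibble::tibble(cell_type = names(tab),
                     fraction = as.numeric(tab) / sum(tab),
                     condition = cond)
    }
    fractions <- dplyr::bind_rows(frac(ref_annotation, "ref"),
                                  frac(target_annotation, "target"))
  }
  structure(
    list(summary = summary, mode = mode, scheme = ref_net$scheme,
         pseudocount = eps, cell_fractions = fractions),
    class = "delta_network"
  )
}

#' @export
print.delta_network <- function(x, ...) {
  cat("<delta_network> scheme:", x$scheme, "| mode:", x$mode, "|",
      sum(x$summary$flag != "none"), "twofold-flagged entries\n")
  invisible(x)
}

#' @rdname delta_summary
#' @param x A `delta_network`.
#' @param ... Unused.
#' @method tidy delta_network
#' @export
tidy.delta_network <- function(x, ...) x$summary

#' @rdname delta_summary
#' @method glance delta_network
#' @export
glance.delta_network <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, mode = x$mode,
    n_up_in_ref = sum(x$summary$flag == "up_in_ref"),
    n_up_in_target = sum(x$summary$flag == "up_in_target"),
    pseudocount = x$pseudocount
  )
}

#' Involvement of focus cell types in condition-exclusive edges
#'
#' For each exclusive edge set of a [match_edge_tables()] result, counts the
#' edges whose sender OR receiver belongs to `focus_types` (e.g. T and B
#' cells when asking how much of an ageing signature is lymphocyte
#' signalling) and reports the fraction of that set.
#'
#' @param delta A `delta_edges` object.
#' @param focus_types Non-empty character vector of cell-type labels, a
#'   subset of the conditions' label set.
#' @return Tibble with one row per exclusive set: `set`, `n_edges`,
#'   `n_involved`, `fraction`.
#' @export
edge_class_involvement <- function(delta, focus_types) {
  if (length(focus_types) == 0L) lr_abort("empty focus cell-type set")
  bad <- setdiff(focus_types, delta$cell_types)
  if (length(bad) > 0L) {
    lr_abort(paste0("focus type(s) not in the label set: ",
                    paste(bad, collapse = ", ")), "lrnet_value_error")
  }
  one <- function(edges, label) {
    inv <- edges$sender %in% focus_types | edges$receiver %in% focus_types
    tibble::tibble(set = label, n_edges = nrow(edges),
                   n_involved = sum(inv),
                   fraction = if (nrow(edges) > 0) mean(inv) else NA_real_)
  }
  dplyr::bind_rows(one(delta$only_ref, "only_ref"),
                   one(delta$only_target, "only_target"))
}

#' Per-gene mean-expression fold changes within one cell type
#'
#' Log2 fold change of mean expression (target over reference) for a set of
#' genes in one cell type, used to name the ligands and receptors driving a
#' summary-edge change. When both means are positive the ratio is exact;
#' when either is zero a pseudocount keeps the value finite -- by default
#' half the smallest positive mean among the genes considered (the same
#' zero-handling rule as [delta_summary()]). Genes absent from a profile
#' follow the mean-0 convention.
#'
#' @param ref_profile,target_profile Profiles from [summarise_cell_types()].
#' @param cell_type The cell type to compare within.
#' @param genes Character vector of gene symbols.
#' @param eps Pseudocount used when a mean is zero; `NULL` (default) derives
#'   it as above.
#' @return Tibble with `gene`, `mean_ref`, `mean_target`, `log2_fc`.
#' @export
per_gene_fold_changes <- function(ref_profile, target_profile, cell_type,
                                  genes, eps = NULL) {
  get_means <- function(profile) {
    sub <- profile[profile$cell_type == cell_type, , drop = FALSE]
    if (nrow(sub) == 0L) {
      lr_abort(paste0("unknown cell type: ", cell_type), "lrnet_value_error")
    }
    m <- sub$mean_expr[match(norm_symbol(genes), norm_symbol(sub$gene))]
    m[is.na(m)] <- 0
    m
  }
  r <- get_means(ref_profile)
  t <- get_means(target_profile)
  if (is.null(eps)) {
    pos <- c(r[r > 0], t[t > 0])
    eps <- if (length(pos) > 0L) min(pos) / 2 else 1
  }
  e <- ifelse(r > 0 & t > 0, 0, eps)
  tibble::tibble(
    gene = genes, mean_ref = r, mean_target = t,
    log2_fc = log2((t + e) / (r + e))
  )
}
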