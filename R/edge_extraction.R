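# Per-gene, per-cell-type matrices backing the edge computations.
# spec[g, ct] = mean[g, ct] / sum_c mean[g, c], with 0 when the gene is
# silent in every cell type (the 0/0 case propagates no NaN).
profile_matrices <- function(profile) {
  genes <- unique(profile$gene)
  types <- attr(profile, "cell_types") %||% sort(unique(profile$cell_type))
  shape <- function(col) {
    m <- matrix(0, nrow = length(genes), ncol = length(types),
                dimnames = list(genes, types))
    m[cbind(match(profile$gene, genes), match(profile$cell_type, types))] <-
      profile[[col]]
    m
  }
  mean_m <- shape("mean_expr")
  tot <- rowSums(mean_m)
  spec <- mean_m / ifelse(tot > 0, tot, 1)
  spec[tot == 0, ] <- 0
  n_cells <- profile$n_cells[match(types, profile$cell_type)]
  list(mean = mean_m, total = shape("total_expr"),
       detection = shape("detection_fraction"), spec = spec,
       genes = genes, gene_key = norm_symbol(genes), types = types,
       n_cells = stats::setNames(n_cells, types))
}

lookup_gene_row <- function(pm, gene) {
  i <- match(norm_symbol(gene), pm$gene_key)
  i  # NA when the gene is not profiled; callers treat that as unexpressed
}

check_cell_type <- function(pm, ct) {
  if (!ct %in% pm$types) {
    lr_abort(paste0("unknown cell type: ", ct), "lrnet_value_error")
  }
}

#' Specificity weight of one candidate edge
#'
#' The specificity of a gene in a cell type is its mean expression divided by
#' the sum of its mean expression across all cell types in the dataset; the
#' edge weight is the product of the ligand's specificity in the sender and
#' the receptor's specificity in the receiver. It ranges from 0 to 1, where 1
#' means both genes are each expressed in exactly one cell type. A gene
#' silent in every cell type contributes 0 (not NaN). The denominator runs
#' over all cell types, including ones failing detection filters: specificity
#' is a property of the dataset, not of the filtered network.
#'
#' @param profile Cell-type profile from [summarise_cell_types()].
#' @param ligand,receptor Gene symbols.
#' @param sender,receiver Cell-type labels (must exist in the profile).
#' @return A weight in \[0, 1\].
#' @export
specificity_weight <- function(profile, ligand, receptor, sender, receiver) {
  pm <- profile_matrices(profile)
  check_cell_type(pm, sender); check_cell_type(pm, receiver)
  li <- lookup_gene_row(pm, ligand); ri <- lookup_gene_row(pm, receptor)
  ls <- if (is.na(li)) 0 else pm$spec[li, sender]
  rs <- if (is.na(ri)) 0 else pm$spec[ri, receiver]
  unname(ls * rs)
}

#' Mean-expression weight of one candidate edge
#'
#' Product of the ligand's mean expression in the sending cell type and the
#' receptor's mean expression in the receiving cell type
#' (expression-units squared). Emphasises highly expressed interactions
#' without discriminating cell-type-specific from housekeeping signalling.
#'
#' @inheritParams specificity_weight
#' @return A non-negative weight; genes absent from the profile count as
#'   mean 0.
#' @export
mean_expression_weight <- function(profile, ligand, receptor,
                                   sender, receiver) {
  pm <- profile_matrices(profile)
  check_cell_type(pm, sender); check_cell_type(pm, receiver)
  li <- lookup_gene_row(pm, ligand); ri <- lookup_gene_row(pm, receptor)
  lm <- if (is.na(li)) 0 else pm$mean[li, sender]
  rm_ <- if (is.na(ri)) 0 else pm$mean[ri, receiver]
  unname(lm * rm_)
}

#' Total-expression weight of one candidate edge
#'
#' Product of the summed expression of the ligand over the sender's cells and
#' of the receptor over the receiver's cells. Unlike the mean weight this
#' acknowledges cell-type abundance: 500 cells at mean 10 CPM contribute a
#' total of 5000 and can outweigh 10 cells at mean 80 CPM (total 800). It
#' equals the mean weight times the two population sizes, and assumes the
#' sampling of cells is representative.
#'
#' @inheritParams specificity_weight
#' @return A non-negative weight.
#' @export
total_expression_weight <- function(profile, ligand, receptor,
                                    sender, receiver) {
  pm <- profile_matrices(profile)
  check_cell_type(pm, sender); check_cell_type(pm, receiver)
  li <- lookup_gene_row(pm, ligand); ri <- lookup_gene_row(pm, receptor)
  lt <- if (is.na(li)) 0 else pm$total[li, sender]
  rt <- if (is.na(ri)) 0 else pm$total[ri, receiver]
  unname(lt * rt)
}

# gene x cell-type pass matrix under the detection/expression thresholds
pass_matrix <- function(pm, settings) {
  det_ok <- if (settings$strict_detection) {
    pm$detection > settings$detection_threshold
  } else {
    pm$detection >= settings$detection_threshold
  }
  expr_ok <- pm$mean >= settings$expression_threshold & pm$mean > 0
  det_ok & expr_ok
}

#' Extract all ligand-receptor edges between cell types
#'
#' For every pair in the database and every ordered (sender, receiver)
#' cell-type combination -- including sender = receiver, the autocrine case
#' -- an edge is emitted when the ligand passes the detection and expression
#' filters in the sender and the receptor passes them in the receiver
#' (independently; there is no joint criterion). Each edge carries the
#' per-gene summaries and all three weights: `mean_weight` (product of
#' means), `specificity_weight` (product of specificities, in \[0, 1\]) and
#' `total_weight` (product of totals). Edges below
#' `settings$specificity_threshold` are removed.
#'
#' @param profile Cell-type profile from [summarise_cell_types()], built over
#'   the database's gene universe.
#' @param db Pair tibble ([lr_pairs()]).
#' @param settings [filter_settings()].
#' @return An edge tibble with one row per (sender, ligand, receptor,
#'   receiver), columns for both genes' mean/total/detection/specificity and
#'   the three edge weights; attributes `"cell_types"` and `"settings"`
#'   record provenance.
#' @export
extract_edges <- function(profile, db, settings = filter_settings()) {
  if (nrow(db) == 0L) lr_abort("empty pair database")
  if (nrow(profile) == 0L) lr_abort("empty cell-type profile")
  pm <- profile_matrices(profile)
  pass <- pass_matrix(pm, settings)
  nt <- length(pm$types)

  per_pair <- function(k) {
    li <- lookup_gene_row(pm, db$ligand[k])
    ri <- lookup_gene_row(pm, db$receptor[k])
    if (is.na(li) || is.na(ri)) return(NULL)
    senders <- pm$types[pass[li, ]]
    receivers <- pm$types[pass[ri, ]]
    if (length(senders) == 0L || length(receivers) == 0L) return(NULL)
    grid <- expand.grid(sender = senders, receiver = receivers,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    tibble::tibble(
      sender = grid$sender,
      ligand = pm$genes[li],
      receptor = pm$genes[ri],
      receiver = grid$receiver,
      ligand_mean = unname(pm$mean[li, grid$sender]),
      ligand_total = unname(pm$total[li, grid$sender]),
      ligand_detection = unname(pm$detection[li, grid$sender]),
      ligand_specificity = unname(pm$spec[li, grid$sender]),
      receptor_mean = unname(pm$mean[ri, grid$receiver]),
      receptor_total = unname(pm$total[ri, grid$receiver]),
      receptor_detection = unname(pm$detection[ri, grid$receiver]),
      receptor_specificity = unname(pm$spec[ri, grid$receiver])
    )
  }
  edges <- dplyr::bind_rows(lapply(seq_len(nrow(db)), per_pair))
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(
      sender = character(), ligand = character(), receptor = character(),
      receiver = character(), ligand_mean = numeric(),
      ligand_total = numeric(), ligand_detection = numeric(),
      ligand_specificity = numeric(), receptor_mean = numeric(),
      receptor_total = numeric(), receptor_detection = numeric(),
      receptor_specificity = numeric()
    )
  }
  edges <- dplyr::mutate(
    edges,
    mean_weight = .data$ligand_mean * .data$receptor_mean,
    specificity_weight = .data$ligand_specificity * .data$receptor_specificity,
    total_weight = .data$ligand_total * .data$receptor_total
  )
  if (settings$specificity_threshold > 0) {
    edges <- edges[edges$specificity_weight >= settings$specificity_threshold,
                   , drop = FALSE]
  }
  attr(edges, "cell_types") <- pm$types
  attr(edges, "settings") <- settings
  edges
}

#' Ligand-receptor pairs co-detected within individual cells
#'
#' Self-signalling, as opposed to cell-type-level autocrine signalling,
#' requires a ligand and its receptor to be expressed in the same single
#' cell. For each cell type, this reports the pairs whose ligand AND receptor
#' both exceed `expr_threshold` in at least `codetect_fraction` of that
#' type's cells (the AND is evaluated cell by cell, so a ligand in one half
#' of the cells and the receptor in the other half co-detects in none).
#'
#' @param m Expression matrix; should be CPM when `expr_threshold` is stated
#'   in CPM.
#' @param annotation Cell annotation tibble.
#' @param db Pair tibble.
#' @param expr_threshold Per-cell expression cutoff (strict `>`); default
#'   10 (CPM).
#' @param codetect_fraction Minimum fraction of cells with joint detection
#'   for the pair to be reported; default 0.20.
#' @return Tibble with columns `cell_type`, `ligand`, `receptor`,
#'   `co_detection_fraction`, one row per reported (cell type, pair).
#' @export
codetect_pairs <- function(m, annotation, db, expr_threshold = 10,
                           codetect_fraction = 0.20) {
  unknown <- setdiff(annotation$cell, colnames(m))
  if (length(unknown) > 0L) {
    lr_abort(paste0("annotation references unknown cell(s): ",
                    paste(utils::head(unknown, 5L), collapse = ", ")),
             "lrnet_value_error")
  }
  row_key <- norm_symbol(rownames(m))
  li <- match(norm_symbol(db$ligand), row_key)
  ri <- match(norm_symbol(db$receptor), row_key)
  usable <- which(!is.na(li) & !is.na(ri))
  types <- sort(unique(annotation$cell_type))
  above <- m > expr_threshold

  out <- lapply(types, function(ct) {
    cells <- annotation$cell[annotation$cell_type == ct]
    sub <- above[, cells, drop = FALSE]
    frac <- rowMeans(sub[li[usable], , drop = FALSE] &
                       sub[ri[usable], , drop = FALSE])
    keep <- frac >= codetect_fraction
    tibble::tibble(
      cell_type = ct,
      ligand = db$ligand[usable][keep],
      receptor = db$receptor[usable][keep],
      co_detection_fraction = unname(frac[keep])
    )
  })
  dplyr::bind_rows(out)
}
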