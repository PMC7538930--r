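# Brute-force reference implementations, written independently of the
# package internals: explicit loops over cells, genes and cell-type pairs.
# They are deliberately slow and simple.

# Per (gene, type) summaries by looping over cells one at a time.
oracle_profile <- function(m, ann, genes) {
  types <- sort(unique(ann$cell_type))
  out <- list()
  for (g in genes) {
    row <- match(toupper(trimws(g)), toupper(trimws(rownames(m))))
    for (ct in types) {
      cells <- ann$cell[ann$cell_type == ct]
      vals <- numeric(length(cells))
      if (!is.na(row)) {
        for (j in seq_along(cells)) vals[j] <- m[row, cells[j]]
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = g, cell_type = ct,
        mean_expr = sum(vals) / length(vals),
        total_expr = sum(vals),
        detection_fraction = sum(vals > 0) / length(vals),
        n_cells = length(cells)
      )
    }
  }
  do.call(rbind, out)
}

# Exhaustive edge enumeration over (pair x type x type) with the filters.
oracle_edges <- function(m, ann, db, detection_threshold = 0.2,
                         expression_threshold = 0,
                         specificity_threshold = 0,
                         strict_detection = FALSE) {
  genes <- unique(c(db$ligand, db$receptor))
  prof <- oracle_profile(m, ann, genes)
  types <- sort(unique(ann$cell_type))
  get <- function(g, ct, col) {
    prof[prof$gene == g & prof$cell_type == ct, col]
  }
  spec_of <- function(g, ct) {
    tot <- sum(sapply(types, function(c2) get(g, c2, "mean_expr")))
    if (tot == 0) return(0)
    get(g, ct, "mean_expr") / tot
  }
  passes <- function(g, ct) {
    det <- get(g, ct, "detection_fraction")
    mu <- get(g, ct, "mean_expr")
    det_ok <- if (strict_detection) det > detection_threshold else
      det >= detection_threshold
    det_ok && mu >= expression_threshold && mu > 0
  }
  rows <- list()
  for (k in seq_len(nrow(db))) {
    L <- db$ligand[k]; R <- db$receptor[k]
    if (is.na(match(toupper(L), toupper(rownames(m)))) ||
        is.na(match(toupper(R), toupper(rownames(m))))) next
    for (s in types) {
      if (!passes(L, s)) next
      for (r in types) {
        if (!passes(R, r)) next
        sw <- spec_of(L, s) * spec_of(R, r)
        if (sw < specificity_threshold) next
        rows[[length(rows) + 1L]] <- data.frame(
          sender = s, ligand = L, receptor = R, receiver = r,
          mean_weight = get(L, s, "mean_expr") * get(R, r, "mean_expr"),
          specificity_weight = sw,
          total_weight = get(L, s, "total_expr") * get(R, r, "total_expr")
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sender = character(), ligand = character(),
                      receptor = character(), receiver = character(),
                      mean_weight = numeric(),
                      specificity_weight = numeric(),
                      total_weight = numeric()))
  }
  do.call(rbind, rows)
}

# Count distinct pairs per ordered type pair from an oracle edge frame.
oracle_edge_count_matrix <- function(oe, types) {
  adj <- matrix(0, length(types), length(types),
                dimnames = list(types, types))
  seen <- character()
  for (i in seq_len(nrow(oe))) {
    key <- paste(oe$sender[i], oe$receiver[i], oe$ligand[i],
                 oe$receptor[i])
    if (key %in% seen) next
    seen <- c(seen, key)
    adj[oe$sender[i], oe$receiver[i]] <-
      adj[oe$sender[i], oe$receiver[i]] + 1
  }
  adj
}

oracle_summed_matrix <- function(oe, types, col) {
  adj <- matrix(0, length(types), length(types),
                dimnames = list(types, types))
  for (i in seq_len(nrow(oe))) {
    adj[oe$sender[i], oe$receiver[i]] <-
      adj[oe$sender[i], oe$receiver[i]] + oe[[col]][i]
  }
  adj
}

# Per-cell AND-mask co-detection count.
oracle_codetect <- function(m, ann, db, expr_threshold, codetect_fraction) {
  types <- sort(unique(ann$cell_type))
  rows <- list()
  for (ct in types) {
    cells <- ann$cell[ann$cell_type == ct]
    for (k in seq_len(nrow(db))) {
      li <- match(toupper(db$ligand[k]), toupper(rownames(m)))
      ri <- match(toupper(db$receptor[k]), toupper(rownames(m)))
      if (is.na(li) || is.na(ri)) next
      n_co <- 0L
      for (cell in cells) {
        if (m[li, cell] > expr_threshold && m[ri, cell] > expr_threshold) {
          n_co <- n_co + 1L
        }
      }
      frac <- n_co / length(cells)
      if (frac >= codetect_fraction) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell_type = ct, ligand = db$ligand[k],
          receptor = db$receptor[k], co_detection_fraction = frac)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# Shared/exclusive partition by explicit set operations on key strings.
oracle_match_counts <- function(ref_keys, target_keys) {
  c(shared = length(intersect(ref_keys, target_keys)),
    only_ref = length(setdiff(ref_keys, target_keys)),
    only_target = length(setdiff(target_keys, ref_keys)))
}

# Union-find over an undirected reading of directed edges.
oracle_components <- function(senders, receivers) {
  nodes <- unique(c(senders, receivers))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(senders)) {
    a <- find(senders[i]); b <- find(receivers[i])
    if (a != b) parent[[a]] <- b
  }
  groups <- split(nodes, vapply(nodes, find, ""))
  groups <- lapply(groups, function(g) sort(unname(g)))
  names(groups) <- NULL
  groups[order(vapply(groups, `[`, "", 1L))]
}
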