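#' Read a genes x cells expression matrix from delimited text
#'
#' Expects tab-delimited text (gzip accepted) with the first column holding
#' gene symbols and the header row holding cell identifiers. Duplicate gene
#' rows (after case-insensitive symbol normalisation) are collapsed by
#' summation with a warning; negative entries are rejected.
#'
#' @param path Path to the matrix file.
#' @param scale What the values are: `"raw_counts"` (default), `"cpm"`, or
#'   `"other_normalised"`. Recorded as the `"scale"` attribute and checked by
#'   [normalise_cpm()].
#' @return A numeric matrix (genes x cells) with gene symbols as rownames,
#'   cell ids as colnames, and a `"scale"` attribute.
#' @export
read_expression <- function(path,
                            scale = c("raw_counts", "cpm",
                                      "other_normalised")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) lr_abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0L) {
    lr_abort(paste0("malformed expression file (", nrow(probs),
                    " parsing problem(s), first at row ", probs$row[1L], ")"),
             "lrnet_format_error")
  }
  if (ncol(tab) < 2L) {
    lr_abort("expression file needs a gene column plus at least one cell",
             "lrnet_format_error")
  }
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    lr_abort("non-numeric expression values", "lrnet_format_error")
  }
  rownames(m) <- genes
  as_expression_matrix(m, scale = scale)
}

#' Validate and normalise an in-memory expression matrix
#'
#' @param m Numeric matrix, genes in rows (rownames = symbols), cells in
#'   columns (colnames = cell ids).
#' @param scale Value scale; see [read_expression()].
#' @return The matrix with duplicate gene rows collapsed by sum and a
#'   `"scale"` attribute set.
#' @export
as_expression_matrix <- function(m, scale = c("raw_counts", "cpm",
                                              "other_normalised")) {
  scale <- match.arg(scale)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    lr_abort("expression matrix needs gene rownames and cell colnames",
             "lrnet_format_error")
  }
  if (anyNA(m)) lr_abort("missing values in expression matrix",
                         "lrnet_value_error")
  if (any(m < 0)) lr_abort("negative expression values",
                           "lrnet_value_error")
  if (anyDuplicated(colnames(m))) {
    lr_abort("duplicated cell identifiers", "lrnet_format_error")
  }
  key <- norm_symbol(rownames(m))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicated gene row(s) collapsed by sum",
            call. = FALSE)
    keep_names <- rownames(m)[!duplicated(key)]
    m <- rowsum(m, group = factor(key, levels = unique(key)))
    rownames(m) <- keep_names
  }
  attr(m, "scale") <- scale
  m
}

#' Normalise raw counts to counts per million (CPM)
#'
#' Scales each cell (column) so its values sum to one million. Library size
#' is computed over all genes in the matrix, not only ligands and receptors,
#' because sequencing depth is a whole-transcriptome property of the cell.
#'
#' @param m Expression matrix with `scale = "raw_counts"`.
#' @param allow_normalised If `TRUE`, a matrix already on the CPM scale is
#'   returned unchanged instead of raising an error.
#' @return The matrix rescaled so each column sums to 1e6; `scale = "cpm"`.
#' @export
normalise_cpm <- function(m, allow_normalised = FALSE) {
  sc <- attr(m, "scale") %||% "raw_counts"
  if (sc == "cpm") {
    if (allow_normalised) return(m)
    lr_abort("matrix is already CPM-normalised (set allow_normalised = TRUE to pass through)")
  }
  libsize <- colSums(m)
  if (any(libsize == 0)) {
    lr_abort(paste0("all-zero cell column(s): ",
                    paste(utils::head(colnames(m)[libsize == 0], 5L),
                          collapse = ", ")),
             "lrnet_value_error")
  }
  out <- sweep(m, 2L, 1e6 / libsize, `*`)
  attr(out, "scale") <- "cpm"
  out
}

#' Read a cell-to-cell-type annotation table
#'
#' Tab-delimited with two columns, cell identifier then cell-type label
#' (conventionally headed `Cell` and `Annotation`).
#'
#' @param path Path to the annotation file.
#' @return Tibble with columns `cell`, `cell_type`.
#' @export
read_cell_annotation <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) {
    lr_abort("annotation file needs cell and cell-type columns",
             "lrnet_format_error")
  }
  cell_annotation(as.character(tab[[1L]]), as.character(tab[[2L]]))
}

#' Construct a cell annotation tibble
#'
#' @param cell Character vector of cell identifiers.
#' @param cell_type Character vector of cell-type labels, same length.
#' @return Tibble with columns `cell`, `cell_type`.
#' @export
cell_annotation <- function(cell, cell_type) {
  if (length(cell) != length(cell_type)) {
    lr_abort("`cell` and `cell_type` must have equal length",
             "lrnet_format_error")
  }
  if (anyDuplicated(cell)) {
    lr_abort("duplicated cell ids in annotation", "lrnet_format_error")
  }
  tibble::tibble(cell = as.character(cell),
                 cell_type = as.character(cell_type))
}

#' Filtering thresholds for edge extraction
#'
#' Bundles the thresholds deciding when a ligand or receptor counts as
#' expressed in a cell type. A gene passes in a cell type when its detection
#' fraction (share of cells with strictly positive expression) reaches
#' `detection_threshold` and its mean expression reaches
#' `expression_threshold`. `specificity_threshold` applies to whole edges
#' when counting them in summary networks.
#'
#' @param detection_threshold Detection fraction cutoff in \[0, 1\]; default
#'   0.20 (a gene expressed in at least 20\% of the type's cells).
#' @param expression_threshold Mean-expression cutoff in expression units
#'   (e.g. CPM); default 0.
#' @param specificity_threshold Specificity-weight cutoff in \[0, 1\];
#'   default 0.
#' @param strict_detection If `TRUE`, the detection comparison is strict
#'   (`>` rather than `>=`), so a gene at exactly the threshold fails. The
#'   default keeps a gene detected in exactly 20\% of cells. Exposed so the
#'   boundary convention can be swept when reconciling counts against other
#'   implementations.
#' @return A list of class `"filter_settings"`.
#' @export
filter_settings <- function(detection_threshold = 0.20,
                            expression_threshold = 0,
                            specificity_threshold = 0,
                            strict_detection = FALSE) {
  stopifnot(detection_threshold >= 0, detection_threshold <= 1,
            expression_threshold >= 0,
            specificity_threshold >= 0, specificity_threshold <= 1)
  structure(list(detection_threshold = detection_threshold,
                 expression_threshold = expression_threshold,
                 specificity_threshold = specificity_threshold,
                 strict_detection = isTRUE(strict_detection)),
            class = "filter_settings")
}

#' Summarise expression per (gene, cell type)
#'
#' For every gene of interest and every cell type, computes the mean
#' expression, the total (summed) expression, and the detection fraction
#' (share of the type's cells with strictly positive values). Genes of
#' interest absent from the matrix -- common with cross-species databases or
#' targeted panels -- are reported with mean 0, total 0 and detection 0
#' rather than raising an error (a message lists how many were missing).
#'
#' @param m Expression matrix (genes x cells), typically CPM.
#' @param annotation Cell annotation tibble ([cell_annotation()]); every
#'   annotated cell must exist in the matrix.
#' @param genes Character vector of gene symbols to profile, usually the
#'   union of ligands and receptors in the active pair database. `NULL`
#'   profiles all genes in the matrix.
#' @return Tibble with columns `gene`, `cell_type`, `mean_expr`,
#'   `total_expr`, `detection_fraction`, `n_cells`. Gene symbols keep the
#'   matrix's casing where the gene is present.
#' @export
summarise_cell_types <- function(m, annotation, genes = NULL) {
  unknown <- setdiff(annotation$cell, colnames(m))
  if (length(unknown) > 0L) {
    lr_abort(paste0("annotation references cell(s) absent from the matrix: ",
                    paste(utils::head(unknown, 5L), collapse = ", ")),
             "lrnet_value_error")
  }
  if (is.null(genes)) genes <- rownames(m)
  genes <- unique(genes)
  row_key <- norm_symbol(rownames(m))
  hit <- match(norm_symbol(genes), row_key)
  missing <- is.na(hit)
  if (any(missing)) {
    message(sum(missing), " requested gene(s) absent from the matrix; ",
            "profiled as unexpressed")
  }
  # keep matrix casing for present genes, requested casing for absent ones
  out_symbols <- ifelse(missing, genes, rownames(m)[hit])

  types <- sort(unique(annotation$cell_type))
  per_type <- lapply(types, function(ct) {
    cells <- annotation$cell[annotation$cell_type == ct]
    sub <- m[, cells, drop = FALSE]
    mean_e <- total_e <- det <- numeric(length(genes))
    present <- which(!missing)
    if (length(present) > 0L) {
      block <- sub[hit[present], , drop = FALSE]
      mean_e[present] <- rowMeans(block)
      total_e[present] <- rowSums(block)
      det[present] <- rowMeans(block > 0)
    }
    tibble::tibble(
      gene = out_symbols, cell_type = ct,
      mean_expr = mean_e, total_expr = total_e,
      detection_fraction = det, n_cells = length(cells)
    )
  })
  profile <- dplyr::bind_rows(per_type)
  attr(profile, "cell_types") <- types
  profile
}
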