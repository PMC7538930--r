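#' Build a ligand-receptor pair table
#'
#' Constructs the tibble representation of a curated ligand-receptor pair
#' database. Each row is one directed interaction: a ligand gene, its cognate
#' receptor gene, where the ligand acts from (`"secreted"`,
#' `"plasma_membrane"`, or `"both"` for ligands with both a secreted and a
#' membrane-bound form), the literature evidence backing the pair, and a
#' free-text source tag. Duplicate (ligand, receptor) rows are merged with
#' their evidence unioned, since multi-source tables legitimately repeat
#' pairs.
#'
#' @param ligand,receptor Character vectors of gene symbols.
#' @param location Ligand location; one of `"secreted"`, `"plasma_membrane"`,
#'   `"both"`. Recycled if length 1. Defaults to `"both"`.
#' @param evidence List of character vectors of literature identifiers
#'   (e.g. PubMed ids), or a character vector recycled per pair. May be empty.
#' @param source Free-text provenance tag per pair.
#' @param species_taxon NCBI taxon id of the species the symbols belong to.
#'   Defaults to 9606 (human).
#' @return A tibble with columns `ligand`, `receptor`, `location`, `evidence`
#'   (list column), `source`, carrying a `species_taxon` attribute.
#' @examples
#' lr_pairs(c("TGFB1", "IL6"), c("TGFBR1", "IL6R"),
#'          location = c("secreted", "secreted"))
#' @export
lr_pairs <- function(ligand, receptor, location = "both",
                     evidence = list(character()), source = "user",
                     species_taxon = 9606L) {
  ligand <- as.character(ligand)
  receptor <- as.character(receptor)
  if (length(ligand) != length(receptor)) {
    lr_abort("`ligand` and `receptor` must have the same length",
             "lrnet_format_error")
  }
  if (any(!nzchar(trimws(ligand))) || any(!nzchar(trimws(receptor)))) {
    lr_abort("ligand and receptor symbols must be non-empty",
             "lrnet_format_error")
  }
  location <- normalise_location(location)
  if (length(location) == 1L) location <- rep(location, length(ligand))
  if (is.character(evidence)) evidence <- as.list(evidence)
  if (length(evidence) == 1L) evidence <- rep(evidence, length(ligand))
  if (length(source) == 1L) source <- rep(source, length(ligand))
  db <- tibble::tibble(
    ligand = trimws(ligand), receptor = trimws(receptor),
    location = location, evidence = evidence, source = source
  )
  db <- dedup_pairs(db, warn = FALSE)
  attr(db, "species_taxon") <- species_taxon
  db
}

normalise_location <- function(x) {
  x <- tolower(gsub("[ -]", "_", trimws(as.character(x))))
  x[x %in% c("plasma_membrane", "membrane", "pm")] <- "plasma_membrane"
  bad <- !x %in% c("secreted", "plasma_membrane", "both")
  if (any(bad)) {
    lr_abort(paste0("unrecognised ligand location value(s): ",
                    paste(unique(x[bad]), collapse = ", ")),
             "lrnet_format_error")
  }
  x
}

# Merge duplicate (ligand, receptor) rows, unioning evidence.
dedup_pairs <- function(db, warn = TRUE) {
  key <- paste(norm_symbol(db$ligand), norm_symbol(db$receptor), sep = "\r")
  if (!anyDuplicated(key)) return(db)
  if (warn) {
    warning(sum(duplicated(key)), " duplicated ligand-receptor row(s) merged",
            call. = FALSE)
  }
  idx <- split(seq_len(nrow(db)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(i) {
    first <- db[i[1L], , drop = FALSE]
    first$evidence <- list(unique(unlist(db$evidence[i])))
    first$source <- paste(unique(db$source[i]), collapse = ";")
    first
  })
  dplyr::bind_rows(rows)
}

#' Read a ligand-receptor pair database from a delimited file
#'
#' Supports two dialects. `"connectomedb"` expects a tab- or comma-delimited
#' table with columns identifying the ligand symbol, receptor symbol, ligand
#' location, literature evidence (e.g. PubMed ids, semicolon- or
#' comma-separated) and a source tag; column matching is case-insensitive on
#' header keywords. `"two_column"` expects a header row followed by
#' `Ligand<TAB>Receptor` rows; pairs from such user lists default to location
#' `"both"` and carry no evidence. Duplicated pairs are merged with a warning
#' and a count of parsed/dropped rows is reported via `message()`.
#'
#' An optional exclusion table (pairs reviewed and rejected, with a reason)
#' can be supplied; it is parsed and attached as the `"excluded"` attribute
#' but its rows never enter the returned database.
#'
#' @param path Path to the pair table (plain text or gzip).
#' @param dialect `"connectomedb"` or `"two_column"`.
#' @param exclusion_path Optional path to an excluded-pairs table with at
#'   least ligand and receptor columns (and optionally a reason column).
#' @param species_taxon Taxon id recorded on the result (default 9606).
#' @return A pair tibble as produced by [lr_pairs()]; the `"excluded"`
#'   attribute holds the parsed exclusion table (or `NULL`).
#' @seealso [write_lr_pairs()], [filter_by_location()], [map_orthologs()]
#' @export
read_lr_pairs <- function(path, dialect = c("connectomedb", "two_column"),
                          exclusion_path = NULL, species_taxon = 9606L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) lr_abort(paste0("file not found: ", path))
  raw <- read_delim_auto(path)
  if (nrow(raw) == 0L) lr_abort(paste0("empty pair file: ", path))
  nm <- tolower(names(raw))

  find_col <- function(keys, required = TRUE, exclude = character()) {
    hit <- which(Reduce(`|`, lapply(keys, function(k) grepl(k, nm))) &
                   !Reduce(`|`, c(list(rep(FALSE, length(nm))),
                                  lapply(exclude, function(k) grepl(k, nm)))))
    if (length(hit) == 0L) {
      if (required) {
        lr_abort(paste0("required column matching '",
                        paste(keys, collapse = "|"), "' absent from ", path),
                 "lrnet_format_error")
      }
      return(NA_integer_)
    }
    hit[1L]
  }

  if (dialect == "two_column") {
    lig_i <- find_col("ligand")
    rec_i <- find_col("receptor")
    db <- lr_pairs(raw[[lig_i]], raw[[rec_i]], location = "both",
                   source = "user", species_taxon = species_taxon)
  } else {
    lig_i <- find_col(c("^ligand"), exclude = "location")
    rec_i <- find_col(c("^receptor"))
    loc_i <- find_col("location", required = FALSE)
    ev_i <- find_col(c("pubmed", "evidence", "pmid"), required = FALSE)
    src_i <- find_col("source", required = FALSE)
    loc <- if (is.na(loc_i)) "both" else {
      v <- raw[[loc_i]]
      v[is.na(v) | !nzchar(trimws(v))] <- "both"
      v
    }
    ev <- if (is.na(ev_i)) list(character()) else {
      lapply(strsplit(as.character(raw[[ev_i]]), "[;,|]\\s*"), function(x) {
        x <- trimws(x[!is.na(x)])
        x[nzchar(x)]
      })
    }
    src <- if (is.na(src_i)) "connectomedb" else as.character(raw[[src_i]])
    keep <- !is.na(raw[[lig_i]]) & !is.na(raw[[rec_i]]) &
      nzchar(trimws(raw[[lig_i]])) & nzchar(trimws(raw[[rec_i]]))
    if (any(!keep)) message(sum(!keep), " row(s) with missing symbols dropped")
    db <- suppressWarnings(lr_pairs(
      raw[[lig_i]][keep], raw[[rec_i]][keep],
      location = normalise_location(if (length(loc) == 1L) loc else loc[keep]),
      evidence = if (is.list(ev)) ev[keep] else ev,
      source = if (length(src) == 1L) src else src[keep],
      species_taxon = species_taxon
    ))
  }
  n_dup <- nrow(raw) - nrow(db)
  if (n_dup > 0L) {
    warning(n_dup, " duplicated/invalid row(s) merged or dropped on load",
            call. = FALSE)
  }
  message("parsed ", nrow(db), " ligand-receptor pair(s) from ", basename(path))

  if (!is.null(exclusion_path)) {
    exc <- read_delim_auto(exclusion_path)
    attr(db, "excluded") <- exc
  }
  db
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) lr_abort(paste0("empty file: ", path))
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Write a pair database to a delimited file
#'
#' Serialises a pair tibble in the curated-database layout read back by
#' [read_lr_pairs()] (`dialect = "connectomedb"`): ligand, receptor, ligand
#' location, semicolon-joined evidence ids, source. A load/write/load round
#' trip reproduces the pair set exactly.
#'
#' @param db Pair tibble from [lr_pairs()] or [read_lr_pairs()].
#' @param path Output path; tab-delimited.
#' @return `path`, invisibly.
#' @export
write_lr_pairs <- function(db, path) {
  out <- tibble::tibble(
    Ligand = db$ligand,
    Receptor = db$receptor,
    `Ligand location` = db$location,
    `PubMed ID` = vapply(db$evidence, paste, "", collapse = ";"),
    Source = db$source
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Restrict a pair database by ligand location
#'
#' Returns the pairs usable in a secreted-ligand or plasma-membrane-ligand
#' analysis. Ligands annotated `"both"` exist in both forms and therefore
#' participate in either analysis, so the secreted and plasma-membrane
#' subsets together cover the whole database.
#'
#' @param db Pair tibble.
#' @param wanted `"secreted"` or `"plasma_membrane"`.
#' @return The filtered pair tibble (possibly empty).
#' @export
filter_by_location <- function(db, wanted = c("secreted", "plasma_membrane")) {
  wanted <- match.arg(wanted)
  out <- db[db$location %in% c(wanted, "both"), , drop = FALSE]
  attr(out, "species_taxon") <- attr(db, "species_taxon")
  out
}

#' Read a HomoloGene-style homology table
#'
#' Three tab-delimited columns: homology group id, taxon id, gene symbol
#' (the flat-file subset of NCBI HomoloGene). No header is assumed unless
#' the first row is non-numeric in the group column.
#'
#' @param path Path to the table.
#' @return Tibble with columns `group`, `taxon`, `symbol`.
#' @export
read_homology_table <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(raw) < 3L) {
    lr_abort("homology table needs three columns (group, taxon, symbol)",
             "lrnet_format_error")
  }
  raw <- raw[, 1:3]
  names(raw) <- c("group", "taxon", "symbol")
  if (is.na(suppressWarnings(as.numeric(raw$group[1L])))) raw <- raw[-1L, ]
  tibble::tibble(
    group = as.character(raw$group),
    taxon = as.integer(raw$taxon),
    symbol = as.character(raw$symbol)
  )
}

#' Project a pair database into another species via homology groups
#'
#' Every pair is mapped through the homology table: a partner's orthologs in
#' the target taxon are all symbols sharing a homology group with it. A pair
#' expands to every (ortholog-ligand x ortholog-receptor) combination --
#' one-to-many orthology is kept lossless rather than collapsed to a single
#' canonical hit, since downstream expression filters remove spurious
#' combinations. Pairs with no ortholog for either partner are dropped and
#' counted (reported via `message()` and the `"n_dropped"` attribute).
#' Symbol matching is case-insensitive.
#'
#' @param db Pair tibble in the source species.
#' @param homology Homology tibble from [read_homology_table()].
#' @param target_taxon Taxon id to project into.
#' @param source_taxon Taxon id of `db` (default the tibble's
#'   `species_taxon` attribute, falling back to 9606).
#' @return Pair tibble in the target species with location and provenance
#'   carried over; attribute `"n_dropped"` counts unmappable source pairs.
#' @export
map_orthologs <- function(db, homology, target_taxon,
                          source_taxon = NULL) {
  source_taxon <- source_taxon %||% attr(db, "species_taxon") %||% 9606L
  if (!any(homology$taxon == target_taxon)) {
    lr_abort(paste0("target taxon ", target_taxon,
                    " absent from homology table"))
  }
  if (!any(homology$taxon == source_taxon)) {
    lr_abort(paste0("source taxon ", source_taxon,
                    " absent from homology table"))
  }
  src <- homology[homology$taxon == source_taxon, ]
  tgt <- homology[homology$taxon == target_taxon, ]
  src_groups <- split(src$group, norm_symbol(src$symbol))
  tgt_by_group <- split(tgt$symbol, tgt$group)

  orthologs <- function(sym) {
    groups <- src_groups[[norm_symbol(sym)]]
    if (is.null(groups)) return(character())
    unique(unlist(tgt_by_group[groups], use.names = FALSE))
  }

  rows <- vector("list", nrow(db))
  n_dropped <- 0L
  for (i in seq_len(nrow(db))) {
    lo <- orthologs(db$ligand[i])
    ro <- orthologs(db$receptor[i])
    if (length(lo) == 0L || length(ro) == 0L) {
      n_dropped <- n_dropped + 1L
      next
    }
    combo <- expand.grid(ligand = lo, receptor = ro,
                         stringsAsFactors = FALSE)
    rows[[i]] <- tibble::tibble(
      ligand = combo$ligand, receptor = combo$receptor,
      location = db$location[i], evidence = db$evidence[i],
      source = db$source[i]
    )
  }
  out <- dedup_pairs(dplyr::bind_rows(rows), warn = FALSE)
  if (n_dropped > 0L) {
    message(n_dropped, " pair(s) dropped: no ortholog in taxon ", target_taxon)
  }
  attr(out, "species_taxon") <- target_taxon
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Degree-preserving randomisation of ligand-receptor pairings
#'
#' Generates `n` randomised databases, each preserving the multiset of ligand
#' symbols and the multiset of receptor symbols while permuting the
#' ligand-to-receptor assignment uniformly at random. This is the
#' conservative null for asking whether observed network structure (e.g. the
#' high specificity of autocrine edges) depends on which ligand actually
#' binds which receptor. Randomised lists may recreate real pairs and may
#' contain repeated tuples; both are properties of the null, not errors.
#'
#' @param db Pair tibble with at least 2 pairs.
#' @param n Number of randomised databases.
#' @param seed Integer seed; output is deterministic given `seed`.
#' @return A list of `n` pair tibbles, each with `nrow(db)` rows.
#' @export
randomise_pairs <- function(db, n, seed) {
  if (nrow(db) < 2L) {
    lr_abort("need at least 2 pairs to permute assignments")
  }
  if (n < 1L) lr_abort("`n` must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      perm <- sample.int(nrow(db))
      out <- db
      out$receptor <- db$receptor[perm]
      out$source <- "randomised"
      out$evidence <- rep(list(character()), nrow(db))
      attr(out, "species_taxon") <- attr(db, "species_taxon")
      out
    })
  })
}
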