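#' Parse a ligand-receptor interaction table
#'
#' Builds a validated ligand-receptor database from a table with columns
#' `ligand`, `receptor`, `pathway` and optionally `limit` (the per-pair
#' spatial signaling limit, in the same length unit as the spot coordinates).
#' Heteromeric complexes are written with subunits joined by a separator,
#' e.g. `"FZD1_LRP6"`.
#'
#' Duplicate (ligand, receptor) rows are collapsed; ligand and receptor
#' complexes keep their order of first appearance. Rows without a pathway are
#' assigned `"unannotated"` with a warning.
#'
#' @param table a data frame with columns `ligand`, `receptor`, `pathway`
#'   (optional) and `limit` (optional).
#' @param subunit_separator separator splitting complex names into subunit
#'   gene symbols. Default `"_"`.
#'
#' @return An `lr_database`: list with `ligand_names`, `ligand_subunits`
#'   (list of character vectors), `receptor_names`, `receptor_subunits`, and
#'   `pairs`, a tibble with columns `ligand`, `receptor`, `ligand_index`,
#'   `receptor_index`, `pathway`, `limit` (NA when no per-pair limit given).
#' @export
#' @examples
#' db <- parse_lr_database(
#'   data.frame(ligand = "WNT5B", receptor = "FZD1_LRP6",
#'              pathway = "WNT", limit = 100)
#' )
#' db$receptor_subunits
parse_lr_database <- function(table, subunit_separator = "_") {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (nrow(table) == 0) abort("ligand-receptor table is empty")
  if (!all(c("ligand", "receptor") %in% names(table)))
    abort("table must have columns 'ligand' and 'receptor'")
  lig <- as.character(table$ligand)
  rec <- as.character(table$receptor)
  if (any(is.na(lig) | lig == "") || any(is.na(rec) | rec == ""))
    abort("ligand/receptor names must be non-empty strings")
  pathway <- if ("pathway" %in% names(table)) as.character(table$pathway) else rep(NA_character_, nrow(table))
  missing_pw <- is.na(pathway) | pathway == ""
  if (any(missing_pw)) {
    warn(sprintf("%d pair(s) without pathway annotation assigned 'unannotated'", sum(missing_pw)))
    pathway[missing_pw] <- "unannotated"
  }
  limit <- if ("limit" %in% names(table)) as.numeric(table$limit) else rep(NA_real_, nrow(table))
  if (any(!is.na(limit) & limit <= 0)) abort("spatial limits must be positive")

  keep <- !duplicated(paste(lig, rec, sep = "\r"))
  if (any(!keep)) inform(sprintf("collapsed %d duplicated ligand-receptor row(s)", sum(!keep)))
  lig <- lig[keep]; rec <- rec[keep]; pathway <- pathway[keep]; limit <- limit[keep]

  ligand_names <- unique(lig)
  receptor_names <- unique(rec)
  pairs <- tibble(
    ligand = lig,
    receptor = rec,
    ligand_index = match(lig, ligand_names),
    receptor_index = match(rec, receptor_names),
    pathway = pathway,
    limit = limit
  )
  structure(
    list(
      ligand_names = ligand_names,
      ligand_subunits = strsplit(ligand_names, subunit_separator, fixed = TRUE),
      receptor_names = receptor_names,
      receptor_subunits = strsplit(receptor_names, subunit_separator, fixed = TRUE),
      pairs = pairs,
      subunit_separator = subunit_separator
    ),
    class = "lr_database"
  )
}

#' @export
print.lr_database <- function(x, ...) {
  cat("<lr_database> ", length(x$ligand_names), " ligand(s), ",
      length(x$receptor_names), " receptor(s), ", nrow(x$pairs),
      " interaction pair(s), ", length(unique(x$pairs$pathway)),
      " pathway(s)\n", sep = "")
  invisible(x)
}

#' @describeIn parse_lr_database tidy view: the pair table.
#' @param x an `lr_database`.
#' @param ... unused.
#' @export
tidy.lr_database <- function(x, ...) x$pairs

#' Write a ligand-receptor database back to CSV
#'
#' Inverse of [read_lr_database()]; round-trips losslessly.
#' @param db an `lr_database`.
#' @param path output CSV path.
#' @export
write_lr_database <- function(db, path) {
  stopifnot(inherits(db, "lr_database"))
  readr::write_csv(db$pairs[, c("ligand", "receptor", "pathway", "limit")], path)
  invisible(path)
}

complex_amount <- function(X, subunits) {
  # minimum over subunit columns; NULL if any subunit gene is absent
  idx <- match(subunits, colnames(X))
  if (anyNA(idx)) return(NULL)
  if (length(idx) == 1) return(X[, idx])
  do.call(pmin, lapply(idx, function(j) X[, j]))
}

#' Assemble per-species transport marginals from expression
#'
#' For every ligand and receptor complex in the database, computes its
#' per-spot amount from expression: the minimum over subunit genes (the amount
#' of a heteromeric complex is limited by its scarcest subunit; a
#' single-subunit complex is just its expression). Complexes whose subunit
#' genes are absent from the data are dropped with a warning, as are pairs
#' whose ligand or receptor is expressed in fewer than `min_pct` of spots.
#'
#' @param expr a [spatial_expression].
#' @param db an [lr_database][parse_lr_database].
#' @param min_pct minimum fraction of spots with nonzero ligand and receptor
#'   amount for a pair to be kept (default 0.005). Set to 0 to disable.
#'
#' @return list with `XL` (n_ligands x n_spots matrix), `XR`
#'   (n_receptors x n_spots), and `pairs`, the kept subset of `db$pairs`
#'   with indices re-mapped to the rows of `XL`/`XR`.
#' @export
assemble_marginals <- function(expr, db, min_pct = 0.005) {
  stopifnot(inherits(expr, "spatial_expression"), inherits(db, "lr_database"))
  n_s <- nrow(expr$X)

  amount_matrix <- function(names, subunits) {
    vals <- lapply(subunits, function(su) complex_amount(expr$X, su))
    ok <- !vapply(vals, is.null, logical(1))
    if (any(!ok)) {
      warn(sprintf("dropping %d complex(es) with subunit genes absent from the data: %s",
                   sum(!ok), paste(utils::head(names[!ok], 10), collapse = ", ")))
    }
    m <- if (any(ok)) do.call(rbind, vals[ok]) else matrix(0, 0, n_s)
    rownames(m) <- names[ok]
    m
  }
  XL <- amount_matrix(db$ligand_names, db$ligand_subunits)
  XR <- amount_matrix(db$receptor_names, db$receptor_subunits)

  frac_expressed <- function(m) if (nrow(m)) rowMeans(m > 0) else numeric(0)
  lig_ok <- frac_expressed(XL) >= min_pct & rowSums(XL) > 0
  rec_ok <- frac_expressed(XR) >= min_pct & rowSums(XR) > 0
  XL <- XL[lig_ok, , drop = FALSE]
  XR <- XR[rec_ok, , drop = FALSE]

  pairs <- db$pairs
  pairs <- pairs[pairs$ligand %in% rownames(XL) & pairs$receptor %in% rownames(XR), , drop = FALSE]
  if (nrow(pairs) == 0) {
    all_sub <- unique(unlist(c(db$ligand_subunits, db$receptor_subunits)))
    missing <- setdiff(all_sub, expr$genes)
    abort(paste0("no ligand-receptor pair survives filtering; missing genes: ",
                 paste(utils::head(missing, 20), collapse = ", ")))
  }
  n_dropped <- nrow(db$pairs) - nrow(pairs)
  if (n_dropped > 0)
    inform(sprintf("%d pair(s) removed by expression filtering", n_dropped))
  pairs$ligand_index <- match(pairs$ligand, rownames(XL))
  pairs$receptor_index <- match(pairs$receptor, rownames(XR))
  list(XL = XL, XR = XR, pairs = pairs)
}
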