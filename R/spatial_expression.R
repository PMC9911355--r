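#' Spatial expression container
#'
#' Bundles a non-negative spots-by-genes expression matrix with matching
#' spatial coordinates and optional per-spot cluster labels. Expression is
#' treated as *mass* by the transport model, so it must be on a linear scale
#' (no log transform).
#'
#' @param X numeric matrix (or Matrix sparse matrix), spots x genes,
#'   non-negative. Column names are used as gene names if `gene_names` is
#'   missing; row names as spot IDs.
#' @param coords numeric matrix or data frame with one row per spot and 2 or 3
#'   coordinate columns, in the dataset's length unit (e.g. micrometres).
#' @param gene_names,spot_ids optional character vectors overriding dimnames.
#' @param labels optional per-spot cluster labels (coerced to factor).
#'
#' @return An object of class `spatial_expression`: a list with elements
#'   `X`, `coords`, `genes`, `spots`, `labels`.
#' @export
spatial_expression <- function(X, coords, gene_names = NULL, spot_ids = NULL,
                               labels = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) abort("expression matrix contains non-finite values")
  if (any(X < 0)) abort("expression must be non-negative (linear mass scale)")
  if (nrow(X) < 2) abort("need at least 2 spots")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!ncol(coords) %in% c(2L, 3L)) abort("coords must have 2 or 3 columns")
  if (nrow(coords) != nrow(X)) abort("coords rows must match expression rows")
  if (any(!is.finite(coords))) {
    bad <- which(!stats::complete.cases(coords) | rowSums(!is.finite(coords)) > 0)
    abort(paste0("non-finite coordinates for spot(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  genes <- gene_names %||% colnames(X) %||% paste0("g", seq_len(ncol(X)))
  spots <- spot_ids %||% rownames(X) %||% paste0("s", seq_len(nrow(X)))
  if (anyDuplicated(genes)) abort("gene names must be unique")
  if (anyDuplicated(spots)) abort("spot IDs must be unique")
  dimnames(X) <- list(spots, genes)
  rownames(coords) <- spots
  if (!is.null(labels)) {
    if (length(labels) != nrow(X)) abort("labels length must match spot count")
    labels <- factor(labels)
  }
  if (anyDuplicated(coords) > 0) {
    warn("duplicated spatial coordinates among spots; signaling directions between coincident spots are undefined")
  }
  structure(
    list(X = X, coords = coords, genes = genes, spots = spots, labels = labels),
    class = "spatial_expression"
  )
}

#' @export
print.spatial_expression <- function(x, ...) {
  cat("<spatial_expression> ", length(x$spots), " spots x ", length(x$genes),
      " genes, ", ncol(x$coords), "D coordinates",
      if (!is.null(x$labels)) paste0(", ", nlevels(x$labels), " clusters"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.spatial_expression <- function(x) dim(x$X)

#' Total-count normalization on a linear scale
#'
#' Scales each spot's expression so that its total equals the median total
#' across spots. No log transform is applied: downstream transport marginals
#' must remain interpretable as amounts of ligand/receptor.
#'
#' @param expr a [spatial_expression].
#' @return a [spatial_expression] with rescaled `X`.
#' @export
normalize_total_counts <- function(expr) {
  stopifnot(inherits(expr, "spatial_expression"))
  tot <- rowSums(expr$X)
  if (any(tot == 0)) warn(sprintf("%d spot(s) with zero total counts left unscaled", sum(tot == 0)))
  target <- median(tot[tot > 0])
  fac <- ifelse(tot > 0, target / tot, 1)
  expr$X <- expr$X * fac
  expr
}

#' @describeIn spatial_expression tidy view: one row per spot with coordinates,
#'   label and total expression.
#' @param x a `spatial_expression`.
#' @param ... unused.
#' @export
tidy.spatial_expression <- function(x, ...) {
  obj <- x
  out <- tibble(
    spot = obj$spots,
    x = unname(obj$coords[, 1]),
    y = unname(obj$coords[, 2]),
    total_counts = unname(rowSums(obj$X))
  )
  if (ncol(obj$coords) == 3) out$z <- obj$coords[, 3]
  if (!is.null(obj$labels)) out$label <- obj$labels
  out
}
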