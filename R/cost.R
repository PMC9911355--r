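#' Euclidean distance matrix between spots
#'
#' @param coords numeric matrix, spots x 2 or 3.
#' @return dense symmetric matrix of pairwise Euclidean distances with zero
#'   diagonal.
#' @export
euclidean_distance_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (!ncol(coords) %in% c(2L, 3L)) abort("coords must have 2 or 3 columns")
  if (any(!is.finite(coords))) {
    bad <- which(rowSums(!is.finite(coords)) > 0)
    abort(paste0("non-finite coordinates for spot(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- NULL
  D
}

phi_funs <- list(
  linear = function(d, T) d,
  square = function(d, T) d^2,
  # scaled so phi(0) = 0 and the scale is relative to the spatial limit
  exponential = function(d, T) exp(d / T) - 1
)

#' Sparse, spatially thresholded transport cost for one ligand-receptor pair
#'
#' The cost of sending signal from spot k to spot l is `phi(D[k,l])` when the
#' spots are within the pair's spatial limit `T`, and infinite otherwise.
#' Infinite entries are never stored: couplings outside the support are
#' structurally zero.
#'
#' @param D distance matrix from [euclidean_distance_matrix()] (or a coords
#'   matrix, converted automatically).
#' @param T positive spatial limit in coordinate units.
#' @param phi scaling function: `"linear"` (cost = distance, default),
#'   `"square"` (distance squared) or `"exponential"` (`exp(d/T) - 1`).
#'
#' @return A `sparse_cost`: list with integer vectors `sender`, `receiver`
#'   (1-based spot indices of stored entries), numeric `cost`, plus `n_s`,
#'   `T`, `phi`.
#' @export
build_cost <- function(D, T, phi = c("linear", "square", "exponential")) {
  phi <- match.arg(phi)
  if (!is.matrix(D) || nrow(D) != ncol(D)) D <- euclidean_distance_matrix(D)
  if (!is.numeric(T) || length(T) != 1 || !is.finite(T) || T <= 0)
    abort("spatial limit T must be a positive number")
  n_s <- nrow(D)
  idx <- which(D <= T)
  if (length(idx) == 0) warn("no spot pair within the spatial limit; coupling will be empty")
  sender <- as.integer((idx - 1L) %% n_s + 1L)
  receiver <- as.integer((idx - 1L) %/% n_s + 1L)
  structure(
    list(sender = sender, receiver = receiver,
         cost = phi_funs[[phi]](D[idx], T),
         n_s = n_s, T = T, phi = phi),
    class = "sparse_cost"
  )
}

#' @export
print.sparse_cost <- function(x, ...) {
  cat("<sparse_cost> ", length(x$cost), " finite entries / ", x$n_s, "^2, T = ",
      x$T, ", phi = ", x$phi, "\n", sep = "")
  invisible(x)
}

#' @describeIn build_cost tidy view: one row per stored (sender, receiver, cost).
#' @param x a `sparse_cost`.
#' @param ... unused.
#' @export
tidy.sparse_cost <- function(x, ...) {
  tibble(sender = x$sender, receiver = x$receiver, cost = x$cost)
}
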