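#' Per-spot sent and received signal totals
#'
#' For a spot-by-spot coupling `S` (one pair, a pathway sum, or the total),
#' the signal sent by spot i is the i-th row sum and the signal received is
#' the i-th column sum.
#'
#' @param S non-negative spot-by-spot matrix (dense or sparse).
#' @param spots optional spot IDs.
#' @return tibble with columns `spot`, `sent`, `received`.
#' @export
received_sent_totals <- function(S, spots = NULL) {
  sent <- as.vector(Matrix::rowSums(S))
  received <- as.vector(Matrix::colSums(S))
  tibble(spot = spots %||% rownames(S) %||% as.character(seq_along(sent)),
         sent = sent, received = received)
}

unit_rows <- function(M) {
  nn <- sqrt(rowSums(M^2))
  ok <- nn > 0
  M[ok, ] <- M[ok, , drop = FALSE] / nn[ok]
  M[!ok, ] <- 0
  M
}

top_k_idx <- function(v, k, self) {
  v[self] <- -Inf
  ord <- order(v, seq_along(v), decreasing = c(TRUE, FALSE), method = "radix")
  utils::head(ord[v[ord] > -Inf], k)
}

#' Spatial signaling direction field
#'
#' Estimates, for every spot, a sending vector pointing towards where its
#' signal goes and a receiving vector pointing away from where its signal
#' comes from. The sending vector of spot i is the re-normalized
#' signal-weighted sum of unit offsets towards its top-`k` receivers, scaled
#' by the total signal i sends, so the vector norm equals the total sent
#' signal. Receiving vectors are built symmetrically from the columns of `S`
#' with reversed offsets. The spot itself is excluded from its neighbor set;
#' when the weighted offsets cancel exactly (or the total is zero) the vector
#' is the zero vector.
#'
#' @param S non-negative spot-by-spot coupling.
#' @param coords spot coordinates (n_s x 2 or 3).
#' @param k number of top sending/receiving partners used for the direction
#'   (default 5). Ties are broken towards the lower spot index.
#' @return A `signal_field`: list with matrices `Vs`, `Vr` (n_s x d),
#'   `coords` and `k`.
#' @export
signaling_direction <- function(S, coords, k = 5) {
  coords <- as.matrix(coords)
  if (k < 1) abort("k must be >= 1")
  n_s <- nrow(coords)
  if (nrow(S) != n_s || ncol(S) != n_s) abort("S and coords disagree on spot count")
  if (all(apply(coords, 2, function(z) diff(range(z))) == 0))
    abort("all coordinates identical: directions undefined")
  Sm <- as.matrix(S)
  sent <- rowSums(Sm); received <- colSums(Sm)
  d <- ncol(coords)
  Vs <- matrix(0, n_s, d); Vr <- matrix(0, n_s, d)
  for (i in seq_len(n_s)) {
    if (sent[i] > 0) {
      nb <- top_k_idx(Sm[i, ], k, i)
      w <- Sm[i, nb]
      off <- unit_rows(coords[nb, , drop = FALSE] -
                         matrix(coords[i, ], length(nb), d, byrow = TRUE))
      v <- colSums(w * off)
      nv <- sqrt(sum(v^2))
      if (nv > 0) Vs[i, ] <- sent[i] * v / nv
    }
    if (received[i] > 0) {
      nb <- top_k_idx(Sm[, i], k, i)
      w <- Sm[nb, i]
      off <- unit_rows(matrix(coords[i, ], length(nb), d, byrow = TRUE) -
                         coords[nb, , drop = FALSE])
      v <- colSums(w * off)
      nv <- sqrt(sum(v^2))
      if (nv > 0) Vr[i, ] <- received[i] * v / nv
    }
  }
  structure(list(Vs = Vs, Vr = Vr, coords = coords, k = k,
                 spots = rownames(coords) %||% as.character(seq_len(n_s))),
            class = "signal_field")
}

#' @export
print.signal_field <- function(x, ...) {
  cat("<signal_field> ", nrow(x$Vs), " spots, ", ncol(x$Vs),
      "D, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' @describeIn signaling_direction tidy view: one row per spot with sending
#'   and receiving vector components.
#' @param x a `signal_field`.
#' @param ... unused.
#' @export
tidy.signal_field <- function(x, ...) {
  obj <- x
  out <- tibble(
    spot = obj$spots,
    x = obj$coords[, 1], y = obj$coords[, 2],
    vx_sent = obj$Vs[, 1], vy_sent = obj$Vs[, 2],
    vx_received = obj$Vr[, 1], vy_received = obj$Vr[, 2]
  )
  if (ncol(obj$coords) == 3) {
    out$z <- obj$coords[, 3]; out$vz_sent <- obj$Vs[, 3]; out$vz_received <- obj$Vr[, 3]
  }
  out
}

#' Interpolate a per-spot vector field onto a regular grid
#'
#' Each grid node takes the Gaussian-kernel-weighted average of nearby spot
#' vectors (bandwidth = `grid_spacing`); nodes farther than 3 bandwidths from
#' every spot are zero. Useful for streamline-style visualization.
#'
#' @param V n_spots x d matrix of vectors (e.g. `field$Vs`), or a
#'   `signal_field` (its sending field is used).
#' @param coords spot coordinates.
#' @param grid_spacing node spacing in coordinate units.
#' @return tibble with grid coordinates `x`, `y` and vector components
#'   `vx`, `vy`.
#' @export
interpolate_field_to_grid <- function(V, coords, grid_spacing) {
  if (inherits(V, "signal_field")) { coords <- V$coords; V <- V$Vs }
  if (grid_spacing <= 0) abort("grid_spacing must be positive")
  coords <- as.matrix(coords)
  gx <- seq(min(coords[, 1]), max(coords[, 1]) + grid_spacing / 2, by = grid_spacing)
  gy <- seq(min(coords[, 2]), max(coords[, 2]) + grid_spacing / 2, by = grid_spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  h <- grid_spacing
  out <- matrix(0, nrow(grid), 2)
  for (n in seq_len(nrow(grid))) {
    d2 <- (coords[, 1] - grid[n, 1])^2 + (coords[, 2] - grid[n, 2])^2
    near <- d2 <= (3 * h)^2
    if (!any(near)) next
    w <- exp(-d2[near] / (2 * h^2))
    out[n, ] <- colSums(w * V[near, 1:2, drop = FALSE]) / sum(w)
  }
  tibble(x = grid[, 1], y = grid[, 2], vx = out[, 1], vy = out[, 2])
}

aggregate_cluster <- function(S, labels) {
  # mean coupling over all ordered spot pairs between clusters (diagonal
  # pairs included in within-cluster entries)
  M <- outer(labels, levels(labels), `==`) * 1
  counts <- outer(colSums(M), colSums(M))
  out <- as.matrix(Matrix::crossprod(M, S %*% M)) / counts
  out[counts == 0] <- NaN
  dimnames(out) <- list(levels(labels), levels(labels))
  out
}

#' Cluster-level communication network with permutation p-values
#'
#' Aggregates a spot-by-spot coupling into a cluster-by-cluster matrix of
#' mean signaling strengths and attaches permutation p-values. The default
#' null permutes cluster labels after solving; because that can miss
#' communication structure tied to space itself, two location-permutation
#' modes re-solve the transport problem with shuffled spot locations
#' (all spots, or within each cluster), via a user-supplied `resolve`
#' function.
#'
#' P-values use the add-one estimator
#' `(1 + #permutations >= observed) / (n_perm + 1)`, so they are never
#' exactly zero.
#'
#' @param S spot-by-spot coupling (one pair, a pathway sum, or the total).
#' @param labels per-spot cluster labels.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param mode `"labels"` (permute labels), `"locations_all"` or
#'   `"locations_within"` (permute spot locations and re-solve).
#' @param resolve for the location modes: `function(perm)` taking a
#'   permutation of spot indices and returning the re-solved spot-by-spot
#'   coupling.
#' @return A `cluster_network`: list with `strength`, `pval` (n_c x n_c
#'   matrices), `n_perm`, `mode`, `clusters`.
#' @export
cluster_communication <- function(S, labels, n_perm = 999, seed = NULL,
                                  mode = c("labels", "locations_all", "locations_within"),
                                  resolve = NULL) {
  mode <- match.arg(mode)
  if (!is.factor(labels)) labels <- factor(labels)
  if (length(labels) != nrow(S)) abort("labels must cover all spots")
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (mode != "labels" && !is.function(resolve))
    abort("location-permutation modes need a `resolve` function that re-solves the coupling")
  if (any(table(labels) == 0)) warn("empty cluster level: its rows/columns are NaN")
  if (!is.null(seed)) set.seed(seed)

  obs <- aggregate_cluster(S, labels)
  n_s <- length(labels)
  count_ge <- matrix(0, nrow(obs), ncol(obs))
  for (b in seq_len(n_perm)) {
    if (mode == "labels") {
      perm_stat <- aggregate_cluster(S, labels[sample.int(n_s)])
    } else {
      perm <- if (mode == "locations_all") sample.int(n_s) else {
        p <- seq_len(n_s)
        for (lv in levels(labels)) {
          idx <- which(labels == lv)
          p[idx] <- idx[sample.int(length(idx))]
        }
        p
      }
      perm_stat <- aggregate_cluster(resolve(perm), labels)
    }
    count_ge <- count_ge + (perm_stat >= obs)
  }
  pval <- (1 + count_ge) / (n_perm + 1)
  pval[is.nan(obs)] <- NaN
  structure(list(strength = obs, pval = pval, n_perm = n_perm, mode = mode,
                 clusters = levels(labels)),
            class = "cluster_network")
}

#' @export
print.cluster_network <- function(x, ...) {
  cat("<cluster_network> ", length(x$clusters), " clusters, ", x$n_perm,
      " permutations (", x$mode, " mode)\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_communication tidy view: one row per ordered cluster
#'   pair with strength and p-value.
#' @param x a `cluster_network`.
#' @param ... unused.
#' @export
tidy.cluster_network <- function(x, ...) {
  cl <- x$clusters
  tibble(
    src = rep(cl, times = length(cl)),
    dst = rep(cl, each = length(cl)),
    strength = as.vector(x$strength),
    pval = as.vector(x$pval)
  )
}

#' Communication-profile matrix
#'
#' Assigns each spot a profile of the amount of signal it sends and receives
#' through every ligand-receptor pair: a spots x (2 * n_pairs) matrix whose
#' first block holds per-pair sent totals and second block per-pair received
#' totals. Used to cluster cells by their communication behavior.
#'
#' @param tensor a `ccc_tensor`.
#' @return A `ccc_profile`: list with matrix `M`, `pair_names`, `spots`.
#' @export
ccc_profile <- function(tensor) {
  stopifnot(inherits(tensor, "ccc_tensor"))
  if (length(tensor$S) < 1) abort("need at least one pair")
  sent <- vapply(tensor$S, function(Sp) as.vector(Matrix::rowSums(Sp)),
                 numeric(tensor$n_s))
  received <- vapply(tensor$S, function(Sp) as.vector(Matrix::colSums(Sp)),
                     numeric(tensor$n_s))
  pn <- names(tensor$S)
  M <- cbind(sent, received)
  colnames(M) <- c(paste0(pn, "|sent"), paste0(pn, "|received"))
  rownames(M) <- tensor$spots
  structure(list(M = M, pair_names = pn,
                 spots = tensor$spots %||% as.character(seq_len(tensor$n_s))),
            class = "ccc_profile")
}

#' @export
print.ccc_profile <- function(x, ...) {
  cat("<ccc_profile> ", nrow(x$M), " spots x ", length(x$pair_names),
      " pairs (sent | received)\n", sep = "")
  invisible(x)
}

#' @describeIn ccc_profile tidy view: long tibble (spot, pair, direction,
#'   amount).
#' @param x a `ccc_profile`.
#' @param ... unused.
#' @export
tidy.ccc_profile <- function(x, ...) {
  n_lr <- length(x$pair_names)
  tibble(
    spot = rep(x$spots, times = 2 * n_lr),
    pair = rep(rep(x$pair_names, each = nrow(x$M)), times = 2),
    direction = rep(c("sent", "received"), each = nrow(x$M) * n_lr),
    amount = as.vector(x$M)
  )
}

#' Cluster spots by their communication profiles
#'
#' Row-normalizes the profile matrix (each spot's profile sums to one; all-zero
#' profiles stay zero) and clusters either by k-means or by Louvain community
#' detection on a shared-nearest-neighbor graph.
#'
#' @param profile a [ccc_profile] (or plain matrix).
#' @param n_clusters number of clusters for the k-means backend.
#' @param method `"kmeans"` (default) or `"graph"`.
#' @param k_nn neighbors for the graph backend (default 10).
#' @param resolution Louvain resolution for the graph backend (default 1).
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @return factor of cluster labels, one per spot.
#' @export
cluster_by_ccc <- function(profile, n_clusters = NULL,
                           method = c("kmeans", "graph"),
                           k_nn = 10, resolution = 1, seed = 1) {
  method <- match.arg(method)
  M <- if (inherits(profile, "ccc_profile")) profile$M else as.matrix(profile)
  rs <- rowSums(M)
  Mn <- M
  Mn[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
  if (all(apply(Mn, 2, function(z) diff(range(z))) == 0)) {
    warn("constant communication profiles: returning a single cluster")
    return(factor(rep(1L, nrow(M))))
  }
  set.seed(seed)
  if (method == "kmeans") {
    if (is.null(n_clusters)) abort("k-means backend needs n_clusters")
    if (n_clusters == 1) return(factor(rep(1L, nrow(M))))
    km <- stats::kmeans(Mn, centers = n_clusters, nstart = 10, iter.max = 100)
    factor(km$cluster)
  } else {
    n <- nrow(Mn)
    k_nn <- min(k_nn, n - 1)
    D <- as.matrix(stats::dist(Mn))
    el <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(D[i, ], seq_len(n))[2:(k_nn + 1)]
      cbind(i, nb)
    }))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::simplify(g)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    factor(igraph::membership(comm))
  }
}
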