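#' Weighted cosine distance between two vector fields
#'
#' Compares a vector field against a reference field (e.g. computed from
#' subsampled versus full data):
#' `sum_i ||V_ref(i)|| * (1 - cos(V_ref(i), V(i))) / sum_i ||V_ref(i)||`,
#' so rows are weighted by the reference field's signal magnitude. Rows where
#' the reference vector is zero carry zero weight and are ignored; rows where
#' only the compared vector is zero take the maximal penalty for that weight
#' (cosine treated as 0). Ranges over [0, 2]: 0 for identical directions,
#' 2 for an exactly reversed field.
#'
#' @param V_full reference field, matrix n x d (or `signal_field`, using
#'   its sending field).
#' @param V_sub compared field of the same shape.
#' @return scalar in [0, 2].
#' @export
cosine_distance_fields <- function(V_full, V_sub) {
  if (inherits(V_full, "signal_field")) V_full <- V_full$Vs
  if (inherits(V_sub, "signal_field")) V_sub <- V_sub$Vs
  V_full <- as.matrix(V_full); V_sub <- as.matrix(V_sub)
  if (!all(dim(V_full) == dim(V_sub))) abort("fields must have the same shape")
  nf <- sqrt(rowSums(V_full^2))
  ns <- sqrt(rowSums(V_sub^2))
  if (sum(nf) == 0) abort("reference field is all-zero: weights undefined")
  cosv <- numeric(length(nf))
  ok <- nf > 0 & ns > 0
  cosv[ok] <- rowSums(V_full[ok, , drop = FALSE] * V_sub[ok, , drop = FALSE]) /
    (nf[ok] * ns[ok])
  sum(nf * (1 - cosv)) / sum(nf)
}

network_edges <- function(net, alpha) {
  stopifnot(inherits(net, "cluster_network"))
  ed <- tidy(net)
  ed <- ed[!is.na(ed$pval) & ed$pval < alpha, c("src", "dst")]
  paste(ed$src, ed$dst, sep = "->")
}

#' Jaccard distance between two binarized cluster networks
#'
#' Keeps the edges with permutation p-value below `alpha` in each network and
#' returns `1 - |intersection| / |union|` of the edge sets. Two empty
#' networks are identical (distance 0).
#'
#' @param net1,net2 [cluster_network][cluster_communication] objects over the
#'   same cluster universe.
#' @param alpha binarization threshold on p-values (default 0.05).
#' @return scalar in [0, 1].
#' @export
jaccard_distance_networks <- function(net1, net2, alpha = 0.05) {
  if (!setequal(net1$clusters, net2$clusters))
    abort("networks must share the same cluster universe")
  e1 <- network_edges(net1, alpha)
  e2 <- network_edges(net2, alpha)
  un <- union(e1, e2)
  if (length(un) == 0) return(0)
  1 - length(intersect(e1, e2)) / length(un)
}

#' Spearman correlation between inferred signaling and target-gene activity
#'
#' Rank correlation (average ranks on ties) between the per-cluster average
#' received signal of a ligand-receptor pair and an externally derived
#' activity of that pair's known target genes, across cell clusters.
#'
#' @param received_by_cluster numeric vector, one value per cluster.
#' @param target_activity_by_cluster numeric vector of the same length
#'   (e.g. percentage of the pair's target genes differentially expressed in
#'   that cluster).
#' @return Spearman's rho in [-1, 1]; NaN (with a warning) when either input
#'   is constant.
#' @export
spearman_signal_target <- function(received_by_cluster, target_activity_by_cluster) {
  x <- as.numeric(received_by_cluster)
  y <- as.numeric(target_activity_by_cluster)
  if (length(x) != length(y)) abort("inputs must have the same length")
  if (length(x) < 3) abort("need at least 3 clusters")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warn("constant input: Spearman correlation undefined")
    return(NaN)
  }
  cor(x, y, method = "spearman")
}
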