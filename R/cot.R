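#' Flatten the multi-species transport problem
#'
#' Stacks all ligand species' per-spot amounts into one source vector `a`
#' (entry `(i-1)*n_s + k` is ligand i's amount at spot k), all receptor
#' species into a target vector `b`, and concatenates the per-pair sparse
#' costs into one big sparse cost with the corresponding row/column offsets.
#' Species pairs that cannot bind contribute no entries (infinite cost).
#'
#' @param XL n_ligands x n_spots non-negative matrix of ligand amounts.
#' @param XR n_receptors x n_spots matrix of receptor amounts.
#' @param pairs tibble with columns `ligand_index`, `receptor_index` (rows of
#'   `XL`/`XR`) identifying the binding pairs.
#' @param costs list of [sparse_cost][build_cost] objects, one per row of
#'   `pairs`.
#' @param eps entropic regularization coefficient (> 0).
#' @param rho penalty per unit of untransported mass (> 0).
#' @return A `flattened_problem` list: `a`, `b`, `row`, `col`, `cost`,
#'   `pair_id` (entry-level bookkeeping), `n_l`, `n_r`, `n_s`, `eps`, `rho`.
#' @export
flatten_problem <- function(XL, XR, pairs, costs, eps, rho) {
  if (!is.numeric(eps) || length(eps) != 1 || !is.finite(eps) || eps <= 0)
    abort("eps must be a positive number")
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho <= 0)
    abort("rho must be a positive number")
  n_l <- nrow(XL); n_r <- nrow(XR); n_s <- ncol(XL)
  if (ncol(XR) != n_s) abort("XL and XR must have the same number of spots")
  if (length(costs) != nrow(pairs)) abort("one cost per pair required")
  if (any(XL < 0) || any(XR < 0)) abort("marginals must be non-negative")

  row <- integer(0); col <- integer(0); cost <- numeric(0); pair_id <- integer(0)
  for (p in seq_len(nrow(pairs))) {
    cs <- costs[[p]]
    if (cs$n_s != n_s) abort("cost support size does not match spot count")
    row <- c(row, (pairs$ligand_index[p] - 1L) * n_s + cs$sender)
    col <- c(col, (pairs$receptor_index[p] - 1L) * n_s + cs$receiver)
    cost <- c(cost, cs$cost)
    pair_id <- c(pair_id, rep.int(p, length(cs$cost)))
  }
  structure(
    list(a = as.vector(t(XL)), b = as.vector(t(XR)),
         row = row, col = col, cost = cost, pair_id = pair_id,
         n_l = n_l, n_r = n_r, n_s = n_s, eps = eps, rho = rho),
    class = "flattened_problem"
  )
}

#' Solve the flattened problem by stabilized Sinkhorn iteration
#'
#' Alternates the two log-domain dual updates until the duals change by less
#' than `tol` in max-norm, then reconstructs the primal coupling
#' `P = exp((f + g - C)/eps)` on the sparse support and unflattens it into one
#' sparse spot-by-spot matrix per ligand-receptor pair. Spots with zero
#' ligand (receptor) amount are masked and yield exactly zero rows (columns).
#'
#' @param prob a [flattened_problem][flatten_problem].
#' @param tol convergence tolerance on the max-norm dual change
#'   (default 1e-8).
#' @param max_iter iteration cap (default 10000). Non-convergence returns the
#'   best iterate with `converged = FALSE` and a warning.
#' @param sparsify drop primal entries below
#'   `1e-8 * total transported mass / n_entries` (entropic couplings are dense
#'   on their support; tiny entries are numerical fog). Default TRUE.
#' @param anneal start the iteration at a large entropic coefficient (the
#'   maximum finite cost) and halve it down to `eps`, warm-starting the duals
#'   at each level. Greatly reduces iteration counts at small `eps` without
#'   changing the fixed point (the regularized problem is strictly convex).
#'   Default TRUE.
#' @param pair_names optional names for the output list of couplings.
#' @return A `ccc_tensor`: list with `S` (named list of sparse dgCMatrix,
#'   one per pair), `pairs`, `n_s`, `eps`, `rho` and `diagnostics`
#'   (iterations, converged, dual_change, marginal excesses).
#' @export
solve_sinkhorn <- function(prob, tol = 1e-8, max_iter = 10000,
                           sparsify = TRUE, anneal = TRUE, pair_names = NULL) {
  stopifnot(inherits(prob, "flattened_problem"))
  if (!is.numeric(tol) || tol <= 0) abort("tol must be positive")
  n_s <- prob$n_s
  nr <- prob$n_l * n_s
  nc <- prob$n_r * n_s
  nnz <- length(prob$cost)

  loga <- ifelse(prob$a > 0, log(prob$a), -Inf)
  logb <- ifelse(prob$b > 0, log(prob$b), -Inf)

  if (nnz == 0) {
    warn("empty cost support: returning an all-zero coupling")
    fit <- list(iterations = 0L, converged = TRUE, dual_change = 0)
    P <- numeric(0)
  } else {
    ord_r <- order(prob$row)
    ord_c <- order(prob$col)
    row_ptr <- c(0L, cumsum(tabulate(prob$row, nbins = nr)))
    col_ptr <- c(0L, cumsum(tabulate(prob$col, nbins = nc)))
    fit <- cot_sinkhorn(
      as.integer(row_ptr), as.integer(prob$col[ord_r] - 1L), prob$cost[ord_r],
      as.integer(col_ptr), as.integer(prob$row[ord_c] - 1L), prob$cost[ord_c],
      loga, logb, prob$eps, prob$rho, tol, as.integer(max_iter),
      if (anneal) max(prob$cost) else 0
    )
    if (!fit$converged)
      warn(sprintf("Sinkhorn did not converge in %d iterations (dual change %.3g)",
                   fit$iterations, fit$dual_change))
    lp <- (fit$f[prob$row] + fit$g[prob$col] - prob$cost) / prob$eps
    P <- ifelse(is.finite(lp), exp(lp), 0)
    if (sparsify && any(P > 0)) {
      thr <- 1e-8 * sum(P) / nnz
      P[P < thr] <- 0
    }
  }

  pair_names <- pair_names %||% paste0("pair", seq_len(max(prob$pair_id, 0L)))
  n_pairs <- length(pair_names)
  S <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    sel <- which(prob$pair_id == p & P > 0)
    S[[p]] <- Matrix::sparseMatrix(
      i = (prob$row[sel] - 1L) %% n_s + 1L,
      j = (prob$col[sel] - 1L) %% n_s + 1L,
      x = P[sel], dims = c(n_s, n_s)
    )
  }
  names(S) <- pair_names

  rs <- numeric(nr); cs <- numeric(nc)
  if (nnz) {
    agg_r <- rowsum(P, prob$row)
    rs[as.integer(rownames(agg_r))] <- agg_r[, 1]
    agg_c <- rowsum(P, prob$col)
    cs[as.integer(rownames(agg_c))] <- agg_c[, 1]
  }
  diagnostics <- list(
    iterations = fit$iterations,
    converged = fit$converged,
    dual_change = fit$dual_change,
    max_ligand_excess = max(c(rs - prob$a, 0)),
    max_receptor_excess = max(c(cs - prob$b, 0)),
    total_mass = sum(P),
    nnz_cost = nnz
  )
  structure(
    list(S = S, n_s = n_s, eps = prob$eps, rho = prob$rho,
         diagnostics = diagnostics),
    class = "ccc_tensor"
  )
}

#' Check the coupling against its capacity and support constraints
#'
#' Diagnostic: reports how far the coupling exceeds the ligand-side and
#' receptor-side capacity inequalities, and counts entries outside the
#' spatial support (distance beyond the pair's limit), which must be zero by
#' construction.
#'
#' @param object a `ccc_tensor` (or plain named list of sparse couplings).
#' @param XL,XR marginal matrices as passed to the solver.
#' @param pairs pair table with `ligand_index`, `receptor_index` and `limit`.
#' @param D optional distance matrix; when given, support violations are
#'   counted against `pairs$limit`.
#' @param tol reporting tolerance (informational only).
#' @return tibble with one row: `max_ligand_excess`, `max_receptor_excess`,
#'   `support_violations`.
#' @export
verify_feasibility <- function(object, XL, XR, pairs, D = NULL, tol = 1e-6) {
  S <- if (inherits(object, "ccc_tensor")) object$S else object
  n_s <- ncol(XL)
  sent <- matrix(0, nrow(XL), n_s)
  received <- matrix(0, nrow(XR), n_s)
  violations <- 0L
  for (p in seq_along(S)) {
    li <- pairs$ligand_index[p]; rj <- pairs$receptor_index[p]
    Sp <- S[[p]]
    sent[li, ] <- sent[li, ] + Matrix::rowSums(Sp)
    received[rj, ] <- received[rj, ] + Matrix::colSums(Sp)
    if (!is.null(D)) {
      tr <- as(Sp, "TsparseMatrix")
      keep <- tr@x > 0
      if (any(keep))
        violations <- violations +
          sum(D[cbind(tr@i[keep] + 1L, tr@j[keep] + 1L)] > pairs$limit[p])
    }
  }
  tibble(
    max_ligand_excess = max(c(sent - XL, 0)),
    max_receptor_excess = max(c(received - XR, 0)),
    support_violations = violations,
    tol = tol
  )
}
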