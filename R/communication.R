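#' Infer cell-cell communication by collective optimal transport
#'
#' The main entry point. Assembles per-species ligand/receptor amounts from
#' expression (minimum over heteromeric subunits), builds spatially
#' thresholded costs, and solves one coupled transport problem over all
#' binding pairs simultaneously, so that ligand and receptor species compete
#' for the same per-spot capacity. The result scores the signaling strength
#' from every sender spot to every receiver spot through every pair.
#'
#' Amounts may remain untransported at a per-unit penalty `rho`; with the
#' default `rho` much larger than any transport cost, signal is coupled
#' wherever the spatial limit allows, which suits database-wide screening.
#'
#' @param expr a [spatial_expression].
#' @param db an [lr_database][parse_lr_database].
#' @param dis_thr global spatial limit (coordinate units) applied to pairs
#'   without a per-pair `limit` in the database. Required if any pair lacks
#'   one; there is no silent default.
#' @param phi cost scaling function, see [build_cost()].
#' @param eps entropic coefficient; default `eps_frac` times the median
#'   finite cost.
#' @param rho untransported-mass penalty; default `rho_frac` times the
#'   maximum finite cost.
#' @param eps_frac,rho_frac fractions used when `eps`/`rho` are not given.
#' @param tol,max_iter,sparsify solver controls, see [solve_sinkhorn()].
#' @param min_pct pair expression filter, see [assemble_marginals()].
#'
#' @return A `ccc_tensor` with elements `S` (named list of sparse
#'   spot-by-spot couplings, names `"LIGAND-RECEPTOR"`), `pairs`, `XL`, `XR`,
#'   `spots`, `coords`, `labels`, `eps`, `rho`, `diagnostics`.
#' @export
#' @examples
#' sim <- simulate_tissue(n_spots = 64, n_ligands = 1, n_receptors = 1, seed = 1)
#' ccc <- infer_communication(sim$expr, sim$db, dis_thr = 6)
#' tidy(ccc)
#' glance(ccc)
infer_communication <- function(expr, db, dis_thr = NULL,
                                phi = c("linear", "square", "exponential"),
                                eps = NULL, rho = NULL,
                                eps_frac = 0.01, rho_frac = 10,
                                tol = 1e-8, max_iter = 10000,
                                sparsify = TRUE, min_pct = 0.005) {
  phi <- match.arg(phi)
  stopifnot(inherits(expr, "spatial_expression"))
  marg <- assemble_marginals(expr, db, min_pct = min_pct)
  pairs <- marg$pairs
  limit <- pairs$limit
  if (anyNA(limit)) {
    if (is.null(dis_thr))
      abort("some pairs have no spatial limit in the database; supply dis_thr")
    limit[is.na(limit)] <- dis_thr
  }
  pairs$limit <- limit

  D <- euclidean_distance_matrix(expr$coords)
  costs <- lapply(limit, function(Tp) build_cost(D, Tp, phi))

  all_costs <- unlist(lapply(costs, `[[`, "cost"))
  if (is.null(eps)) {
    med <- median(all_costs)
    eps <- eps_frac * if (is.finite(med) && med > 0) med else max(all_costs, 1)
  }
  if (is.null(rho)) {
    mx <- suppressWarnings(max(all_costs))
    rho <- rho_frac * if (is.finite(mx) && mx > 0) mx else 1
  }

  prob <- flatten_problem(marg$XL, marg$XR, pairs, costs, eps = eps, rho = rho)
  fit <- solve_sinkhorn(prob, tol = tol, max_iter = max_iter,
                        sparsify = sparsify,
                        pair_names = paste(pairs$ligand, pairs$receptor, sep = "-"))
  for (p in seq_along(fit$S)) dimnames(fit$S[[p]]) <- list(expr$spots, expr$spots)
  feas <- verify_feasibility(fit, marg$XL, marg$XR, pairs, D = D)
  fit$diagnostics$support_violations <- feas$support_violations
  fit$pairs <- pairs
  fit$XL <- marg$XL
  fit$XR <- marg$XR
  fit$spots <- expr$spots
  fit$coords <- expr$coords
  fit$labels <- expr$labels
  fit$phi <- phi
  fit
}

#' @export
print.ccc_tensor <- function(x, ...) {
  d <- x$diagnostics
  cat("<ccc_tensor> ", length(x$S), " ligand-receptor pair(s) x ", x$n_s,
      " spots\n  eps = ", signif(x$eps, 4), ", rho = ", signif(x$rho, 4),
      "; ", d$iterations, " iterations, converged: ", d$converged,
      "\n  total transported mass = ", signif(d$total_mass, 5), "\n", sep = "")
  invisible(x)
}

#' Tidy a coupling tensor into sender/receiver triplets
#'
#' @param x a `ccc_tensor`.
#' @param ... unused.
#' @return tibble with columns `ligand`, `receptor`, `pathway`, `sender`,
#'   `receiver`, `weight` (nonzero couplings only).
#' @export
tidy.ccc_tensor <- function(x, ...) {
  spots <- x$spots %||% as.character(seq_len(x$n_s))
  pw <- if (!is.null(x$pairs)) x$pairs$pathway else rep(NA_character_, length(x$S))
  purrr::imap_dfr(x$S, function(Sp, nm) {
    tr <- as(Sp, "TsparseMatrix")
    p <- match(nm, names(x$S))
    lr <- if (!is.null(x$pairs)) x$pairs[p, ] else NULL
    tibble(
      ligand = if (is.null(lr)) nm else lr$ligand,
      receptor = if (is.null(lr)) nm else lr$receptor,
      pathway = pw[p],
      sender = spots[tr@i + 1L],
      receiver = spots[tr@j + 1L],
      weight = tr@x
    )
  })
}

#' One-row solver summary
#' @param x a `ccc_tensor`.
#' @param ... unused.
#' @export
glance.ccc_tensor <- function(x, ...) {
  d <- x$diagnostics
  tibble(
    n_pairs = length(x$S), n_spots = x$n_s,
    eps = x$eps, rho = x$rho,
    iterations = d$iterations, converged = d$converged,
    dual_change = d$dual_change,
    max_ligand_excess = d$max_ligand_excess,
    max_receptor_excess = d$max_receptor_excess,
    support_violations = d$support_violations %||% NA_integer_,
    total_mass = d$total_mass
  )
}

#' Extract a single coupling matrix, or aggregate by pathway / in total
#'
#' @param tensor a `ccc_tensor`.
#' @param pair pair name `"LIGAND-RECEPTOR"`.
#' @return sparse n_s x n_s matrix.
#' @export
pair_matrix <- function(tensor, pair) {
  if (!pair %in% names(tensor$S)) abort(paste0("unknown pair: ", pair))
  tensor$S[[pair]]
}

#' @rdname pair_matrix
#' @param pathway pathway name; the couplings of all its pairs are summed.
#' @export
pathway_matrix <- function(tensor, pathway) {
  sel <- which(tensor$pairs$pathway == pathway)
  if (length(sel) == 0) abort(paste0("unknown pathway: ", pathway))
  Reduce(`+`, tensor$S[sel])
}

#' @rdname pair_matrix
#' @export
total_matrix <- function(tensor) Reduce(`+`, tensor$S)
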