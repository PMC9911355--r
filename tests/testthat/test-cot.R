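two_spot_problem <- function(a = c(1, 0), b = c(0, 1), dist = 1, T = 10,
                             eps = 0.01, rho = 10) {
  D <- euclidean_distance_matrix(rbind(c(0, 0), c(dist, 0)))
  pairs <- tibble::tibble(ligand_index = 1L, receptor_index = 1L)
  flatten_problem(matrix(a, 1), matrix(b, 1), pairs,
                  list(build_cost(D, T = T)), eps = eps, rho = rho)
}

test_that("flattening uses the (i-1)*n_s + k indexing and is invertible", {
  n_s <- 3
  XL <- matrix(runif(6), 2)  # 2 ligands
  XR <- matrix(runif(3), 1)
  D <- euclidean_distance_matrix(cbind(1:3, 0))
  pairs <- tibble::tibble(ligand_index = 2L, receptor_index = 1L)
  prob <- flatten_problem(XL, XR, pairs, list(build_cost(D, 10)), eps = 1, rho = 1)
  # ligand 2 at spot 3 (0-based: i=1, k=2) lands at flat row 1*3 + 2 (0-based) = 6 (1-based)
  expect_true(6L %in% prob$row)
  expect_equal(prob$a[6], XL[2, 3])
  expect_equal(sort(unique(prob$row)), 4:6)
  # round trip: unflattened indices recover (pair, sender, receiver)
  k <- (prob$row - 1L) %% n_s + 1L
  l <- (prob$col - 1L) %% n_s + 1L
  i <- (prob$row - 1L) %/% n_s + 1L
  expect_true(all(i == 2L))
  expect_equal((i - 1L) * n_s + k, prob$row)
  expect_true(all(l %in% 1:3))
})

test_that("invalid coefficients are rejected and zero marginals yield empty couplings", {
  D <- euclidean_distance_matrix(cbind(1:2, 0))
  pairs <- tibble::tibble(ligand_index = 1L, receptor_index = 1L)
  costs <- list(build_cost(D, 10))
  XL <- matrix(1, 1, 2); XR <- matrix(1, 1, 2)
  expect_error(flatten_problem(XL, XR, pairs, costs, eps = 0, rho = 1), "eps")
  expect_error(flatten_problem(XL, XR, pairs, costs, eps = 1, rho = -1), "rho")
  prob <- flatten_problem(0 * XL, XR, pairs, costs, eps = 0.1, rho = 1)
  fit <- solve_sinkhorn(prob)
  expect_equal(sum(fit$S[[1]]), 0)
})

test_that("a single cheap route transports everything", {
  fit <- solve_sinkhorn(two_spot_problem())
  S <- as.matrix(fit$S[[1]])
  # cost 1 < 2*rho: the LP optimum moves all mass 0 -> 1
  expect_equal(S[1, 2], 1, tolerance = 0.02)
  expect_lt(sum(S) - S[1, 2], 1e-6)
  expect_true(fit$diagnostics$converged)
})

test_that("couplings beyond the spatial limit are structurally zero", {
  fit <- suppressWarnings(solve_sinkhorn(two_spot_problem(dist = 11, T = 10)))
  expect_equal(sum(fit$S[[1]]), 0)
})

test_that("two equal ligands split one receptor evenly", {
  D <- euclidean_distance_matrix(rbind(c(0, 0), c(1, 0)))
  pairs <- tibble::tibble(ligand_index = c(1L, 2L), receptor_index = c(1L, 1L))
  costs <- list(build_cost(D, 10), build_cost(D, 10))
  XL <- rbind(c(1, 0), c(1, 0))  # both ligands at spot 1
  XR <- matrix(c(0, 1), 1)       # one receptor unit at spot 2
  prob <- flatten_problem(XL, XR, pairs, costs, eps = 0.01, rho = 10)
  fit <- solve_sinkhorn(prob)
  m1 <- sum(fit$S[[1]]); m2 <- sum(fit$S[[2]])
  expect_equal(m1, m2, tolerance = 1e-6)
  expect_equal(m1 + m2, 1, tolerance = 0.02)
  expect_lte(m1 + m2, 1 + 1e-6)
})

test_that("zero-cost self routes reproduce the identity coupling", {
  co <- cbind(c(0, 10, 20), 0)  # far apart; T below spacing keeps only self edges
  D <- euclidean_distance_matrix(co)
  pairs <- tibble::tibble(ligand_index = 1L, receptor_index = 1L)
  a <- c(0.3, 1.2, 0.7)
  prob <- flatten_problem(matrix(a, 1), matrix(a, 1), pairs,
                          list(build_cost(D, T = 1)), eps = 0.01, rho = 10)
  fit <- solve_sinkhorn(prob)
  expect_equal(as.matrix(fit$S[[1]]), diag(a), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("marginal inequalities hold and support violations are zero on random solves", {
  for (seed in 1:8) {
    inst <- random_instance(seed, n_s_max = 30, n_species_max = 3,
                            eps = 0.05, T = 2)
    fit <- suppressWarnings(solve_sinkhorn(inst$prob))
    inst$pairs$limit <- 2
    rep <- verify_feasibility(fit, inst$XL, inst$XR, inst$pairs, D = inst$D)
    tol <- 1e-6 * max(c(inst$XL, inst$XR))
    expect_lte(rep$max_ligand_excess, tol)
    expect_lte(rep$max_receptor_excess, tol)
    expect_identical(rep$support_violations, 0L)
  }
})

test_that("verify_feasibility reports hand-built violations", {
  XL <- matrix(c(1, 0), 1); XR <- matrix(c(0, 1), 1)
  pairs <- tibble::tibble(ligand_index = 1L, receptor_index = 1L, limit = 10)
  S <- list(Matrix::sparseMatrix(i = 1, j = 2, x = 1.1, dims = c(2, 2)))
  rep <- verify_feasibility(S, XL, XR, pairs)
  expect_equal(rep$max_ligand_excess, 0.1, tolerance = 1e-12)
  empty <- list(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(2, 2)))
  rep0 <- verify_feasibility(empty, XL, XR, pairs)
  expect_equal(rep0$max_ligand_excess, 0)
  expect_equal(rep0$max_receptor_excess, 0)
})

test_that("ligand competition is monotone: more of ligand 1 never helps ligand 2", {
  co <- rbind(c(-1, 0), c(1, 0), c(0, 0))
  D <- euclidean_distance_matrix(co)
  pairs <- tibble::tibble(ligand_index = c(1L, 2L), receptor_index = c(1L, 1L))
  costs <- list(build_cost(D, 10), build_cost(D, 10))
  XR <- matrix(c(0, 0, 1), 1)
  coupled2 <- sapply(seq(0.1, 2, length.out = 10), function(a1) {
    XL <- rbind(c(a1, 0, 0), c(0, 1, 0))
    prob <- flatten_problem(XL, XR, pairs, costs, eps = 0.02, rho = 10)
    sum(solve_sinkhorn(prob)$S[[2]])
  })
  expect_true(all(diff(coupled2) <= 0))
})

test_that("entropic objective approaches the exact LP optimum as eps -> 0", {
  skip_if_not_installed("boot")
  gaps <- sapply(1:10, function(seed) {
    inst <- random_instance(seed)
    fit <- suppressWarnings(solve_sinkhorn(inst$prob, tol = 1e-10,
                                           max_iter = 300000, sparsify = FALSE))
    lp <- lp_objective(inst$prob)
    abs(entropic_objective(inst$prob, fit) - lp) / abs(lp)
  })
  expect_true(all(gaps < 0.01))
})

test_that("scaling both marginals (and eps) scales the transported objective", {
  skip_if_not_installed("boot")
  inst <- random_instance(3)
  s <- 2.5
  prob2 <- inst$prob
  prob2$a <- s * prob2$a; prob2$b <- s * prob2$b; prob2$eps <- s * prob2$eps
  f1 <- suppressWarnings(solve_sinkhorn(inst$prob, tol = 1e-10, max_iter = 300000))
  f2 <- suppressWarnings(solve_sinkhorn(prob2, tol = 1e-10, max_iter = 300000))
  o1 <- entropic_objective(inst$prob, f1)
  o2 <- entropic_objective(prob2, f2)
  expect_equal(o2 / o1, s, tolerance = 0.01)
})

test_that("permuting spots permutes the coupling accordingly", {
  inst <- random_instance(6, n_s_max = 8, eps = 0.05)
  fit <- solve_sinkhorn(inst$prob)
  n_s <- inst$prob$n_s
  perm <- sample(n_s)
  costs_p <- lapply(inst$costs, function(cs)
    build_cost(euclidean_distance_matrix(inst$coords[perm, , drop = FALSE]), cs$T, cs$phi))
  prob_p <- flatten_problem(inst$XL[, perm, drop = FALSE], inst$XR[, perm, drop = FALSE],
                            inst$pairs, costs_p, eps = inst$prob$eps, rho = inst$prob$rho)
  fit_p <- solve_sinkhorn(prob_p)
  for (p in seq_along(fit$S))
    expect_equal(as.matrix(fit_p$S[[p]]),
                 as.matrix(fit$S[[p]])[perm, perm], tolerance = 1e-6)
})

test_that("non-convergence is reported, not hidden", {
  inst <- random_instance(1)  # eps = 1e-3 * median cost: slow convergence
  expect_warning(fit <- solve_sinkhorn(inst$prob, max_iter = 5), "converge")
  expect_false(fit$diagnostics$converged)
  expect_true(is.finite(fit$diagnostics$dual_change))
})
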