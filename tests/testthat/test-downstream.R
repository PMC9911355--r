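test_that("sent/received totals are row and column sums", {
  S <- rbind(c(0, 1), c(0, 0))
  tot <- received_sent_totals(S)
  expect_equal(tot$received, c(0, 1))
  expect_equal(tot$sent, c(1, 0))

  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(3, 3))
  tot0 <- received_sent_totals(empty)
  expect_equal(tot0$sent, rep(0, 3))

  S <- random_coupling(15, seed = 2)
  tot <- received_sent_totals(S)
  expect_equal(sum(tot$sent), sum(S))
  expect_equal(sum(tot$received), sum(S))
})

test_that("a single edge gives the textbook direction vectors", {
  S <- rbind(c(0, 2), c(0, 0))
  co <- rbind(c(0, 0), c(5, 0))
  f <- signaling_direction(S, co, k = 1)
  expect_equal(f$Vs[1, ], c(2, 0))
  expect_equal(f$Vr[2, ], c(2, 0))  # receiving from the left: offset x_i - x_j
  expect_equal(f$Vs[2, ], c(0, 0))
  expect_equal(f$Vr[1, ], c(0, 0))
})

test_that("tidied fields carry coordinates and vector components", {
  S <- rbind(c(0, 2), c(0, 0))
  co <- rbind(c(0, 0), c(5, 0))
  tb <- tidy(signaling_direction(S, co, k = 1))
  expect_named(tb, c("spot", "x", "y", "vx_sent", "vy_sent",
                     "vx_received", "vy_received"))
  expect_equal(tb$vx_sent, c(2, 0))
  expect_equal(tb$vx_received, c(0, 2))
  expect_equal(tb$x, c(0, 5))
})

test_that("exactly cancelling offsets give the zero vector", {
  S <- rbind(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0))
  co <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  f <- signaling_direction(S, co, k = 2)
  expect_equal(f$Vs[1, ], c(0, 0))
})

test_that("direction field matches the brute-force formula on random couplings", {
  set.seed(13)
  n <- 12
  S <- random_coupling(n, density = 0.4, seed = 13)
  co <- matrix(runif(2 * n, 0, 10), n)
  for (k in c(3, n)) {
    f <- signaling_direction(S, co, k = k)
    ref <- direct_direction_field(S, co, k)
    expect_equal(f$Vs, ref$Vs, tolerance = 1e-12)
    expect_equal(f$Vr, ref$Vr, tolerance = 1e-12)
  }
})

test_that("vector norms equal total sent/received signal", {
  S <- random_coupling(20, density = 0.3, seed = 5)
  co <- matrix(runif(40, 0, 10), 20)
  f <- signaling_direction(S, co, k = 5)
  tot <- received_sent_totals(S)
  norms_s <- sqrt(rowSums(f$Vs^2))
  norms_r <- sqrt(rowSums(f$Vr^2))
  nz <- norms_s > 0
  expect_lt(max(abs(norms_s[nz] - tot$sent[nz]) / tot$sent[nz]), 1e-9)
  nz <- norms_r > 0
  expect_lt(max(abs(norms_r[nz] - tot$received[nz]) / tot$received[nz]), 1e-9)
  expect_error(signaling_direction(S, matrix(1, 20, 2), k = 5), "identical")
})

test_that("grid interpolation averages with a Gaussian kernel", {
  # a grid node sitting on a lone spot inherits its vector
  co <- matrix(c(0, 0), 1)
  V <- matrix(c(1, 0), 1)
  g <- interpolate_field_to_grid(V, co, grid_spacing = 1)
  at_spot <- g[g$x == 0 & g$y == 0, ]
  expect_equal(c(at_spot$vx, at_spot$vy), c(1, 0))

  # zero field stays zero
  g0 <- interpolate_field_to_grid(0 * V, co, grid_spacing = 1)
  expect_true(all(g0$vx == 0 & g0$vy == 0))

  # a uniform field interpolates to itself away from the boundary
  set.seed(3)
  co <- matrix(runif(400, 0, 20), 200)
  V <- matrix(rep(c(0.5, -0.25), each = 200), 200)
  g <- interpolate_field_to_grid(V, co, grid_spacing = 2)
  interior <- g$x > 4 & g$x < 16 & g$y > 4 & g$y < 16
  expect_equal(g$vx[interior], rep(0.5, sum(interior)), tolerance = 1e-9)
  expect_equal(g$vy[interior], rep(-0.25, sum(interior)), tolerance = 1e-9)
})

test_that("cluster aggregation averages over all ordered spot pairs", {
  S <- rbind(c(0, 1), c(0, 0))
  net <- cluster_communication(S, c("A", "B"), n_perm = 9, seed = 1)
  expect_equal(net$strength["A", "B"], 1)
  expect_equal(net$strength["B", "A"], 0)
  # within-cluster block includes diagonal spot pairs: |I| = 4
  net2 <- cluster_communication(S, c("A", "A"), n_perm = 9, seed = 1)
  expect_equal(net2$strength["A", "A"], 1 / 4)
})

test_that("permutation p-values use the add-one estimator and stay in range", {
  S <- random_coupling(30, seed = 8)
  labels <- rep(c("A", "B", "C"), each = 10)
  net <- cluster_communication(S, labels, n_perm = 99, seed = 42)
  expect_true(all(net$pval >= 1 / 100 & net$pval <= 1))
  # a resolver that ignores the permutation makes every pair maximally null
  net_id <- cluster_communication(S, labels, n_perm = 19, seed = 1,
                                  mode = "locations_all",
                                  resolve = function(perm) S)
  expect_true(all(net_id$pval == 1))
})

test_that("location permutation reorders spots before re-aggregation", {
  S <- random_coupling(12, seed = 3)
  labels <- rep(c("A", "B"), each = 6)
  seen <- new.env(); seen$perms <- list()
  net <- cluster_communication(S, labels, n_perm = 5, seed = 2,
                               mode = "locations_within",
                               resolve = function(perm) {
                                 seen$perms <- c(seen$perms, list(perm))
                                 S[perm, perm]
                               })
  # within-cluster permutations never move a spot across clusters
  for (perm in seen$perms) {
    expect_true(all(perm[1:6] %in% 1:6))
    expect_true(all(perm[7:12] %in% 7:12))
  }
  expect_true(all(net$pval >= 1 / 6 & net$pval <= 1))
})

test_that("empty cluster levels give NaN with a warning", {
  S <- random_coupling(4, seed = 1)
  labels <- factor(c("A", "A", "B", "B"), levels = c("A", "B", "C"))
  expect_warning(net <- cluster_communication(S, labels, n_perm = 9, seed = 1),
                 "empty")
  expect_true(all(is.nan(net$strength["C", ])))
})

make_tensor <- function(S_list, spots = NULL) {
  n_s <- nrow(S_list[[1]])
  structure(list(S = lapply(S_list, methods::as, "CsparseMatrix"),
                 n_s = n_s, spots = spots %||% as.character(seq_len(n_s)),
                 eps = 1, rho = 1,
                 diagnostics = list(iterations = 0L, converged = TRUE,
                                    dual_change = 0, total_mass = sum(sapply(S_list, sum)))),
            class = "ccc_tensor")
}

test_that("communication profiles hold per-pair sent and received totals", {
  S <- Matrix::Matrix(rbind(c(0, 1), c(0, 0)), sparse = TRUE)
  prof <- ccc_profile(make_tensor(list(`L-R` = S)))
  expect_equal(unname(prof$M), cbind(c(1, 0), c(0, 1)))

  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(2, 2))
  prof0 <- ccc_profile(make_tensor(list(`L-R` = zero)))
  expect_true(all(prof0$M == 0))

  S_list <- list(`A-B` = Matrix::Matrix(random_coupling(10, seed = 1), sparse = TRUE),
                 `C-D` = Matrix::Matrix(random_coupling(10, seed = 2), sparse = TRUE))
  prof <- ccc_profile(make_tensor(S_list))
  n_lr <- 2
  sent_block <- prof$M[, 1:n_lr]
  received_block <- prof$M[, n_lr + 1:n_lr]
  expect_equal(colSums(sent_block), colSums(received_block), ignore_attr = TRUE)
})

test_that("profile clustering recovers planted communication blocks", {
  set.seed(21)
  n <- 60
  M <- matrix(0, n, 4)
  M[1:30, 1] <- runif(30, 1, 2)    # block 1 sends via pair 1
  M[31:60, 2] <- runif(30, 1, 2)   # block 2 sends via pair 2
  M[, 3:4] <- 0.01 * matrix(runif(2 * n), n)
  truth <- rep(1:2, each = 30)
  lab <- cluster_by_ccc(M, n_clusters = 2, method = "kmeans", seed = 7)
  expect_equal(ari(lab, truth), 1)
  # graph backend: blocks are disconnected in the kNN graph once k spans them
  lab_g <- cluster_by_ccc(M, method = "graph", k_nn = 20, seed = 7)
  expect_equal(ari(lab_g, truth), 1)
  expect_equal(nlevels(cluster_by_ccc(M, n_clusters = 1, seed = 1)), 1)
  expect_warning(lab1 <- cluster_by_ccc(matrix(1, 10, 3), n_clusters = 2),
                 "constant")
  expect_equal(nlevels(lab1), 1)
})

test_that("profile clustering is equivariant under spot permutation", {
  set.seed(2)
  M <- rbind(matrix(runif(40, 1, 2), 20, 2), matrix(runif(40, 5, 6), 20, 2))
  lab <- cluster_by_ccc(M, n_clusters = 2, seed = 3)
  perm <- sample(40)
  lab_p <- cluster_by_ccc(M[perm, ], n_clusters = 2, seed = 3)
  expect_equal(ari(lab_p, lab[perm]), 1)
})
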