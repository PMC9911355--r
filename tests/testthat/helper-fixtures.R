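# Shared fixtures and independent oracles for the test suite.

# random sparse non-negative coupling matrix
random_coupling <- function(n_s, density = 0.1, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n_s, n_s)
  nnz <- max(1, round(density * n_s^2))
  idx <- sample.int(n_s^2, nnz)
  m[idx] <- runif(nnz, 0.1, 2)
  m
}

# small random collective-transport instance (flattened problem + metadata)
random_instance <- function(seed, n_s_max = 4, n_species_max = 2,
                            eps = NULL, rho = 5, T = 10) {
  set.seed(seed)
  n_s <- sample(3:n_s_max, 1)
  n_l <- sample(1:n_species_max, 1)
  n_r <- sample(1:n_species_max, 1)
  coords <- matrix(runif(n_s * 2, 0, 3), n_s)
  D <- euclidean_distance_matrix(coords)
  XL <- matrix(runif(n_l * n_s, 0.1, 1), n_l)
  XR <- matrix(runif(n_r * n_s, 0.1, 1), n_r)
  pairs <- expand.grid(ligand_index = seq_len(n_l), receptor_index = seq_len(n_r))
  pairs <- pairs[sample(nrow(pairs), max(1, nrow(pairs) - 1)), , drop = FALSE]
  costs <- lapply(seq_len(nrow(pairs)), function(i) build_cost(D, T = T, phi = "linear"))
  if (is.null(eps)) eps <- 1e-3 * stats::median(unlist(lapply(costs, `[[`, "cost")))
  prob <- flatten_problem(XL, XR, pairs, costs, eps = eps, rho = rho)
  list(prob = prob, XL = XL, XR = XR, pairs = pairs, costs = costs, D = D,
       coords = coords)
}

# exact linear-program oracle: min <P,C> + rho * untransported mass,
# row sums <= a, column sums <= b, P >= 0 on the stored support
lp_objective <- function(prob) {
  nnz <- length(prob$cost)
  A <- matrix(0, length(prob$a) + length(prob$b), nnz)
  for (e in seq_len(nnz)) {
    A[prob$row[e], e] <- 1
    A[length(prob$a) + prob$col[e], e] <- 1
  }
  keep <- rowSums(A) > 0
  sol <- boot::simplex(a = prob$cost - 2 * prob$rho, A1 = A[keep, , drop = FALSE],
                       b1 = c(prob$a, prob$b)[keep], maxi = FALSE)
  sol$value + prob$rho * (sum(prob$a) + sum(prob$b))
}

# objective value <P,C> + rho * untransported of a solved coupling
entropic_objective <- function(prob, fit) {
  cost_term <- 0; transported <- 0
  n_s <- prob$n_s
  for (p in seq_along(fit$S)) {
    sel <- which(prob$pair_id == p)
    k <- (prob$row[sel] - 1L) %% n_s + 1L
    l <- (prob$col[sel] - 1L) %% n_s + 1L
    Pv <- fit$S[[p]][cbind(k, l)]
    cost_term <- cost_term + sum(Pv * prob$cost[sel])
    transported <- transported + sum(Pv)
  }
  cost_term + prob$rho * (sum(prob$a) + sum(prob$b) - 2 * transported)
}

# brute-force implementation of the printed direction-field formulas
direct_direction_field <- function(S, coords, k) {
  S <- as.matrix(S)
  n <- nrow(S); d <- ncol(coords)
  nrm <- function(v) { nv <- sqrt(sum(v^2)); if (nv > 0) v / nv else v * 0 }
  Vs <- matrix(0, n, d); Vr <- matrix(0, n, d)
  for (i in seq_len(n)) {
    row <- S[i, ]; row[i] <- -Inf
    nb <- order(-row, seq_len(n))[seq_len(min(k, n - 1))]
    nb <- nb[row[nb] > -Inf]
    acc <- rep(0, d)
    for (j in nb) acc <- acc + S[i, j] * nrm(coords[j, ] - coords[i, ])
    if (sum(S[i, -i]) + S[i, i] > 0 && sum(S[i, ]) > 0)
      Vs[i, ] <- sum(S[i, ]) * nrm(acc)
    col <- S[, i]; col[i] <- -Inf
    nb <- order(-col, seq_len(n))[seq_len(min(k, n - 1))]
    nb <- nb[col[nb] > -Inf]
    acc <- rep(0, d)
    for (j in nb) acc <- acc + S[j, i] * nrm(coords[i, ] - coords[j, ])
    if (sum(S[, i]) > 0) Vr[i, ] <- sum(S[, i]) * nrm(acc)
  }
  list(Vs = Vs, Vr = Vr)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_i <- sum(ch2(rowSums(tab)))
  sum_j <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# tiny on-disk dataset for the io tests
write_toy_dataset <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  X <- matrix(c(1, 0, 2,
                0.5, 1, 0,
                0, 2, 1,
                1, 1, 1), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("LIGA", "RECA", "RECB", "LIGB")))
  readr::write_csv(tibble::as_tibble(X, rownames = "spot"), file.path(dir, "expr.csv"))
  readr::write_csv(
    tibble::tibble(spot = c("s1", "s2", "s3"), x = c(0, 1, 0), y = c(0, 0, 1)),
    file.path(dir, "coords.csv"))
  readr::write_csv(
    tibble::tibble(ligand = c("LIGA", "LIGB"), receptor = c("RECA", "RECB"),
                   pathway = c("pwA", "pwB"), limit = c(5, 5)),
    file.path(dir, "lr_db.csv"))
  # same expression as 1-based triplets
  nz <- which(X != 0, arr.ind = TRUE)
  readr::write_csv(
    tibble::tibble(row = nz[, 1], col = nz[, 2], value = X[nz]),
    file.path(dir, "expr_triplet.csv"))
  readr::write_lines(colnames(X), file.path(dir, "genes.txt"))
  readr::write_lines(rownames(X), file.path(dir, "spots.txt"))
  invisible(dir)
}
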