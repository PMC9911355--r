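#' Test genes for association with received signal
#'
#' Screens every gene for dependence of its expression on the amount of
#' signal a spot receives: a cubic B-spline regression of expression on the
#' rank of the received signal is compared against the intercept-only model
#' by an F-test, with Benjamini-Hochberg correction across genes. Regressing
#' on ranks makes the test invariant to monotone rescaling of the received
#' signal, so strongly skewed transport totals do not dominate the fit. The
#' reported direction is the sign of the Spearman correlation between
#' expression and received signal.
#'
#' @param expr a [spatial_expression] or spots x genes matrix.
#' @param r received-signal vector (length n_spots, non-negative, not
#'   constant), e.g. the `received` column of [received_sent_totals()].
#' @param n_knots number of interior spline knots (default 4; the cubic basis
#'   then has `n_knots + 3` degrees of freedom).
#' @param fdr_alpha significance level applied to BH-adjusted q-values when
#'   flagging genes (default 0.05).
#' @return tibble with columns `gene`, `statistic` (F), `p_value`, `q_value`,
#'   `direction` (+1/-1/0) and `significant`, sorted by p-value. Constant
#'   genes get `p_value = 1`.
#' @export
signaling_deg_test <- function(expr, r, n_knots = 4, fdr_alpha = 0.05) {
  Y <- if (inherits(expr, "spatial_expression")) expr$X else as.matrix(expr)
  if (length(r) != nrow(Y)) abort("r must have one value per spot")
  if (any(r < 0)) abort("received signal must be non-negative")
  if (diff(range(r)) == 0) abort("received signal is constant: association undefined")
  n <- nrow(Y)
  x <- rank(r, ties.method = "average")
  B <- splines::bs(x, df = n_knots + 3, degree = 3)
  Xd <- cbind(1, B)
  qr_x <- qr(Xd)
  df1 <- qr_x$rank - 1
  df2 <- n - qr_x$rank
  if (df2 <= 0) abort("too few spots for the spline basis")

  fitted <- qr.fitted(qr_x, Y)
  rss1 <- colSums((Y - fitted)^2)
  rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  const <- rss0 <= .Machine$double.eps * n
  Fstat[const] <- 0
  p[const] <- 1
  q <- p.adjust(p, method = "BH")
  dir_cor <- suppressWarnings(cor(Y, r, method = "spearman"))
  direction <- ifelse(is.na(dir_cor), 0, sign(dir_cor))

  out <- tibble(
    gene = colnames(Y) %||% paste0("g", seq_len(ncol(Y))),
    statistic = unname(Fstat), p_value = unname(p), q_value = unname(q),
    direction = as.vector(direction),
    significant = q < fdr_alpha
  )
  dplyr::arrange(out, .data$p_value)
}

#' Unique impact of received signal on a target gene
#'
#' Trains a random-forest regression of the target gene on the received
#' signal together with the genes most correlated (absolute Spearman) with
#' the target, and returns the normalized impurity-decrease (Gini) importance
#' of the received-signal feature. Including strongly correlated genes as
#' competitors isolates the part of the target's variation that only the
#' inferred communication explains, rather than intracellular co-expression.
#'
#' @param expr a [spatial_expression] or spots x genes matrix.
#' @param r received-signal vector.
#' @param target_gene gene name (column of `expr`).
#' @param n_top_corr number of competitor genes (default 20); with 0, the
#'   received signal is the sole feature and its importance is 1.
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed for the forest.
#' @return list with `importance` (share of total impurity decrease
#'   attributed to the received signal, in [0, 1]), `features`, and the full
#'   named importance vector `all_importance`.
#' @export
signaling_importance <- function(expr, r, target_gene, n_top_corr = 20,
                                 n_trees = 500, seed = 1) {
  Y <- if (inherits(expr, "spatial_expression")) expr$X else as.matrix(expr)
  if (!target_gene %in% colnames(Y)) abort(paste0("target gene not found: ", target_gene))
  if (length(r) != nrow(Y)) abort("r must have one value per spot")
  y <- Y[, target_gene]
  pool <- setdiff(colnames(Y), target_gene)
  if (n_top_corr > length(pool)) {
    warn(sprintf("only %d candidate genes available; using all", length(pool)))
    n_top_corr <- length(pool)
  }
  feats <- character(0)
  if (n_top_corr > 0) {
    cc <- abs(suppressWarnings(cor(Y[, pool, drop = FALSE], y, method = "spearman")))
    cc[is.na(cc)] <- 0
    feats <- pool[order(-cc, seq_along(pool))][seq_len(n_top_corr)]
  }
  dat <- data.frame(.target = y, .received_signal = r,
                    Y[, feats, drop = FALSE], check.names = FALSE)
  # all features considered at every split (regression-forest convention),
  # so competitor genes only win splits they genuinely explain better
  rf <- ranger::ranger(
    dependent.variable.name = ".target", data = dat,
    num.trees = n_trees, importance = "impurity", seed = seed,
    mtry = ncol(dat) - 1L,
    respect.unordered.factors = "order"
  )
  imp <- rf$variable.importance
  imp[imp < 0] <- 0
  total <- sum(imp)
  share <- if (total > 0) unname(imp[".received_signal"]) / total else NA_real_
  list(importance = share,
       features = c(".received_signal", feats),
       all_importance = imp / max(total, .Machine$double.eps))
}
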