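#' @title Score likelihood tables
#' @description A `score_table` holds conditional summed-score likelihoods
#'   on a quadrature grid: a matrix with one row per score (0..S) and one
#'   column per grid node.  The conditioning is either the pair
#'   `(eta, xi_n)` — columns run over the product of the primary nodes
#'   (fastest) and the focal cluster's specific nodes — or `eta` only.
#'   At every node the values sum to 1 over scores: the scores partition
#'   the response space.
#' @name score_table
NULL

new_score_table <- function(values, conditioning, cluster = NA_integer_,
                            n_eta, n_xi = 1L) {
  structure(list(values = values, scores = seq_len(nrow(values)) - 1L,
                 conditioning = conditioning, cluster = cluster,
                 n_eta = n_eta, n_xi = n_xi),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("Score likelihood table: scores 0..", max(x$scores),
      ", ", ncol(x$values), " grid node(s), conditioning: ",
      if (x$conditioning == "eta_xi") "(eta, xi)" else "eta only", "\n", sep = "")
  invisible(x)
}

# item response probabilities for the items in `idx` over the (eta, xi)
# product grid (xi_pts = NULL: eta grid only); returns items x nodes matrix
# of T(1), nodes ordered eta-fastest
cluster_irf <- function(model, idx, grid, xi_pts = NULL) {
  n_eta <- nrow(grid$eta_pts)
  A0 <- a0_matrix(model)[idx, , drop = FALSE]
  eta_lin <- A0 %*% t(grid$eta_pts)                       # items x n_eta
  if (is.null(xi_pts)) {
    return(stats::plogis(model$items$c[idx] + eta_lin))
  }
  lin <- eta_lin[, rep(seq_len(n_eta), length(xi_pts)), drop = FALSE] +
    outer(model$items$a_spec[idx], rep(xi_pts, each = n_eta)) +
    model$items$c[idx]
  stats::plogis(lin)
}

#' Stage I: within-cluster summed-score likelihoods
#'
#' Accumulates the likelihoods \eqn{P_n(s_n \mid \eta, \xi_n)} of the
#' within-cluster summed scores by the Lord-Wingersky recursion: initialize
#' with the first item's category probabilities, then add one item at a
#' time, each step convolving the current table with the new item's
#' `T(0)`/`T(1)`.
#'
#' For `cluster = 0` (items loading on no specific dimension) the table is
#' conditioned on `eta` only.  An empty cluster yields the trivial table
#' assigning probability 1 to score 0 everywhere.
#'
#' @param model a [two_tier_model()].
#' @param cluster cluster index (0..N).
#' @param grid an [make_grid()] grid.
#' @return a [score_table] with `I_n + 1` rows, conditioned on
#'   `(eta, xi_n)` (or `eta` for cluster 0 / empty clusters).
#' @export
within_cluster_likelihoods <- function(model, cluster, grid) {
  idx <- which(model$items$cluster == cluster)
  n_eta <- nrow(grid$eta_pts)
  if (length(idx) == 0L) {
    return(new_score_table(matrix(1, 1L, n_eta), "eta", as.integer(cluster), n_eta))
  }
  # an "empty" specific dimension (all loadings zero) contributes nothing:
  # the likelihoods depend on eta alone, so skip the xi axis entirely
  eta_only <- cluster == 0L || all(model$items$a_spec[idx] == 0)
  T1 <- cluster_irf(model, idx, grid,
                    xi_pts = if (eta_only) NULL else grid$xi[[cluster]]$pts)
  n_xi <- if (eta_only) 1L else length(grid$xi[[cluster]]$pts)

  P <- rbind(1 - T1[1L, ], T1[1L, ])
  for (i in seq_along(idx)[-1L]) {
    t1 <- T1[i, ]
    t0 <- 1 - t1
    nr <- nrow(P)
    Pnew <- matrix(0, nr + 1L, ncol(P))
    Pnew[1L, ] <- P[1L, ] * t0
    Pnew[nr + 1L, ] <- P[nr, ] * t1
    if (nr > 1L) {
      Pnew[2L:nr, ] <- P[2L:nr, , drop = FALSE] * rep(t0, each = nr - 1L) +
        P[1L:(nr - 1L), , drop = FALSE] * rep(t1, each = nr - 1L)
    }
    P <- Pnew
  }
  new_score_table(P, if (eta_only) "eta" else "eta_xi", as.integer(cluster),
                  n_eta, n_xi)
}

# weighted sum over the xi blocks of an eta-fastest (eta, xi) value matrix
xi_reduce <- function(values, n_eta, wts) {
  out <- matrix(0, nrow(values), n_eta)
  for (k in seq_along(wts)) {
    cols <- ((k - 1L) * n_eta + 1L):(k * n_eta)
    out <- out + values[, cols, drop = FALSE] * wts[k]
  }
  out
}

#' Integrate the specific dimension out of a Stage-I table
#'
#' Approximates \eqn{P_n(s_n \mid \eta) = \int P_n(s_n \mid \eta, \xi_n)
#' g(\xi_n)\, d\xi_n} by the rectangular quadrature sum
#' \eqn{\sum_q P_n(s_n \mid \eta, Y_q) W_n(Y_q)}, leaving the likelihoods a
#' function of the primary dimension only.
#'
#' @param table a `(eta, xi)`-conditioned [score_table].
#' @param grid the grid the table was built on.
#' @return an `eta`-only [score_table] with the same score range.
#' @export
marginalize_specific <- function(table, grid) {
  if (table$conditioning != "eta_xi") {
    stop("table is not conditioned on (eta, xi)", call. = FALSE)
  }
  w <- grid$xi[[table$cluster]]$w
  if (length(w) != table$n_xi) {
    stop("grid weights do not match the table's specific dimension", call. = FALSE)
  }
  new_score_table(xi_reduce(table$values, table$n_eta, w), "eta",
                  table$cluster, table$n_eta)
}

# Stage I + marginalization, with the cluster-0 shortcut
cluster_likelihoods_eta <- function(model, cluster, grid) {
  tb <- within_cluster_likelihoods(model, cluster, grid)
  if (tb$conditioning == "eta_xi") tb <- marginalize_specific(tb, grid)
  tb
}

#' Stage II: combine cluster likelihood tables
#'
#' Treats each cluster's marginal table as a polytomous pseudo-item with
#' `I_n + 1` categories and convolves them: the likelihood of total score
#' `s` accumulates every pair of previous score and cluster score adding to
#' `s`.  The operation is associative and order-invariant.  An empty list
#' yields the trivial table (score 0 with likelihood 1).
#'
#' @param tables list of `eta`-only [score_table]s on a common grid.
#' @param n_nodes number of grid nodes, required only when `tables` is
#'   empty.
#' @return an `eta`-only [score_table] with `sum(S_n) + 1` rows.
#' @export
combine_clusters <- function(tables, n_nodes = NULL) {
  if (length(tables) == 0L) {
    if (is.null(n_nodes)) stop("n_nodes needed for an empty combination", call. = FALSE)
    return(new_score_table(matrix(1, 1L, n_nodes), "eta", NA_integer_, n_nodes))
  }
  for (tb in tables) {
    if (tb$conditioning != "eta") {
      stop("combine_clusters needs eta-only tables; marginalize first", call. = FALSE)
    }
  }
  nc <- unique(vapply(tables, function(tb) ncol(tb$values), integer(1)))
  if (length(nc) != 1L) stop("tables are on different grids", call. = FALSE)

  L <- matrix(1, 1L, nc)
  for (tb in tables) {
    P <- tb$values
    Lnew <- matrix(0, nrow(L) + nrow(P) - 1L, nc)
    for (s in seq_len(nrow(P))) {
      rows <- s:(s + nrow(L) - 1L)
      Lnew[rows, ] <- Lnew[rows, , drop = FALSE] + L * rep(P[s, ], each = nrow(L))
    }
    L <- Lnew
  }
  new_score_table(L, "eta", NA_integer_, tables[[1L]]$n_eta)
}

#' Rest-score likelihoods for a focal cluster
#'
#' Combines the marginalized Stage-I tables of every cluster except the
#' focal one, yielding \eqn{R_n(s_{(n)} \mid \eta)} for rest scores
#' \eqn{0..S_{(n)}}.
#'
#' @inheritParams within_cluster_likelihoods
#' @param focal the focal cluster index.
#' @return an `eta`-only [score_table].
#' @export
rest_score_likelihoods <- function(model, focal, grid) {
  others <- setdiff(sort(unique(model$items$cluster)), focal)
  if (length(others) == 0L) stop("no rest items", call. = FALSE)
  combine_clusters(lapply(others, function(n) cluster_likelihoods_eta(model, n, grid)))
}

#' Total summed-score likelihoods
#'
#' Runs both stages over all clusters, producing \eqn{L(s \mid \eta)} for
#' the total summed score — the engine behind the summed-score EAP table.
#'
#' @inheritParams within_cluster_likelihoods
#' @return an `eta`-only [score_table] over scores `0..S`.
#' @export
total_score_likelihoods <- function(model, grid) {
  ids <- sort(unique(model$items$cluster))
  combine_clusters(lapply(ids, function(n) cluster_likelihoods_eta(model, n, grid)))
}
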