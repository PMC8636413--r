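# Independent oracles used across the suite.  These deliberately avoid the
# package's recursion code paths: likelihoods come from direct enumeration
# of response patterns and explicit quadrature sums.

# within-cluster summed-score likelihoods by enumerating the 2^I response
# patterns of that cluster's items; returns (I+1) x nodes matrix over the
# (eta, xi) product grid (eta-fastest), computed from item_response() only
enum_cluster_table <- function(model, cluster, grid) {
  idx <- which(model$items$cluster == cluster)
  n_eta <- nrow(grid$eta_pts)
  xi_pts <- grid$xi[[cluster]]$pts
  eta_nodes <- grid$eta_pts[rep(seq_len(n_eta), length(xi_pts)), , drop = FALSE]
  xi_nodes <- rep(xi_pts, each = n_eta)
  out <- matrix(0, length(idx) + 1L, nrow(eta_nodes))
  pats <- as.matrix(expand.grid(rep(list(0:1), length(idx))))
  for (p in seq_len(nrow(pats))) {
    lik <- rep(1, nrow(eta_nodes))
    for (k in seq_along(idx)) {
      r <- item_response(model_item(model, idx[k]), eta_nodes, xi_nodes)
      lik <- lik * if (pats[p, k] == 1) r$T1 else r$T0
    }
    s <- sum(pats[p, ])
    out[s + 1L, ] <- out[s + 1L, ] + lik
  }
  out
}

# small random model with 2-4 clusters for property loops
rand_model <- function(seed, max_items = 12L, M = 1L) {
  set.seed(seed * 7L + 1L)
  N <- sample(2:4, 1L)
  per <- sample(1:3, N, replace = TRUE)
  while (sum(per) > max_items) per[which.max(per)] <- per[which.max(per)] - 1L
  synth_model(seed, M = M, N = N, items_per_cluster = pmax(per, 1L))
}

# random score-combination probability table (rows x cols), normalized
rand_prob_table <- function(seed, nr = NULL, nc = NULL) {
  set.seed(seed + 1000L)
  if (is.null(nr)) nr <- sample(2:6, 1L)
  if (is.null(nc)) nc <- sample(2:8, 1L)
  m <- matrix(rexp(nr * nc), nr, nc)
  m / sum(m)
}
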