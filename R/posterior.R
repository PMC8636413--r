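#' Summed-score posteriors for the primary dimension(s)
#'
#' For every total summed score `s`, forms the normalized posterior of
#' \eqn{\eta} on the quadrature grid,
#' \eqn{p(\eta \mid s) \propto L(s \mid \eta) h(\eta)}, together with its
#' marginal probability \eqn{p(s)}, posterior mean (the summed-score EAP
#' scale score) and posterior variance (its error variance).  All moments
#' are quadrature sums over the discrete posterior.
#'
#' @param model a [two_tier_model()].
#' @param grid an [make_grid()] grid.
#' @return object of class `score_posteriors`: list with `table` (data
#'   frame: `s`, `prob`, `eap*`, `var*` columns), `posterior` (nodes x
#'   scores matrix of normalized weights), `mean` (scores x M), `var`
#'   (list of M x M matrices), and `grid`.
#' @export
lw20_posteriors <- function(model, grid) {
  L <- total_score_likelihoods(model, grid)$values      # (S+1) x n_eta
  joint <- L * rep(grid$eta_w, each = nrow(L))
  p <- rowSums(joint)
  post <- t(joint / p)                                  # nodes x scores
  M <- grid$M
  mu <- crossprod(post, grid$eta_pts)                   # scores x M
  vars <- vector("list", nrow(L))
  for (s in seq_len(nrow(L))) {
    cent <- sweep(grid$eta_pts, 2L, mu[s, ])
    vars[[s]] <- crossprod(cent * post[, s], cent)
  }
  tab <- data.frame(s = seq_len(nrow(L)) - 1L, prob = p)
  if (M == 1L) {
    tab$eap <- mu[, 1L]
    tab$var <- vapply(vars, function(v) v[1L, 1L], numeric(1))
  } else {
    for (d in seq_len(M)) tab[[paste0("eap_", d)]] <- mu[, d]
    for (d in seq_len(M)) for (e in d:M) {
      tab[[paste0("var_", d, e)]] <- vapply(vars, function(v) v[d, e], numeric(1))
    }
  }
  structure(list(table = tab, posterior = post, mean = mu, var = vars,
                 grid = grid),
            class = "score_posteriors")
}

#' @export
print.score_posteriors <- function(x, digits = 3, ...) {
  cat("Summed-score EAP table (", nrow(x$table), " scores)\n", sep = "")
  print(round(x$table, digits))
  invisible(x)
}

# moment column names for a combo table
combo_moment_names <- function(M) {
  if (M == 1L) {
    c("mu0", "s00", "mu_n", "s_nn", "s0n")
  } else {
    c(paste0("mu0_", seq_len(M)),
      unlist(lapply(seq_len(M), function(d) paste0("s00_", d, d:M))),
      "mu_n", "s_nn", paste0("s0n_", seq_len(M)))
  }
}

#' Score-combination posteriors for a focal cluster
#'
#' For the focal cluster `n`, every pair of within-cluster summed score
#' \eqn{s_n} and rest score \eqn{s_{(n)}} defines a posterior over
#' \eqn{(\eta, \xi_n)}:
#' \deqn{p(\eta, \xi_n \mid s_n, s_{(n)}) \propto
#'   P_n(s_n \mid \eta, \xi_n)\, R_n(s_{(n)} \mid \eta)\,
#'   g(\xi_n)\, h(\eta).}
#' The normalizing constant is the marginal probability of observing the
#' score combination.  This function computes, for all
#' `(I_n + 1) x (S_(n) + 1)` combinations, the marginal probability and
#' the posterior mean vector and covariance matrix (primary dimensions
#' first, focal specific dimension last) by quadrature on the product grid.
#'
#' Combinations with numerically zero probability are retained with
#' `prob = 0` and `NaN` moments so the table shape stays predictable.
#'
#' @param model a [two_tier_model()].
#' @param focal focal cluster index (1..N).
#' @param grid an [make_grid()] grid.
#' @return object of class `combo_table`: list with `combos` (data frame
#'   with columns `s_n`, `s_rest`, `prob` and moment columns `mu0*`,
#'   `s00*`, `mu_n`, `s_nn`, `s0n*`), `p` (probability matrix, rows =
#'   focal scores), plus the retained Stage-I/II components needed to
#'   reconstruct any combination's posterior.
#' @seealso [combo_posterior()] for a single combination with its grid
#'   posterior, [normal_approx()] for the normal approximation.
#' @export
combo_posteriors <- function(model, focal, grid) {
  if (focal < 1L || focal > model$N) stop("focal cluster out of range", call. = FALSE)
  P1 <- within_cluster_likelihoods(model, focal, grid)
  R <- rest_score_likelihoods(model, focal, grid)
  n_eta <- nrow(grid$eta_pts)
  M <- grid$M

  if (P1$conditioning == "eta_xi") {
    wxi <- grid$xi[[focal]]$w
    xpts <- grid$xi[[focal]]$pts
    B <- xi_reduce(P1$values, n_eta, wxi)
    C1 <- xi_reduce(P1$values, n_eta, wxi * xpts)
    C2 <- xi_reduce(P1$values, n_eta, wxi * xpts^2)
  } else {
    # focal cluster with no specific loading: xi posterior equals its prior
    mn <- model$xi_mean[focal]; vr <- model$xi_var[focal]
    B <- P1$values
    C1 <- B * mn
    C2 <- B * (vr + mn^2)
  }

  D <- t(R$values) * grid$eta_w                          # n_eta x (Sr+1)
  p <- B %*% D                                           # (S1+1) x (Sr+1)

  n1 <- nrow(B); nr <- ncol(D)
  combos <- data.frame(s_n = rep(seq_len(n1) - 1L, nr),
                       s_rest = rep(seq_len(nr) - 1L, each = n1))
  pv <- as.vector(p)
  combos$prob <- pv

  mom <- function(num) as.vector(num) / pv               # NaN when prob = 0
  mu0 <- matrix(0, n1 * nr, M)
  for (d in seq_len(M)) mu0[, d] <- mom(B %*% (D * grid$eta_pts[, d]))
  mu_n <- mom(C1 %*% D)

  cols <- list()
  for (d in seq_len(M)) {
    cols[[if (M == 1L) "mu0" else paste0("mu0_", d)]] <- mu0[, d]
  }
  for (d in seq_len(M)) for (e in d:M) {
    sde <- mom(B %*% (D * grid$eta_pts[, d] * grid$eta_pts[, e])) -
      mu0[, d] * mu0[, e]
    if (d == e) sde <- ifelse(sde > -1e-10 & sde < 0, 0, sde)
    cols[[if (M == 1L) "s00" else paste0("s00_", d, e)]] <- sde
  }
  cols$mu_n <- mu_n
  snn <- mom(C2 %*% D) - mu_n^2
  cols$s_nn <- ifelse(snn > -1e-10 & snn < 0, 0, snn)
  for (d in seq_len(M)) {
    cols[[if (M == 1L) "s0n" else paste0("s0n_", d)]] <-
      mom(C1 %*% (D * grid$eta_pts[, d])) - mu0[, d] * mu_n
  }
  for (nm in combo_moment_names(M)) combos[[nm]] <- cols[[nm]]

  structure(list(combos = combos, p = p, focal = as.integer(focal), M = M,
                 model = model, grid = grid,
                 stage1 = P1, B = B, C1 = C1, C2 = C2, rest = R),
            class = "combo_table")
}

#' @export
print.combo_table <- function(x, digits = 3, ...) {
  cat("Score-combination posterior table, focal cluster ", x$focal,
      " (", nrow(x$combos), " combinations, total probability ",
      format(sum(x$combos$prob), digits = 6), ")\n", sep = "")
  print(round(x$combos, digits))
  invisible(x)
}

#' Posterior of a single score combination
#'
#' Reconstructs the normalized grid posterior of \eqn{(\eta, \xi_n)} for
#' one `(s_n, s_rest)` pair from a [combo_posteriors()] table.
#'
#' @param ct a `combo_table`.
#' @param s_n focal-cluster summed score.
#' @param s_rest rest score.
#' @return object of class `combo_posterior`: `prob`, `mu` (length M+1),
#'   `sigma` ((M+1) x (M+1)), and the normalized weights: `w_eta` over the
#'   primary grid and, when the focal cluster has a specific grid, `w_full`
#'   over the `(eta, xi)` product grid (eta-fastest) with `xi_pts`.
#' @export
combo_posterior <- function(ct, s_n, s_rest) {
  i <- s_n + 1L; j <- s_rest + 1L
  if (i < 1L || i > nrow(ct$p) || j < 1L || j > ncol(ct$p)) {
    stop("score combination out of range", call. = FALSE)
  }
  prob <- ct$p[i, j]
  grid <- ct$grid
  M <- ct$M
  row <- ct$combos[ct$combos$s_n == s_n & ct$combos$s_rest == s_rest, ]
  nm <- combo_moment_names(M)
  mu <- c(unlist(row[grep("^mu0", nm, value = TRUE)], use.names = FALSE), row$mu_n)
  sigma <- matrix(0, M + 1L, M + 1L)
  for (d in seq_len(M)) for (e in d:M) {
    v <- row[[if (M == 1L) "s00" else paste0("s00_", d, e)]]
    sigma[d, e] <- sigma[e, d] <- v
  }
  for (d in seq_len(M)) {
    v <- row[[if (M == 1L) "s0n" else paste0("s0n_", d)]]
    sigma[d, M + 1L] <- sigma[M + 1L, d] <- v
  }
  sigma[M + 1L, M + 1L] <- row$s_nn

  w_eta <- ct$B[i, ] * grid$eta_w * ct$rest$values[j, ]
  w_full <- NULL; xi_pts <- NULL
  if (ct$stage1$conditioning == "eta_xi") {
    wxi <- grid$xi[[ct$focal]]$w
    n_eta <- nrow(grid$eta_pts)
    w_full <- ct$stage1$values[i, ] *
      rep(wxi, each = n_eta) *
      rep(ct$rest$values[j, ] * grid$eta_w, length(wxi))
    if (prob > 0) w_full <- w_full / sum(w_full)
    xi_pts <- grid$xi[[ct$focal]]$pts
  }
  if (prob > 0) w_eta <- w_eta / sum(w_eta)
  structure(list(s_n = s_n, s_rest = s_rest, prob = prob,
                 mu = mu, sigma = sigma, M = M,
                 w_eta = w_eta, w_full = w_full, xi_pts = xi_pts,
                 grid = grid, focal = ct$focal),
            class = "combo_posterior")
}

#' Multivariate normal approximation to a posterior
#'
#' Builds a normal density object from a posterior mean and covariance —
#' typically the quadrature moments of a score-combination posterior.  The
#' approximation supports density evaluation and rectangle/band probability
#' queries via [prob_rect()] and [band_volume()].
#'
#' @param x a [combo_posterior()], or a numeric mean vector.
#' @param sigma covariance matrix (when `x` is a mean vector); must be
#'   positive definite.
#' @return object of class `mvn_approx` with elements `mean` and `cov`.
#' @export
normal_approx <- function(x, sigma = NULL) {
  if (inherits(x, "combo_posterior")) {
    mu <- x$mu; sigma <- x$sigma
  } else {
    mu <- as.numeric(x)
  }
  sigma <- as.matrix(sigma)
  if (any(!is.finite(mu)) || any(!is.finite(sigma))) {
    stop("degenerate posterior", call. = FALSE)
  }
  tryCatch(chol(sigma), error = function(e) stop("degenerate posterior", call. = FALSE))
  structure(list(mean = mu, cov = sigma), class = "mvn_approx")
}

#' @export
print.mvn_approx <- function(x, ...) {
  cat("Normal posterior approximation\n  mean:", round(x$mean, 3),
      "\n  cov:\n")
  print(round(x$cov, 3))
  invisible(x)
}

#' Density of a normal approximation
#' @param obj an [normal_approx()] object.
#' @param x matrix of evaluation points (one row per point).
#' @return numeric vector of density values.
#' @export
mvn_density <- function(obj, x) {
  dmvn_ordinate(x, obj$mean, obj$cov)
}

#' Rectangle probability of a bivariate normal approximation
#'
#' Probability mass of an axis-aligned rectangle under a 2-dimensional
#' [normal_approx()], computed by a midpoint rule on an `n` x `n` grid
#' spanning `span` posterior standard deviations around the mean (the same
#' integration scheme as [band_volume()]).  Infinite bounds are allowed.
#'
#' @param obj a 2-dimensional `mvn_approx`.
#' @param lower,upper length-2 numeric bounds.
#' @param n grid resolution per axis.
#' @param span half-width of the integration box in posterior SDs.
#' @return probability in `[0, 1]`.
#' @export
prob_rect <- function(obj, lower, upper, n = 201L, span = 6) {
  band_volume(obj,
              lower_fn = function(x) rep(lower[2L], length(x)),
              upper_fn = function(x) rep(upper[2L], length(x)),
              xlim = c(lower[1L], upper[1L]), n = n, span = span)
}

#' Probability mass between two curves under a bivariate normal
#'
#' Integrates a 2-dimensional [normal_approx()] density over the band
#' `lower_fn(x) <= y <= upper_fn(x)` (optionally clipped to `xlim`) with a
#' midpoint rule on an `n` x `n` box spanning `span` posterior SDs around
#' the mean in each coordinate.
#'
#' @param obj a 2-dimensional `mvn_approx`.
#' @param lower_fn,upper_fn vectorized functions of the first coordinate
#'   returning the band bounds on the second.
#' @param xlim optional limits on the first coordinate.
#' @param n grid resolution per axis.
#' @param span half-width of the integration box in posterior SDs.
#' @return probability in `[0, 1]`.
#' @export
band_volume <- function(obj, lower_fn, upper_fn, xlim = NULL,
                        n = 201L, span = 6) {
  sd1 <- sqrt(obj$cov[1L, 1L]); sd2 <- sqrt(obj$cov[2L, 2L])
  xs <- seq(obj$mean[1L] - span * sd1, obj$mean[1L] + span * sd1, length.out = n)
  ys <- seq(obj$mean[2L] - span * sd2, obj$mean[2L] + span * sd2, length.out = n)
  dx <- xs[2L] - xs[1L]; dy <- ys[2L] - ys[1L]
  pts <- cbind(rep(xs, times = n), rep(ys, each = n))
  dens <- mvn_density(obj, pts)
  lo <- lower_fn(pts[, 1L]); hi <- upper_fn(pts[, 1L])
  inside <- pts[, 2L] >= lo & pts[, 2L] <= hi
  if (!is.null(xlim)) {
    inside <- inside & pts[, 1L] >= xlim[1L] & pts[, 1L] <= xlim[2L]
  }
  min(sum(dens[inside]) * dx * dy, 1)
}
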