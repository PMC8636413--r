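#' Rectangular quadrature from density ordinates
#'
#' Normalizes nonnegative density ordinates over an ordered set of points so
#' the weights sum to one.  This is the weighting convention used throughout
#' the recursions: equally spaced points, weights proportional to the prior
#' density at each point.
#'
#' @param points strictly increasing numeric vector.
#' @param ordinates nonnegative density values at `points`.
#' @return list with elements `pts` and `w` (weights summing to 1).
#' @export
rect_quad <- function(points, ordinates) {
  if (any(diff(points) <= 0)) stop("points must be strictly increasing", call. = FALSE)
  if (length(points) != length(ordinates)) {
    stop("points and ordinates differ in length", call. = FALSE)
  }
  if (any(ordinates < 0) || sum(ordinates) <= 0) {
    stop("ordinates must be nonnegative with positive sum", call. = FALSE)
  }
  list(pts = as.numeric(points), w = as.numeric(ordinates) / sum(ordinates))
}

# multivariate normal density ordinates at rows of x (no normalization needed
# beyond the standard constant; weights are renormalized anyway)
dmvn_ordinate <- function(x, mean, cov) {
  x <- as.matrix(x)
  L <- tryCatch(chol(cov),
                error = function(e) stop("prior covariance must be positive definite",
                                         call. = FALSE))
  z <- backsolve(L, t(x) - mean, transpose = TRUE)
  exp(-0.5 * colSums(z^2)) / ((2 * pi)^(ncol(x) / 2) * prod(diag(L)))
}

#' Build the quadrature grids for a two-tier model
#'
#' Constructs `Q` equally spaced points per dimension on `range`.  For the
#' primary dimensions the grid is the direct product of the `M` univariate
#' point sets, with weights proportional to the (possibly correlated)
#' multivariate normal prior ordinate at each node, normalized to sum to 1.
#' Each specific dimension gets a univariate grid weighted by its own normal
#' prior.
#'
#' The default `Q = 49` on `[-6, 6]` is a practical resolution for scoring;
#' coarse grids (e.g. `Q = 5` on `[-2, 2]`) are useful only for tracing the
#' arithmetic of the recursions by hand.
#'
#' @param model a [two_tier_model()].
#' @param Q number of points per dimension (>= 2).
#' @param range length-2 numeric, grid endpoints.
#' @return object of class `lw_grid` with elements `eta_pts` (nodes x M
#'   matrix), `eta_w` (normalized weights), `eta_idx` (nodes x M matrix of
#'   per-dimension level indices), `dim_pts` (the shared univariate point
#'   set), and `xi` (per-cluster list of `pts`/`w`).
#' @examples
#' m <- two_tier_model(data.frame(cluster = 1, a0 = 1, a_spec = 1, c = 0))
#' g <- make_grid(m, Q = 5, range = c(-2, 2))
#' round(g$eta_w, 3)  # .054 .244 .403 .244 .054
#' @export
make_grid <- function(model, Q = 49, range = c(-6, 6)) {
  if (Q < 2) stop("Q must be >= 2", call. = FALSE)
  if (length(range) != 2 || range[1] >= range[2]) {
    stop("range must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  pts <- seq(range[1], range[2], length.out = Q)
  M <- model$M

  idx <- as.matrix(expand.grid(rep(list(seq_len(Q)), M)))
  dimnames(idx) <- NULL
  eta_pts <- matrix(pts[idx], nrow(idx), M)
  dens <- dmvn_ordinate(eta_pts, model$prior_mean, model$prior_cov)
  eta_w <- dens / sum(dens)

  xi <- lapply(seq_len(model$N), function(n) {
    rect_quad(pts, stats::dnorm(pts, model$xi_mean[n], sqrt(model$xi_var[n])))
  })

  structure(list(eta_pts = eta_pts, eta_w = eta_w, eta_idx = idx,
                 dim_pts = pts, M = M, xi = xi, Q = Q, range = range),
            class = "lw_grid")
}

#' @export
print.lw_grid <- function(x, ...) {
  cat("Rectangular quadrature grid: Q =", x$Q, "on [",
      x$range[1], ",", x$range[2], "] per dimension;",
      nrow(x$eta_pts), "primary node(s),", length(x$xi), "specific grid(s)\n")
  invisible(x)
}
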