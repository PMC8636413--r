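# Downstream procedures built on score-combination posterior tables:
# region classification against cut scores, score-combination percentiles,
# subscore screening via a probability-weighted regression band, and
# discrete high-density regions for aberrance detection.

# marginal posterior weights of one latent dimension for every combo.
# dim: "eta" / "eta_d" / "xi".  Returns list(pts, w) with w a
# (points x n_combos) matrix, combo order matching ct$combos.
combo_marginals <- function(ct, dim) {
  grid <- ct$grid
  n_eta <- nrow(grid$eta_pts)
  n1 <- nrow(ct$p); nr <- ncol(ct$p)
  pv <- as.vector(ct$p)
  R <- ct$rest$values

  if (dim == "xi") {
    if (ct$stage1$conditioning != "eta_xi") {
      # focal cluster without specific loadings: posterior = prior grid
      g <- rect_quad(grid$dim_pts,
                     stats::dnorm(grid$dim_pts, ct$model$xi_mean[ct$focal],
                                  sqrt(ct$model$xi_var[ct$focal])))
      w <- matrix(g$w, length(g$w), n1 * nr)
      w[, pv == 0] <- NaN
      return(list(pts = g$pts, w = w))
    }
    xg <- grid$xi[[ct$focal]]
    DW <- t(R) * grid$eta_w                       # n_eta x nr
    w <- matrix(0, length(xg$pts), n1 * nr)
    for (k in seq_along(xg$pts)) {
      cols <- ((k - 1L) * n_eta + 1L):(k * n_eta)
      E <- (ct$stage1$values[, cols, drop = FALSE] %*% DW) * xg$w[k]  # n1 x nr
      w[k, ] <- as.vector(E)
    }
  } else {
    d <- if (dim == "eta") 1L else as.integer(sub("^eta_", "", dim))
    if (is.na(d) || d < 1L || d > ct$M) stop("unknown dimension '", dim, "'", call. = FALSE)
    grp <- grid$eta_idx[, d]
    w <- matrix(0, length(grid$dim_pts), n1 * nr)
    for (j in seq_len(nr)) {
      blk <- t(ct$B) * (grid$eta_w * R[j, ])      # n_eta x n1
      w[, ((j - 1L) * n1 + 1L):(j * n1)] <- rowsum(blk, grp)
    }
  }
  w <- sweep(w, 2L, pv, "/")                      # NaN where prob = 0
  list(pts = grid$dim_pts, w = w)
}

#' Classify posterior mass into achievement regions
#'
#' Cut scores on a latent scale divide it into ordered regions (e.g.
#' emerging / progressing / proficient).  For each score combination and
#' each requested dimension, this computes the probability that the latent
#' variable falls in each region, from the marginal posterior of that
#' dimension.
#'
#' By default the probabilities are sums of the normalized quadrature
#' marginal's weights in each region (each grid point's cell extends to the
#' midpoints between neighbours, so a cut is effectively snapped to the
#' nearest cell boundary).  With `method = "normal"` the marginal of the
#' normal approximation is used instead and the probabilities are
#' differences of normal CDFs.
#'
#' @param ct a [combo_posteriors()] table.
#' @param cuts named list of strictly increasing cut-score vectors; names
#'   select dimensions: `"eta"` (when `M = 1`), `"eta_1"`..`"eta_M"`, or
#'   `"xi"` (the focal cluster's specific dimension).
#' @param method `"quadrature"` (default) or `"normal"`.
#' @param combos optional data frame of `s_n`, `s_rest` pairs to restrict
#'   the output.
#' @return data frame with one row per combination per dimension: `s_n`,
#'   `s_rest`, `dim`, and `K + 1` region probability columns
#'   `region_1`..`region_K+1` summing to 1 (NaN for impossible
#'   combinations).
#' @export
classify_regions <- function(ct, cuts, method = c("quadrature", "normal"),
                             combos = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(cuts), length(names(cuts)) == length(cuts))
  for (cu in cuts) {
    if (any(diff(cu) <= 0)) stop("cut scores must be strictly increasing", call. = FALSE)
  }
  keep <- seq_len(nrow(ct$combos))
  if (!is.null(combos)) {
    keep <- match(paste(combos$s_n, combos$s_rest),
                  paste(ct$combos$s_n, ct$combos$s_rest))
    if (anyNA(keep)) stop("requested combination out of range", call. = FALSE)
  }
  out <- list()
  for (dim in names(cuts)) {
    cu <- cuts[[dim]]
    K <- length(cu)
    if (method == "quadrature") {
      mg <- combo_marginals(ct, dim)
      if (min(cu) < min(mg$pts) || max(cu) > max(mg$pts)) {
        warning("cut score outside the quadrature range for '", dim, "'")
      }
      reg <- findInterval(mg$pts, cu) + 1L
      probs <- t(rowsum(mg$w[, keep, drop = FALSE], reg))
      full <- matrix(0, length(keep), K + 1L)
      full[, sort(unique(reg))] <- probs
    } else {
      nm <- combo_moment_names(ct$M)
      row <- ct$combos[keep, , drop = FALSE]
      if (dim == "xi") {
        mu <- row$mu_n; sd <- sqrt(row$s_nn)
      } else {
        d <- if (dim == "eta") 1L else as.integer(sub("^eta_", "", dim))
        mu <- row[[if (ct$M == 1L) "mu0" else paste0("mu0_", d)]]
        sd <- sqrt(row[[if (ct$M == 1L) "s00" else paste0("s00_", d, d)]])
      }
      bounds <- c(-Inf, cu, Inf)
      full <- matrix(0, length(keep), K + 1L)
      for (r in seq_len(K + 1L)) {
        full[, r] <- stats::pnorm(bounds[r + 1L], mu, sd) -
          stats::pnorm(bounds[r], mu, sd)
      }
    }
    df <- data.frame(s_n = ct$combos$s_n[keep], s_rest = ct$combos$s_rest[keep],
                     dim = dim)
    colnames(full) <- paste0("region_", seq_len(K + 1L))
    out[[dim]] <- cbind(df, as.data.frame(full))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# coerce a combo table / matrix / data frame to a probability data frame
combo_prob_df <- function(x) {
  if (inherits(x, "combo_table")) return(x$combos[c("s_n", "s_rest", "prob")])
  if (is.matrix(x)) {
    return(data.frame(s_n = rep(seq_len(nrow(x)) - 1L, ncol(x)),
                      s_rest = rep(seq_len(ncol(x)) - 1L, each = nrow(x)),
                      prob = as.vector(x)))
  }
  if (is.data.frame(x) && all(c("s_n", "s_rest", "prob") %in% names(x))) {
    return(x[c("s_n", "s_rest", "prob")])
  }
  stop("cannot interpret 'x' as a score-combination probability table", call. = FALSE)
}

# probability matrix, rows = focal scores, cols = rest scores
combo_prob_matrix <- function(x) {
  if (inherits(x, "combo_table")) return(x$p)
  if (is.matrix(x)) return(x)
  df <- combo_prob_df(x)
  m <- matrix(0, max(df$s_n) + 1L, max(df$s_rest) + 1L)
  m[cbind(df$s_n + 1L, df$s_rest + 1L)] <- df$prob
  m
}

#' Conditional percentile of one score given the other
#'
#' Among examinees with a given focal score, the percentile standing of a
#' score on the rest of the test, computed from the score-combination
#' probabilities normalized by the focal marginal.  The default is the
#' conventional percentile rank — the percentage scoring strictly below
#' `at`, \eqn{100 \times P(s_{rest} < at \mid s_n = given)}.  This is an
#' observed-score analogue of a student growth percentile.
#'
#' @param x a [combo_posteriors()] table, a probability matrix (rows =
#'   focal scores starting at 0), or a data frame with `s_n`, `s_rest`,
#'   `prob`.
#' @param given focal score conditioned on (must have positive marginal
#'   probability).
#' @param at rest score whose percentile is sought.
#' @param rule `"lt"` (default): `P(< at)`; `"le"`: cumulative
#'   `P(<= at)`; `"midpoint"`: `P(< at) + P(= at)/2`.
#' @return percentile in `[0, 100]`.
#' @export
conditional_percentile <- function(x, given, at, rule = c("lt", "le", "midpoint")) {
  rule <- match.arg(rule)
  p <- combo_prob_matrix(x)
  if (given < 0L || given + 1L > nrow(p)) stop("'given' out of range", call. = FALSE)
  row <- p[given + 1L, ]
  tot <- sum(row)
  if (tot <= 0) stop("zero marginal probability for the conditioning score", call. = FALSE)
  scores <- seq_along(row) - 1L
  cum <- switch(rule,
                le = sum(row[scores <= at]),
                lt = sum(row[scores < at]),
                midpoint = sum(row[scores < at]) + sum(row[scores == at]) / 2)
  100 * cum / tot
}

#' Marginal probability of one side's summed score
#'
#' Sums the score-combination probabilities over the other side, e.g. the
#' model-implied fraction of the population obtaining a given focal score.
#'
#' @inheritParams conditional_percentile
#' @param side `"focal"` or `"rest"`.
#' @param score the summed score.
#' @return probability.
#' @export
marginal_score_prob <- function(x, side = c("focal", "rest"), score) {
  side <- match.arg(side)
  p <- combo_prob_matrix(x)
  if (side == "focal") sum(p[score + 1L, ]) else sum(p[, score + 1L])
}

#' Screen a subscore for reporting value
#'
#' A cluster-specific (subscore) estimate is worth reporting when it cannot
#' be predicted well from the overall score.  Following that logic, the
#' specific-dimension EAP \eqn{\mu_n} of each score combination is
#' regressed on the primary EAP \eqn{\mu_0}, weighted by the combination's
#' marginal probability, and a prediction band at `level` is drawn around
#' the fit.  For each combination, the proportion of its (bivariate normal
#' approximated) posterior volume falling inside the band is computed —
#' akin to a p-value: the smaller the proportion, the stronger the case for
#' reporting the subscore for that combination.
#'
#' The band is the normal-quantile prediction interval
#' \eqn{\hat\mu(x) \pm z_{(1+level)/2}\, s\sqrt{1 + h(x)}} from the
#' weighted least squares fit, with the probability weights normalized to
#' sum 1 and scaled by the number of combinations so that equal weights
#' reduce to the ordinary unweighted interval.
#'
#' @param x a [combo_posteriors()] table from a model with `M = 1`, or a
#'   data frame with columns `prob`, `mu0`, `mu_n`, `s00`, `s0n`, `s_nn`.
#' @param level band coverage level in (0, 1).
#' @param n,span resolution and extent of the band-volume integration (see
#'   [band_volume()]).
#' @return object of class `subscore_screen`: list with `fit` (intercept,
#'   slope, residual variance, weight-normalized design inverse, `z`,
#'   `level`) and `combos` (the input combinations plus a `volume`
#'   column).
#' @export
subscore_screen <- function(x, level = 0.95, n = 201L, span = 6) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  df <- if (inherits(x, "combo_table")) {
    if (x$M != 1L) stop("subscore screening requires M = 1", call. = FALSE)
    x$combos
  } else {
    as.data.frame(x)
  }
  need <- c("prob", "mu0", "mu_n", "s00", "s0n", "s_nn")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  use <- which(df$prob > 0 & is.finite(df$mu0) & is.finite(df$mu_n))
  if (length(use) < 3L) stop("need >= 3 combinations with positive probability",
                             call. = FALSE)
  K <- length(use)
  w <- df$prob[use] / sum(df$prob[use])
  xv <- df$mu0[use]; yv <- df$mu_n[use]
  if (max(xv) - min(xv) < 1e-12) stop("degenerate regression: all mu0 equal",
                                      call. = FALSE)
  X <- cbind(1, xv)
  Wk <- w * K
  XtWX <- crossprod(X, X * Wk)
  beta <- solve(XtWX, crossprod(X, yv * Wk))
  res <- yv - drop(X %*% beta)
  s2 <- sum(Wk * res^2) / (K - 2L)
  xtwx_inv <- solve(XtWX)
  z <- stats::qnorm((1 + level) / 2)
  fit <- list(intercept = beta[1L], slope = beta[2L], sigma2 = s2,
              xtwx_inv = xtwx_inv, z = z, level = level, K = K)

  half_width <- function(x0) {
    X0 <- cbind(1, x0)
    z * sqrt(s2 * (1 + rowSums((X0 %*% xtwx_inv) * X0)))
  }
  pred <- function(x0) fit$intercept + fit$slope * x0

  volume <- rep(NA_real_, nrow(df))
  for (k in use) {
    sig <- matrix(c(df$s00[k], df$s0n[k], df$s0n[k], df$s_nn[k]), 2L)
    obj <- tryCatch(normal_approx(c(df$mu0[k], df$mu_n[k]), sig),
                    error = function(e) NULL)
    if (is.null(obj)) next
    volume[k] <- band_volume(obj,
                             lower_fn = function(x) pred(x) - half_width(x),
                             upper_fn = function(x) pred(x) + half_width(x),
                             n = n, span = span)
  }
  df$volume <- volume
  structure(list(fit = fit, combos = df, predict = pred,
                 half_width = half_width),
            class = "subscore_screen")
}

#' @export
print.subscore_screen <- function(x, digits = 3, ...) {
  cat("Subscore screening (", round(100 * x$fit$level), "% prediction band)\n",
      "  mu_n = ", round(x$fit$intercept, digits), " + ",
      round(x$fit$slope, digits), " * mu0,  residual SD ",
      round(sqrt(x$fit$sigma2), digits), "\n", sep = "")
  cols <- intersect(c("s_n", "s_rest", "prob", "volume"), names(x$combos))
  print(round(x$combos[cols], digits))
  invisible(x)
}

#' Discrete high-density region of score combinations
#'
#' Stacks the score-combination probabilities into a single column, sorts
#' them from largest to smallest, and accumulates until the cumulative
#' probability reaches `alpha`; the combinations contributing to that first
#' `100 * alpha`% form the HDR.  Combinations outside the region are rare
#' score patterns that may indicate aberrant responding.  Sorting ties are
#' broken by `(s_n, s_rest)` lexicographic order, so the region is
#' deterministic and minimal: dropping its last member pushes coverage
#' below `alpha`.
#'
#' @inheritParams conditional_percentile
#' @param alpha coverage level in (0, 1).
#' @return data frame (class `hdr_result`) sorted by decreasing
#'   probability with columns `s_n`, `s_rest`, `prob`, `rank`, `cum`,
#'   `included`; attributes `alpha` and `coverage`.
#' @export
hdr <- function(x, alpha = 0.95) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  df <- combo_prob_df(x)
  ord <- order(-df$prob, df$s_n, df$s_rest)
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  df$cum <- cumsum(df$prob)
  total <- df$cum[nrow(df)]
  k <- which(df$cum >= alpha * total - 1e-12)[1L]
  if (is.na(k)) k <- nrow(df)
  df$included <- df$rank <= k
  rownames(df) <- NULL
  structure(df, alpha = alpha, coverage = sum(df$prob[df$included]) / total,
            class = c("hdr_result", "data.frame"))
}

#' @export
print.hdr_result <- function(x, ...) {
  cat("High-density region at alpha =", attr(x, "alpha"),
      "| included:", sum(x$included), "of", nrow(x),
      "combinations, coverage", format(attr(x, "coverage"), digits = 4), "\n")
  NextMethod()
}

#' Tiered HDR membership
#'
#' Labels every score combination by the tightest HDR containing it, e.g.
#' `in95` / `in99` / `out` for the default levels — the three shading tiers
#' of an aberrance map.
#'
#' @inheritParams hdr
#' @param alphas increasing coverage levels.
#' @return data frame with `s_n`, `s_rest`, `prob`, `tier`.
#' @export
hdr_tiers <- function(x, alphas = c(0.95, 0.99)) {
  alphas <- sort(alphas)
  df <- combo_prob_df(x)
  tier <- rep("out", nrow(df))
  for (a in rev(alphas)) {
    h <- hdr(df, a)
    key <- paste(h$s_n[h$included], h$s_rest[h$included])
    tier[paste(df$s_n, df$s_rest) %in% key] <- paste0("in", round(100 * a))
  }
  df$tier <- tier
  df
}
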