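#' Construct a two-tier item factor model
#'
#' A two-tier model has \eqn{M} primary latent dimensions \eqn{\eta} shared by
#' all items and \eqn{N} specific latent dimensions \eqn{\xi_n}, each measured
#' by one non-overlapping item cluster.  Every item loads on the primary
#' dimension(s) and on at most one specific dimension; items with
#' `cluster = 0` load on no specific dimension.  The bifactor model is the
#' special case \eqn{M = 1}; a correlated-traits MIRT model is a two-tier
#' model whose specific dimensions are empty (all specific slopes zero).
#'
#' The item response function for a dichotomous item \eqn{i} in cluster
#' \eqn{n} is the multidimensional logistic
#' \deqn{T_i(1 \mid \eta, \xi_n) =
#'   \mathrm{logit}^{-1}(c_i + a_i^{0\prime} \eta + a_i^{n} \xi_n),}
#' with intercept \eqn{c_i}, primary slopes \eqn{a_i^0} (length \eqn{M}) and
#' specific slope \eqn{a_i^n}.  Item parameters are assumed known and fixed
#' (e.g., from a prior calibration); this package performs no estimation.
#'
#' @param items data frame with one row per item and columns `cluster`
#'   (integer, 0..N), `c` (intercept), primary slopes `a0_1`..`a0_M` (or a
#'   single column `a0` when `M = 1`), and optionally `a_spec` (specific
#'   slope, ignored for `cluster = 0` items and defaulting to 0) and
#'   `item_id`.
#' @param M number of primary dimensions; inferred from the `a0_*` columns
#'   when `NULL`.
#' @param N number of specific dimensions; defaults to the largest cluster
#'   index present.  Clusters with no items are allowed.
#' @param prior_mean,prior_cov mean vector (length `M`) and covariance
#'   matrix (`M` x `M`, symmetric positive definite) of the primary prior
#'   \eqn{h(\eta)}.  Default standard multivariate normal.
#' @param xi_mean,xi_var per-cluster normal prior mean and variance of each
#'   \eqn{g(\xi_n)} (length `N`).  Default standard normal, matching the
#'   usual assumption of mutually independent standard-normal specific
#'   dimensions.
#'
#' @return An object of class `two_tier_model`.
#' @examples
#' items <- data.frame(cluster = c(1, 1, 2, 2),
#'                     a0 = c(1.2, 1.2, 1.0, 1.0),
#'                     a_spec = c(1, 1, .8, .8),
#'                     c = c(-1, -.6, -.2, .2))
#' m <- two_tier_model(items)
#' m
#' @export
two_tier_model <- function(items, M = NULL, N = NULL,
                           prior_mean = NULL, prior_cov = NULL,
                           xi_mean = NULL, xi_var = NULL) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  if (nrow(items) == 0L) stop("no items", call. = FALSE)

  if ("a0" %in% names(items) && !("a0_1" %in% names(items))) {
    names(items)[names(items) == "a0"] <- "a0_1"
  }
  a0_cols <- grep("^a0_[0-9]+$", names(items), value = TRUE)
  a0_cols <- paste0("a0_", sort(as.integer(sub("^a0_", "", a0_cols))))
  if (is.null(M)) M <- length(a0_cols)
  if (M < 1L) stop("M must be >= 1 (no primary slope columns found)", call. = FALSE)
  if (length(a0_cols) != M || !all(a0_cols == paste0("a0_", seq_len(M)))) {
    stop("primary slope columns must be a0_1..a0_", M, call. = FALSE)
  }
  for (col in c("cluster", "c")) {
    if (is.null(items[[col]])) stop("missing required column '", col, "'", call. = FALSE)
  }
  if (is.null(items$a_spec)) items$a_spec <- 0
  if (is.null(items$item_id)) items$item_id <- paste0("item", seq_len(nrow(items)))

  num_cols <- c("cluster", "c", a0_cols, "a_spec")
  for (col in num_cols) {
    v <- items[[col]]
    if (!is.numeric(v)) stop("column '", col, "' must be numeric", call. = FALSE)
    if (any(!is.finite(v))) {
      stop("non-finite value in column '", col, "' (row ",
           which(!is.finite(v))[1L], ")", call. = FALSE)
    }
  }
  cl <- items$cluster
  if (any(cl != round(cl)) || any(cl < 0)) {
    stop("cluster indices must be non-negative integers", call. = FALSE)
  }
  items$cluster <- as.integer(cl)
  items$a_spec[items$cluster == 0L] <- 0

  if (is.null(N)) N <- max(items$cluster, 0L)
  N <- as.integer(N)
  if (max(items$cluster) > N) {
    stop("cluster index ", max(items$cluster), " exceeds N = ", N, call. = FALSE)
  }

  if (is.null(prior_mean)) prior_mean <- rep(0, M)
  if (is.null(prior_cov)) prior_cov <- diag(M)
  prior_cov <- as.matrix(prior_cov)
  if (length(prior_mean) != M || !all(dim(prior_cov) == M)) {
    stop("prior mean/covariance dimensions must match M = ", M, call. = FALSE)
  }
  if (!isSymmetric(prior_cov, tol = 1e-10)) {
    stop("prior covariance must be symmetric", call. = FALSE)
  }
  tryCatch(chol(prior_cov),
           error = function(e) stop("prior covariance must be positive definite",
                                    call. = FALSE))

  if (is.null(xi_mean)) xi_mean <- rep(0, N)
  if (is.null(xi_var)) xi_var <- rep(1, N)
  if (N > 0L && (length(xi_mean) != N || length(xi_var) != N || any(xi_var <= 0))) {
    stop("xi prior must supply a mean and positive variance per cluster", call. = FALSE)
  }

  items <- items[c("item_id", "cluster", "c", a0_cols, "a_spec")]
  structure(list(items = items, M = M, N = N,
                 prior_mean = as.numeric(prior_mean), prior_cov = prior_cov,
                 xi_mean = as.numeric(xi_mean), xi_var = as.numeric(xi_var)),
            class = "two_tier_model")
}

#' @export
print.two_tier_model <- function(x, ...) {
  sizes <- tabulate(x$items$cluster, nbins = max(x$N, 1L))
  cat("Two-tier item factor model\n")
  cat("  items:", nrow(x$items), " primary dims (M):", x$M,
      " specific dims (N):", x$N, "\n")
  cat("  cluster sizes:", paste(sizes, collapse = ", "))
  if (any(x$items$cluster == 0L)) {
    cat("  (+", sum(x$items$cluster == 0L), "items on no specific dimension)")
  }
  cat("\n")
  invisible(x)
}

# primary slope matrix, items x M
a0_matrix <- function(model) {
  as.matrix(model$items[paste0("a0_", seq_len(model$M))])
}

#' Extract one item's parameters
#'
#' @param model a [two_tier_model()].
#' @param i item row index.
#' @return list with `item_id`, `cluster`, `c`, `a0` (length-M vector),
#'   `a_spec`.
#' @export
model_item <- function(model, i) {
  row <- model$items[i, ]
  list(item_id = row$item_id, cluster = row$cluster, c = row$c,
       a0 = as.numeric(row[paste0("a0_", seq_len(model$M))]),
       a_spec = row$a_spec)
}

#' Item response function
#'
#' Evaluates the two-tier logistic item response function at one or more
#' latent-variable points, returning the probabilities of both response
#' categories.
#'
#' @param item item parameters: a list with elements `c`, `a0` (numeric,
#'   length `M`) and `a_spec`, e.g. from [model_item()].
#' @param eta primary latent dimension value(s): a numeric vector of length
#'   `M` (one point), or a matrix with `M` columns (one row per point).
#' @param xi specific latent dimension value(s); recycled against the rows
#'   of `eta`.
#' @return list with numeric vectors `T0` and `T1`; `T0 + T1 = 1`.
#' @examples
#' it <- list(c = -1, a0 = 1.2, a_spec = 1)
#' item_response(it, eta = -2, xi = -2)$T0  # 0.996
#' @export
item_response <- function(item, eta, xi = 0) {
  a0 <- item$a0
  if (is.null(a0)) a0 <- unlist(item[grep("^a0_[0-9]+$", names(item))], use.names = FALSE)
  a0 <- as.numeric(a0)
  eta <- if (is.matrix(eta)) eta else matrix(eta, ncol = length(a0))
  if (ncol(eta) != length(a0)) {
    stop("eta has ", ncol(eta), " columns but the item has ", length(a0),
         " primary slopes", call. = FALSE)
  }
  a_spec <- if (is.null(item$a_spec)) 0 else item$a_spec
  lin <- item$c + drop(eta %*% a0) + a_spec * xi
  t1 <- stats::plogis(lin)
  list(T0 = 1 - t1, T1 = t1)
}
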