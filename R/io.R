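# CSV/JSON interchange for models and result tables, plus the response
# pattern enumeration oracle.  All tabular output is comma-separated,
# '.'-decimal, UTF-8 with LF line endings, so files are bit-reproducible
# across platforms.

#' Read an item parameter table
#'
#' Expects a CSV with header `item_id, cluster, c, a0_1..a0_M, a_spec`
#' (`a0` accepted for `M = 1`); `M` is inferred from the header.  Malformed
#' rows are reported with their line number.
#'
#' @param path CSV file.
#' @return data frame of validated item parameters (not yet a model; see
#'   [read_model()]).
#' @export
read_params <- function(path) {
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(items) == 0L) stop("no items in '", path, "'", call. = FALSE)
  known <- c("item_id", "cluster", "c", "a_spec", "a0",
             grep("^a0_[0-9]+$", names(items), value = TRUE))
  extra <- setdiff(names(items), known)
  if (length(extra) > 0L) {
    stop("unknown column(s) in '", path, "': ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(names(items), "item_id")) {
    v <- items[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric value in column '", col, "' at line ", bad + 1L,
           " of '", path, "'", call. = FALSE)
    }
  }
  items
}

#' Write a model's item parameters to CSV
#' @param model a [two_tier_model()].
#' @param path output file.
#' @export
write_params <- function(model, path) {
  utils::write.csv(model$items, path, row.names = FALSE, quote = FALSE,
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a model configuration
#'
#' The configuration JSON carries what the parameter CSV cannot: dimension
#' counts, the primary prior (mean vector and covariance matrix), optional
#' per-cluster specific priors, and the quadrature spec, e.g.
#' `{"M": 1, "N": 3, "prior_eta": {"mean": [0], "cov": [[1]]},
#'   "quadrature": {"Q": 49, "range": [-6, 6]}}`.
#'
#' @param path JSON file.
#' @return named list.
#' @export
read_model_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname read_model_config
#' @param model a [two_tier_model()].
#' @param Q,range quadrature spec to record.
#' @export
write_model_config <- function(model, path, Q = 49, range = c(-6, 6)) {
  cfg <- list(M = model$M, N = model$N,
              prior_eta = list(mean = model$prior_mean, cov = model$prior_cov),
              prior_xi = list(mean = model$xi_mean, var = model$xi_var),
              quadrature = list(Q = Q, range = range))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Assemble a model from a parameter CSV and optional config JSON
#'
#' @param params_path item parameter CSV (see [read_params()]).
#' @param config_path optional JSON (see [read_model_config()]); when
#'   absent, standard-normal independent priors are used.
#' @return a [two_tier_model()]; the attribute `"quadrature"` carries the
#'   config's grid spec when present.
#' @export
read_model <- function(params_path, config_path = NULL) {
  items <- read_params(params_path)
  if (is.null(config_path)) return(two_tier_model(items))
  cfg <- read_model_config(config_path)
  model <- two_tier_model(items,
                          M = cfg$M, N = cfg$N,
                          prior_mean = cfg$prior_eta$mean,
                          prior_cov = cfg$prior_eta$cov,
                          xi_mean = cfg$prior_xi$mean,
                          xi_var = cfg$prior_xi$var)
  if (!is.null(cfg$quadrature)) attr(model, "quadrature") <- cfg$quadrature
  model
}

#' Write a result table to CSV
#'
#' Accepts a [score_table] (rows = scores, columns = grid nodes), a
#' [combo_posteriors()] table, an [lw20_posteriors()] object, or any data
#' frame.  Report values are rounded half-even to `digits` decimals unless
#' `full_precision`.
#'
#' @param x the object.
#' @param path output CSV.
#' @param digits decimals for report rounding.
#' @param full_precision write at full precision.
#' @export
write_table <- function(x, path, digits = 3, full_precision = FALSE) {
  df <- if (inherits(x, "score_table")) {
    out <- as.data.frame(x$values)
    names(out) <- paste0("node_", seq_len(ncol(out)))
    cbind(score = x$scores, out)
  } else if (inherits(x, "combo_table")) {
    x$combos
  } else if (inherits(x, "score_posteriors")) {
    x$table
  } else {
    as.data.frame(x)
  }
  if (!full_precision) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Brute-force score-combination table by pattern enumeration
#'
#' The validation oracle: enumerates all `2^I` response patterns, computes
#' each pattern's likelihood as the product of item response probabilities
#' on the full `(eta, xi_1..xi_N)` product grid, integrates against the
#' prior weights, and aggregates by `(s_n, s_rest)`.  Moments of
#' `(eta, xi_n)` come from the same grid sums.  Exponential in the item
#' count, hence refused beyond `max_items`.
#'
#' @inheritParams combo_posteriors
#' @param max_items enumeration guard (default 14).
#' @return list shaped like a [combo_posteriors()] result (`combos`, `p`),
#'   class `combo_table_enum`.
#' @export
brute_force_combo_probs <- function(model, focal, grid, max_items = 14L) {
  I <- nrow(model$items)
  if (I > max_items) {
    stop("refusing to enumerate 2^", I, " patterns (limit ", max_items,
         " items)", call. = FALSE)
  }
  M <- model$M; N <- model$N
  n_eta <- nrow(grid$eta_pts)

  # full product grid: eta nodes x xi_1 x ... x xi_N
  xi_lens <- vapply(grid$xi, function(g) length(g$pts), integer(1))
  idx <- as.matrix(expand.grid(c(list(seq_len(n_eta)),
                                 lapply(xi_lens, seq_len))))
  W <- grid$eta_w[idx[, 1L]]
  for (n in seq_len(N)) W <- W * grid$xi[[n]]$w[idx[, n + 1L]]

  # item response probabilities at every full-grid node
  A0 <- a0_matrix(model)
  lin <- A0 %*% t(grid$eta_pts[idx[, 1L], , drop = FALSE]) + model$items$c
  for (n in seq_len(N)) {
    in_cl <- model$items$cluster == n
    if (any(in_cl)) {
      xi_vals <- grid$xi[[n]]$pts[idx[, n + 1L]]
      lin[in_cl, ] <- lin[in_cl, , drop = FALSE] +
        outer(model$items$a_spec[in_cl], xi_vals)
    }
  }
  T1 <- stats::plogis(lin)                                 # items x nodes

  patterns <- as.matrix(expand.grid(rep(list(0:1), I)))    # 2^I x items
  # log-likelihood of each pattern at each node
  eps <- 1e-300
  logL <- patterns %*% log(pmax(T1, eps)) +
    (1 - patterns) %*% log(pmax(1 - T1, eps))
  Lmat <- exp(logL)                                        # patterns x nodes

  in_focal <- model$items$cluster == focal
  s_n <- as.vector(patterns[, in_focal, drop = FALSE] %*% rep(1, sum(in_focal)))
  s_rest <- rowSums(patterns) - s_n
  n1 <- sum(in_focal) + 1L
  nr <- I - sum(in_focal) + 1L
  key <- s_n + n1 * s_rest                                 # 0-based combo id

  G <- rowsum(Lmat, key, reorder = TRUE)                   # combos x nodes
  stopifnot(nrow(G) == n1 * nr)

  coords <- cbind(grid$eta_pts[idx[, 1L], , drop = FALSE],
                  xi = grid$xi[[focal]]$pts[idx[, focal + 1L]])
  p <- as.vector(G %*% W)
  mom <- function(f) as.vector(G %*% (W * f)) / p
  combos <- data.frame(s_n = rep(seq_len(n1) - 1L, nr),
                       s_rest = rep(seq_len(nr) - 1L, each = n1),
                       prob = p)
  mu0 <- matrix(0, n1 * nr, M)
  for (d in seq_len(M)) mu0[, d] <- mom(coords[, d])
  mu_n <- mom(coords[, M + 1L])
  cols <- list()
  for (d in seq_len(M)) cols[[if (M == 1L) "mu0" else paste0("mu0_", d)]] <- mu0[, d]
  for (d in seq_len(M)) for (e in d:M) {
    cols[[if (M == 1L) "s00" else paste0("s00_", d, e)]] <-
      mom(coords[, d] * coords[, e]) - mu0[, d] * mu0[, e]
  }
  cols$mu_n <- mu_n
  cols$s_nn <- mom(coords[, M + 1L]^2) - mu_n^2
  for (d in seq_len(M)) {
    cols[[if (M == 1L) "s0n" else paste0("s0n_", d)]] <-
      mom(coords[, d] * coords[, M + 1L]) - mu0[, d] * mu_n
  }
  for (nm in combo_moment_names(M)) combos[[nm]] <- cols[[nm]]

  structure(list(combos = combos, p = matrix(p, n1, nr), focal = focal, M = M),
            class = "combo_table_enum")
}
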