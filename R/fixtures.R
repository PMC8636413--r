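# Built-in parameter fixtures and a synthetic model generator.  The two
# named fixtures carry published calibrated parameters so every operation
# can be exercised and checked without external data.

new_fixture <- function(name, model, Q, range, cuts = NULL, note = "") {
  structure(list(name = name, model = model, Q = Q, range = range,
                 cuts = cuts, note = note),
            class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("Fixture '", x$name, "': ", x$note, "\n", sep = "")
  print(x$model)
  cat("  recommended grid: Q =", x$Q, "on [", x$range[1], ",", x$range[2], "]\n")
  invisible(x)
}

#' Build the recommended quadrature grid of a fixture
#' @param fx a fixture from [sixitem_fixture()] or [elpa21_fixture()].
#' @param Q,range overrides for the fixture's recommended grid.
#' @return an [make_grid()] grid.
#' @export
fixture_grid <- function(fx, Q = fx$Q, range = fx$range) {
  make_grid(fx$model, Q = Q, range = range)
}

#' Six-item bifactor demonstration scale
#'
#' A hypothetical six-item dichotomous scale with bifactor structure: one
#' primary dimension and three specific dimensions, two items per cluster,
#' all priors independent standard normal.  Its recommended grid — five
#' equally spaced points at -2, -1, 0, 1, 2 per dimension — is deliberately
#' coarse so every intermediate quantity of the recursions can be verified
#' by hand; it is not a production resolution.
#'
#' @return a `fixture_spec` with the model and recommended grid spec.
#' @examples
#' fx <- sixitem_fixture()
#' grid <- fixture_grid(fx)
#' combo_posteriors(fx$model, focal = 1, grid)
#' @export
sixitem_fixture <- function() {
  items <- data.frame(
    item_id = paste0("item", 1:6),
    cluster = c(1L, 1L, 2L, 2L, 3L, 3L),
    c       = c(-1.0, -0.6, -0.2, 0.2, 0.6, 1.0),
    a0_1    = c(1.2, 1.2, 1.0, 1.0, 0.8, 0.8),
    a_spec  = c(1.0, 1.0, 0.8, 0.8, 1.2, 1.2)
  )
  model <- two_tier_model(items, M = 1L, N = 3L)
  new_fixture("sixitem", model, Q = 5L, range = c(-2, 2),
              note = "six-item bifactor demonstration scale (3 clusters of 2)")
}

#' ELPA21 adjacent-grade listening fixture
#'
#' Calibrated item parameters of two fixed listening test forms of a
#' multi-state English language proficiency assessment: 24 dichotomous
#' items in the lower grade band (4-5) and 30 in the upper grade band
#' (6-8).  Each form measures its own grade-band proficiency variable, so
#' the model is a correlated-traits MIRT model for longitudinal data,
#' treated as a two-tier model with `M = 2` primary dimensions and empty
#' specific dimensions (all specific slopes zero).  The estimated
#' population distribution has means .09 and -.05, variances 1.25 and .62,
#' and covariance .80 (correlation .91).  Standard-setting cut scores
#' divide each scale into emerging / progressing / proficient.
#'
#' @return a `fixture_spec`; `$cuts` holds the per-dimension cut scores
#'   (`eta_1` = lower band, `eta_2` = upper band).
#' @export
elpa21_fixture <- function() {
  lower_c <- c(3.26, 2.95, 1.10, 2.85, 1.95, 1.59, 2.82, 4.02, 0.18, 2.08,
               2.24, 1.70, 4.34, 2.80, 3.77, 2.96, 3.33, 0.33, -0.95, 2.18,
               1.79, 1.78, 2.49, 1.38)
  lower_a <- c(1.43, 1.53, 0.46, 1.88, 1.51, 1.10, 1.50, 1.64, 0.29, 1.27,
               1.28, 0.95, 1.71, 1.52, 2.10, 1.80, 1.79, 0.76, 0.57, 1.46,
               1.20, 1.57, 1.65, 1.01)
  upper_c <- c(1.60, 0.98, 2.34, 1.65, 2.20, 0.89, 2.94, 2.70, 5.40, 3.51,
               5.40, 4.34, 4.09, 6.03, 5.76, 4.94, 4.71, 7.92, 2.67, 2.45,
               0.66, 2.14, 1.51, 1.93, 2.51, 2.72, 3.85, 0.35, 2.28, 1.39)
  upper_a <- c(1.48, 1.54, 1.73, 1.42, 1.64, 1.10, 2.03, 1.32, 2.64, 2.24,
               2.73, 2.16, 2.14, 2.04, 2.95, 2.10, 2.56, 2.95, 1.66, 1.81,
               1.49, 1.74, 1.81, 1.39, 1.90, 1.86, 2.31, 0.73, 1.65, 1.26)
  items <- data.frame(
    item_id = c(paste0("Lower", seq_along(lower_c)),
                paste0("Upper", seq_along(upper_c))),
    cluster = rep(c(1L, 2L), c(length(lower_c), length(upper_c))),
    c = c(lower_c, upper_c),
    a0_1 = c(lower_a, rep(0, length(upper_c))),
    a0_2 = c(rep(0, length(lower_c)), upper_a),
    a_spec = 0
  )
  model <- two_tier_model(items, M = 2L, N = 2L,
                          prior_mean = c(0.09, -0.05),
                          prior_cov = matrix(c(1.25, 0.80, 0.80, 0.62), 2L))
  new_fixture("elpa21", model, Q = 49L, range = c(-6, 6),
              cuts = list(eta_1 = c(-1.1875, -0.65),
                          eta_2 = c(-1.375, -0.65)),
              note = "adjacent-grade listening forms (24 + 30 items), correlated-traits MIRT")
}

#' Generate a random two-tier model
#'
#' Reproducible synthetic models for property testing and oracle checks.
#' Primary slopes are drawn positive (monotonicity-friendly) from
#' `slope_range`, specific slopes likewise, intercepts uniformly from
#' `intercept_range`.  The default ranges span the magnitudes typical of
#' calibrated educational and patient-reported-outcome item banks.  The
#' global RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param M,N dimension counts.
#' @param items_per_cluster integer vector (recycled to length `N`).
#' @param slope_range,intercept_range length-2 numeric ranges.
#' @return a [two_tier_model()] with standard-normal priors.
#' @export
synth_model <- function(seed, M = 1L, N = 3L, items_per_cluster = 3L,
                        slope_range = c(0.5, 2.5),
                        intercept_range = c(-2, 2)) {
  if (length(slope_range) != 2L || slope_range[1] > slope_range[2] ||
      slope_range[1] < 0) {
    stop("invalid slope_range", call. = FALSE)
  }
  if (length(intercept_range) != 2L || intercept_range[1] > intercept_range[2]) {
    stop("invalid intercept_range", call. = FALSE)
  }
  if (M < 1L || N < 1L || any(items_per_cluster < 1L)) {
    stop("M, N and items_per_cluster must be positive", call. = FALSE)
  }
  items_per_cluster <- rep_len(items_per_cluster, N)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  I <- sum(items_per_cluster)
  items <- data.frame(
    item_id = paste0("synth", seq_len(I)),
    cluster = rep(seq_len(N), items_per_cluster),
    c = stats::runif(I, intercept_range[1], intercept_range[2])
  )
  for (d in seq_len(M)) {
    items[[paste0("a0_", d)]] <- stats::runif(I, slope_range[1], slope_range[2])
  }
  items$a_spec <- stats::runif(I, slope_range[1], slope_range[2])
  two_tier_model(items, M = M, N = N)
}
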