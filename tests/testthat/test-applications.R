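six <- sixitem_fixture()
gsix <- fixture_grid(six)
ct_six <- combo_posteriors(six$model, 1, gsix)

test_that("region probabilities partition the posterior mass", {
  cl <- classify_regions(ct_six, list(eta = c(-1, 0.5)))
  expect_equal(rowSums(cl[, 4:6]), rep(1, 15), tolerance = 1e-10)
  # a cut far below the grid puts all mass in the upper region
  cl2 <- suppressWarnings(classify_regions(ct_six, list(eta = -100)))
  expect_equal(cl2$region_1, rep(0, 15))
  expect_equal(cl2$region_2, rep(1, 15), tolerance = 1e-10)
  expect_warning(classify_regions(ct_six, list(eta = -100)), "outside")
  # the specific dimension can be classified too
  clx <- classify_regions(ct_six, list(xi = 0))
  expect_equal(rowSums(clx[, 4:5]), rep(1, 15), tolerance = 1e-10)
  # normal mode rows also sum to 1 and, on a production-resolution grid,
  # agree with the quadrature marginal to within the approximation error
  cln <- classify_regions(ct_six, list(eta = c(-1, 0.5)), method = "normal")
  expect_equal(rowSums(cln[, 4:6]), rep(1, 15), tolerance = 1e-10)
  ct49 <- combo_posteriors(six$model, 1, make_grid(six$model, 49, c(-6, 6)))
  q49 <- classify_regions(ct49, list(eta = c(-1, 0.5)))
  n49 <- classify_regions(ct49, list(eta = c(-1, 0.5)), method = "normal")
  expect_lt(max(abs(as.matrix(q49[, 4:6]) - as.matrix(n49[, 4:6]))), 0.1)
})

test_that("region classification agrees with Monte Carlo under the normal mode", {
  cp <- combo_posterior(ct_six, 1, 2)
  cln <- classify_regions(ct_six, list(eta = c(-1, 0.5)), method = "normal",
                          combos = data.frame(s_n = 1, s_rest = 2))
  set.seed(11)
  n <- 1e5
  draws <- stats::rnorm(n, cp$mu[1], sqrt(cp$sigma[1, 1]))
  mc <- c(mean(draws < -1), mean(draws >= -1 & draws < 0.5), mean(draws >= 0.5))
  for (r in 1:3) {
    se <- sqrt(mc[r] * (1 - mc[r]) / n)
    expect_lt(abs(cln[[paste0("region_", r)]] - mc[r]), 3 * se + 1e-12)
  }
})

test_that("conditional percentiles follow the cumulative convention", {
  # hand-built 3 x 3 table
  p <- matrix(c(.10, .05, .05,
                .10, .20, .10,
                .05, .15, .20), 3, byrow = TRUE)
  expect_equal(conditional_percentile(p, 1, 1, rule = "le"), 100 * .30 / .40)
  expect_equal(conditional_percentile(p, 1, 1, rule = "lt"), 100 * .10 / .40)
  expect_equal(conditional_percentile(p, 1, 1, rule = "midpoint"), 100 * .20 / .40)
  expect_equal(conditional_percentile(p, 2, 2, rule = "le"), 100)
  expect_error(conditional_percentile(rbind(c(0, 0), c(1, 0)), 0, 1), "zero marginal")
  # nondecreasing in `at`
  pct <- vapply(0:2, function(a) conditional_percentile(p, 0, a), numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("marginal score probabilities agree with single-band recursion", {
  expect_equal(sum(vapply(0:2, function(s) marginal_score_prob(ct_six, "focal", s),
                          numeric(1))), 1, tolerance = 1e-10)
  # independent clusters given eta: the focal marginal equals the
  # focal-cluster-only summed-score probabilities under the shared prior
  m <- synth_model(8, M = 1, N = 2, items_per_cluster = c(2, 3))
  g <- make_grid(m, Q = 31, range = c(-5, 5))
  ct <- combo_posteriors(m, 1, g)
  solo <- two_tier_model(m$items[m$items$cluster == 1, ], M = 1, N = 1)
  lp <- lw20_posteriors(solo, make_grid(solo, Q = 31, range = c(-5, 5)))
  for (s in 0:2) {
    expect_equal(marginal_score_prob(ct, "focal", s), lp$table$prob[s + 1],
                 tolerance = 1e-10)
  }
})

test_that("subscore screening flags discordant score combinations", {
  sc <- subscore_screen(ct_six, level = 0.95)
  expect_true(all(sc$combos$volume >= 0 & sc$combos$volume <= 1))
  # the least-covered combination is an extreme discordant pair, not a
  # concordant one
  worst <- sc$combos[which.min(sc$combos$volume), c("s_n", "s_rest")]
  expect_true(paste(worst$s_n, worst$s_rest) %in% c("2 0", "0 4"))
  # widening the band never shrinks any volume proportion
  sc99 <- subscore_screen(ct_six, level = 0.99)
  expect_true(all(sc99$combos$volume >= sc$combos$volume - 1e-9))
})

test_that("combinations near a line with tiny spread are fully covered", {
  # residual scatter (~.02) far exceeds the posterior spread (sd .01), so
  # the prediction band swallows every posterior
  df <- data.frame(prob = rep(1 / 5, 5), mu0 = seq(-2, 2),
                   mu_n = 0.5 * seq(-2, 2) + 0.1 + c(.02, -.02, .015, -.01, .02),
                   s00 = 1e-4, s0n = 0, s_nn = 1e-4)
  sc <- subscore_screen(df, level = 0.95)
  expect_true(all(sc$combos$volume > 0.95))
  expect_equal(sc$fit$slope, 0.5, tolerance = 0.02)
  # degenerate predictor
  df$mu0 <- 1
  expect_error(subscore_screen(df), "degenerate regression")
})

test_that("subscore volume proportion agrees with Monte Carlo", {
  sc <- subscore_screen(ct_six, level = 0.95)
  k <- which(sc$combos$s_n == 0 & sc$combos$s_rest == 4)
  row <- sc$combos[k, ]
  set.seed(21)
  n <- 1e5
  sig <- matrix(c(row$s00, row$s0n, row$s0n, row$s_nn), 2)
  draws <- sweep(matrix(stats::rnorm(2 * n), n, 2) %*% chol(sig), 2,
                 c(row$mu0, row$mu_n), "+")
  fitted <- sc$predict(draws[, 1])
  hw <- sc$half_width(draws[, 1])
  mc <- mean(draws[, 2] >= fitted - hw & draws[, 2] <= fitted + hw)
  expect_lt(abs(row$volume - mc), 3 * sqrt(mc * (1 - mc) / n))
})

test_that("high-density regions are top-probability sets", {
  h <- hdr(matrix(c(.5, .3, .15, .05), 1), alpha = 0.95)
  expect_equal(h$included, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(h, "coverage"), 0.95)
  # uniform probabilities: ceiling(alpha * K) combos included
  K <- 40
  hu <- hdr(matrix(rep(1 / K, K), 4), alpha = 0.95)
  expect_equal(sum(hu$included), ceiling(0.95 * K))
  # nesting
  for (seed in 1:10) {
    p <- rand_prob_table(seed)
    h95 <- hdr(p, 0.95); h99 <- hdr(p, 0.99)
    in95 <- paste(h95$s_n[h95$included], h95$s_rest[h95$included])
    in99 <- paste(h99$s_n[h99$included], h99$s_rest[h99$included])
    expect_true(all(in95 %in% in99))
    expect_gte(attr(h95, "coverage"), 0.95)
  }
})

test_that("the fixture HDR matches the brute-force minimal covering set", {
  h <- hdr(ct_six, alpha = 0.95)
  probs <- sort(ct_six$combos$prob, decreasing = TRUE)
  k_min <- which(cumsum(probs) >= 0.95 * sum(probs) - 1e-12)[1]
  expect_equal(sum(h$included), k_min)
  # removing the last included combination drops coverage below alpha
  inc <- sort(h$prob[h$included], decreasing = TRUE)
  expect_lt(sum(inc[-length(inc)]), 0.95)
  expect_gte(attr(h, "coverage"), 0.95)
})

test_that("hdr tiers label combinations by the tightest covering region", {
  tiers <- hdr_tiers(ct_six)
  expect_setequal(unique(tiers$tier), c("in95", "in99", "out"))
  h95 <- hdr(ct_six, 0.95)
  expect_equal(sum(tiers$tier == "in95"), sum(h95$included))
})
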