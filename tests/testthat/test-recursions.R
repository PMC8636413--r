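# Worked-example checks use the six-item bifactor fixture on its coarse
# demonstration grid (5 points at -2..2 per dimension), where every
# intermediate quantity is printed to 3 decimals in the source tables.
# Grid node columns are eta-fastest: node (eta_i, xi_j) = i + (j-1)*5.

six <- sixitem_fixture()
gsix <- fixture_grid(six)
# the seven printed nodes: (-2,-2) (-2,-1) (-2,0) (0,0) (2,0) (2,1) (2,2)
printed_cols <- c(1, 6, 11, 13, 15, 20, 25)

test_that("within-cluster recursion reproduces the printed Stage-I tables", {
  t1 <- within_cluster_likelihoods(six$model, 1, gsix)
  expect_equal(round(t1$values[, printed_cols], 3),
               rbind(c(.989, .970, .922, .472, .028, .005, .001),
                     c(.011, .030, .077, .433, .284, .131, .053),
                     c(.000, .000, .002, .095, .688, .864, .947)))
  t2 <- within_cluster_likelihoods(six$model, 2, gsix)
  expect_equal(round(t2$values[, printed_cols], 3),
               rbind(c(.947, .887, .773, .248, .014, .003, .001),
                     c(.053, .110, .213, .505, .213, .110, .053),
                     c(.001, .003, .014, .248, .773, .887, .947)))
  t3 <- within_cluster_likelihoods(six$model, 3, gsix)
  expect_equal(round(t3$values[, printed_cols], 3),
               rbind(c(.922, .773, .472, .095, .007, .001, .000),
                     c(.077, .213, .433, .433, .155, .053, .017),
                     c(.002, .014, .095, .472, .838, .947, .983)))
})

test_that("marginalization over the specific dimension matches the printed tables", {
  m2 <- marginalize_specific(within_cluster_likelihoods(six$model, 2, gsix), gsix)
  expect_equal(round(m2$values, 3),
               rbind(c(.742, .519, .277, .106, .028),
                     c(.230, .375, .446, .375, .230),
                     c(.028, .106, .277, .519, .742)))
  m3 <- marginalize_specific(within_cluster_likelihoods(six$model, 3, gsix), gsix)
  expect_equal(round(m3$values, 3),
               rbind(c(.469, .302, .166, .077, .029),
                     c(.364, .396, .364, .285, .192),
                     c(.166, .302, .469, .638, .779)))
  # a table constant in xi passes through unchanged
  flat <- within_cluster_likelihoods(six$model, 2, gsix)
  flat$values <- flat$values[, rep(1:5, 5)]
  out <- marginalize_specific(flat, gsix)
  expect_equal(out$values, flat$values[, 1:5])
  expect_error(marginalize_specific(m2, gsix), "not conditioned")
})

test_that("rest-score likelihoods reproduce the printed Stage-II table", {
  R1 <- rest_score_likelihoods(six$model, 1, gsix)
  expect_equal(round(R1$values, 3),
               rbind(c(.348, .157, .046, .008, .001),
                     c(.378, .319, .175, .059, .012),
                     c(.220, .337, .339, .214, .088),
                     c(.049, .155, .310, .387, .321),
                     c(.005, .032, .130, .331, .578)))
})

test_that("single items, empty clusters and trivial combinations behave as units", {
  one <- two_tier_model(data.frame(cluster = 1, a0 = 0, a_spec = 0, c = 0.4))
  g <- make_grid(one, Q = 4, range = c(-2, 2))
  tb <- within_cluster_likelihoods(one, 1, g)
  p <- stats::plogis(0.4)
  expect_equal(tb$values, rbind(rep(1 - p, 4), rep(p, 4)))
  # empty cluster: trivial single-score table
  empty <- within_cluster_likelihoods(six$model, 0, gsix)
  expect_equal(empty$values, matrix(1, 1, 5))
  # combining with the trivial table is the identity
  m2 <- marginalize_specific(within_cluster_likelihoods(six$model, 2, gsix), gsix)
  expect_equal(combine_clusters(list(m2, empty))$values, m2$values)
  expect_equal(combine_clusters(list(), n_nodes = 5)$values, matrix(1, 1, 5))
})

test_that("cluster combination equals brute-force score-triple enumeration", {
  set.seed(42)
  mk <- function(nscore) {
    v <- matrix(rexp(nscore * 4), nscore, 4)
    v <- sweep(v, 2, colSums(v), "/")
    lw25:::new_score_table(v, "eta", NA_integer_, 4L)
  }
  tabs <- list(mk(3), mk(3), mk(3))
  got <- combine_clusters(tabs)$values
  want <- matrix(0, 7, 4)
  for (i in 0:2) for (j in 0:2) for (k in 0:2) {
    want[i + j + k + 1, ] <- want[i + j + k + 1, ] +
      tabs[[1]]$values[i + 1, ] * tabs[[2]]$values[j + 1, ] * tabs[[3]]$values[k + 1, ]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("recursion equals response-pattern enumeration", {
  # the worked example's cluster 3, against direct pattern enumeration
  enum3 <- enum_cluster_table(six$model, 3, gsix)
  rec3 <- within_cluster_likelihoods(six$model, 3, gsix)
  expect_equal(rec3$values, enum3, tolerance = 1e-12)
  # random small models
  for (seed in 1:5) {
    m <- rand_model(seed, max_items = 8L)
    g <- make_grid(m, Q = 5, range = c(-3, 3))
    for (n in seq_len(m$N)) {
      expect_equal(within_cluster_likelihoods(m, n, g)$values,
                   enum_cluster_table(m, n, g), tolerance = 1e-10)
    }
  }
})

test_that("item and cluster order do not change any table", {
  m <- rand_model(11, max_items = 9L)
  g <- make_grid(m, Q = 5, range = c(-3, 3))
  set.seed(99)
  perm <- sample(nrow(m$items))
  m2 <- two_tier_model(m$items[perm, ], M = m$M, N = m$N)
  for (n in seq_len(m$N)) {
    expect_equal(within_cluster_likelihoods(m, n, g)$values,
                 within_cluster_likelihoods(m2, n, g)$values, tolerance = 1e-12)
  }
  tabs <- lapply(seq_len(m$N), function(n) lw25:::cluster_likelihoods_eta(m, n, g))
  expect_equal(combine_clusters(tabs)$values,
               combine_clusters(rev(tabs))$values, tolerance = 1e-12)
})

test_that("likelihood tables conserve probability at every node", {
  for (seed in 1:6) {
    m <- rand_model(seed + 20, max_items = 10L)
    g <- make_grid(m, Q = 5, range = c(-3, 3))
    for (n in seq_len(m$N)) {
      tb <- within_cluster_likelihoods(m, n, g)
      expect_lt(max(abs(colSums(tb$values) - 1)), 1e-10)
      mg <- marginalize_specific(tb, g)
      expect_lt(max(abs(colSums(mg$values) - 1)), 1e-10)
    }
    expect_lt(max(abs(colSums(total_score_likelihoods(m, g)$values) - 1)), 1e-10)
  }
})

test_that("focal-by-rest convolution recovers the total-score likelihoods", {
  m <- rand_model(31, max_items = 10L)
  g <- make_grid(m, Q = 5, range = c(-3, 3))
  L <- total_score_likelihoods(m, g)$values
  for (focal in seq_len(m$N)) {
    P <- lw25:::cluster_likelihoods_eta(m, focal, g)$values
    R <- rest_score_likelihoods(m, focal, g)$values
    conv <- matrix(0, nrow(P) + nrow(R) - 1, ncol(P))
    for (i in seq_len(nrow(P))) for (j in seq_len(nrow(R))) {
      conv[i + j - 1, ] <- conv[i + j - 1, ] + P[i, ] * R[j, ]
    }
    expect_equal(conv, L, tolerance = 1e-12)
  }
})

test_that("rest scores for a two-cluster model are the other cluster's table", {
  m <- synth_model(5, M = 1, N = 2, items_per_cluster = c(3, 2))
  g <- make_grid(m, Q = 7, range = c(-4, 4))
  expect_equal(rest_score_likelihoods(m, 1, g)$values,
               lw25:::cluster_likelihoods_eta(m, 2, g)$values)
  m1 <- synth_model(6, M = 1, N = 1, items_per_cluster = 3)
  g1 <- make_grid(m1, Q = 5, range = c(-3, 3))
  expect_error(rest_score_likelihoods(m1, 1, g1), "no rest items")
})

test_that("zero specific loadings collapse Stage I to the primary grid", {
  it <- data.frame(cluster = c(1, 1, 2), a0 = c(1.1, .8, 1.3),
                   a_spec = c(0, 0, 1.2), c = c(-.5, .2, .1))
  m <- two_tier_model(it)
  g <- make_grid(m, Q = 7, range = c(-4, 4))
  tb <- within_cluster_likelihoods(m, 1, g)
  expect_identical(tb$conditioning, "eta")
  # identical likelihoods to forcing the item through the (eta, xi) plane
  it2 <- it; it2$a_spec[1:2] <- 1e-12
  tb2 <- marginalize_specific(
    within_cluster_likelihoods(two_tier_model(it2), 1, g), g)
  expect_equal(tb$values, tb2$values, tolerance = 1e-9)
})
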