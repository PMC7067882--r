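test_that("skew-normal fit: symmetry gives zero shape, asymmetry skews", {
  sym <- fit_skew_normal(4.0, 2.04, 5.96)
  expect_lt(abs(sym$a), 0.05)
  expect_equal(sym$fitted_quantiles, c(2.04, 4.0, 5.96), tolerance = 0.01)
  # a right-skewed calibration (upper tail wider than lower)
  cal <- fit_skew_normal(4.92, 3.86, 6.92)
  expect_gt(cal$a, 0)
  expect_true(all(abs(cal$fitted_quantiles - c(3.86, 4.92, 6.92)) /
                    c(3.86, 4.92, 6.92) < 0.01))
  dens <- stats::integrate(function(x) dskewnorm(x, cal$xi, cal$omega, cal$a),
                           -50, 60, rel.tol = 1e-9)
  expect_equal(dens$value, 1, tolerance = 1e-6)
  expect_error(fit_skew_normal(4, 5, 6), "ci_low < point < ci_high")
})

test_that("skew-normal quantiles and sampler agree", {
  set.seed(8)
  x <- rskewnorm(2e5, 1.5, 2, 3)
  q <- qskewnorm(c(0.025, 0.5, 0.975), 1.5, 2, 3)
  expect_equal(q, unname(stats::quantile(x, c(0.025, 0.5, 0.975))),
               tolerance = 0.02)
})

test_that("offset lognormal quantile arithmetic", {
  q <- offset_lognormal_quantiles(0.82, 0.33, 2.65)
  expect_equal(unname(q["q50"]), 2.65 + exp(0.82), tolerance = 1e-12)
  expect_equal(unname(offset_lognormal_quantiles(0, 0.7, 0)["q50"]), 1,
               tolerance = 1e-12)
  # sampling oracle
  set.seed(15)
  draws <- 2.65 + stats::rlnorm(1e6, 0.82, 0.33)
  expect_true(all(abs(q - stats::quantile(draws, c(0.025, 0.5, 0.975))) /
                    q < 0.005))
})

test_that("discrete distributions: construction, quantiles, means", {
  d <- disc_dist(c(3, 1, 2, 2), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(d$x, 1:3)
  expect_equal(d$p, c(0.2, 0.7, 0.1))
  expect_equal(dist_quantile(d, c(0, 0.2, 0.5, 1)), c(1, 1, 2, 3))
  expect_equal(dist_mean(d), 0.2 + 1.4 + 0.3)
  expect_error(disc_dist(1, -1), "non-negative")
  q <- dist_quantile(d, c(0.025, 0.5, 0.975))
  expect_true(q[1] <= q[2] && q[2] <= q[3])
})

test_that("rate distribution: degenerate limits and scaling law", {
  cal <- fit_skew_normal(4.92e6, 3.86e6, 6.92e6)
  # near point-mass inputs concentrate at h / d0
  tight <- structure(list(point = 4.92e6, ci_low = 4.919e6, ci_high = 4.921e6,
                          xi = 4.92e6, omega = 500, a = 0),
                     class = "calibration_spec")
  rd0 <- rate_distribution(0.05, 1e-8, tight)
  q <- dist_quantile(rd0, c(0.025, 0.5, 0.975))
  expect_equal(q[2], 0.05 / 4.92e6, tolerance = 1e-3)
  expect_lt((q[3] - q[1]) / q[2], 2e-3)  # spread collapses with the inputs
  # doubling all calibration dates halves the rate quantiles
  cal2 <- fit_skew_normal(2 * 4.92e6, 2 * 3.86e6, 2 * 6.92e6)
  r1 <- rate_distribution(0.0492, 0.0025, cal)
  r2 <- rate_distribution(0.0492, 0.0025, cal2)
  expect_equal(dist_quantile(r1, c(0.025, 0.5, 0.975)),
               2 * dist_quantile(r2, c(0.025, 0.5, 0.975)), tolerance = 0.01)
  expect_error(rate_distribution(0.05, 0.002, cal, grid = list(n_h = 1)),
               "degenerate")
})

test_that("rate and date distributions match Monte-Carlo sampling oracles", {
  cal <- fit_skew_normal(4.92e6, 3.86e6, 6.92e6)
  h_hat <- 0.0492; se <- 0.0025
  rd <- rate_distribution(h_hat, se, cal)
  set.seed(31)
  h <- stats::rnorm(1e6, h_hat, se)
  h <- h[h > h_hat - 5 * se]
  d <- rskewnorm(length(h), cal$xi, cal$omega, cal$a)
  keep <- d > qskewnorm(0.001, cal$xi, cal$omega, cal$a) &
    d < qskewnorm(0.999, cal$xi, cal$omega, cal$a)
  mu <- h[keep] / d[keep]
  probs <- c(0.025, 0.5, 0.975)
  expect_true(all(abs(dist_quantile(rd, probs) /
                        stats::quantile(mu, probs) - 1) < 0.01))
  dd <- node_date_distribution(72200 * 1e-8, rd)
  ages <- 72200 * 1e-8 / mu
  expect_true(all(abs(dist_quantile(dd, probs) /
                        stats::quantile(ages, probs) - 1) < 0.01))
})

test_that("HPD intervals are shortest intervals with the target mass", {
  d <- disc_dist(1:100, rep(0.01, 100))
  h <- dist_hpd(d, 0.9)
  expect_equal(h[2] - h[1], 89)
  skew <- disc_dist(c(1, 2, 3, 10), c(0.5, 0.3, 0.15, 0.05))
  expect_equal(dist_hpd(skew, 0.95), c(1, 3))  # drops the far tail point
  expect_equal(dist_hpd(skew, 1), c(1, 10))
})

test_that("node-date propagation: zero, point mass, two-point", {
  rd_point <- disc_dist(1e-8, 1)
  expect_equal(dist_quantile(node_date_distribution(0, rd_point), 0.5), 0)
  d <- node_date_distribution(7e-4, rd_point)
  expect_equal(dist_quantile(d, 0.5), 7e4, tolerance = 1e-12)
  rd2 <- disc_dist(c(1e-8, 2e-8), c(0.5, 0.5))
  d2 <- node_date_distribution(1.4e-3, rd2)
  expect_equal(d2$x, c(7e4, 1.4e5))
  expect_equal(d2$p, c(0.5, 0.5))
  expect_error(node_date_distribution(-1, rd2), "non-negative")
})

test_that("topology mixtures: identity, invariance, discrete quantiles", {
  d <- disc_dist(c(1e4, 5e4, 9e4), c(0.25, 0.5, 0.25))
  expect_equal(combine_topologies(list(d), 1), d)
  same <- combine_topologies(list(d, d), c(0.3, 0.7))
  expect_equal(same$x, d$x)
  expect_equal(same$p, d$p, tolerance = 1e-12)
  mix <- combine_topologies(list(disc_dist(70e3, 1), disc_dist(140e3, 1)),
                            c(0.8, 0.2))
  expect_equal(dist_quantile(mix, 0.5), 70e3)
  expect_equal(dist_quantile(mix, 0.975), 140e3)
})

test_that("date report: concentrated weights equal the best topology", {
  sim <- simulate_alignment(default_cheetah_scenario(seed = 51, length = 4000))
  topos <- enumerate_topologies(cheetah_taxa,
                                constraint = c("Puma", "Jaguarundi"))
  true_id <- topology_key(sim$subs_tree)
  w <- structure(data.frame(topology_id = names(topos),
                            weight = as.numeric(names(topos) == true_id)),
                 class = c("rell_weights", "data.frame"))
  cal <- fit_skew_normal(4.92e6, 3.86e6, 6.92e6)
  model <- tn93_params(c(0.31, 0.26, 0.13, 0.30), 30, 16, gamma_shape = 0.3)
  rep <- date_report(sim$alignment, topos, w, cal,
                     clades = list(q = c("India", "SEAfrica_ref",
                                         "SEAfrica_hist", "SEAfrica_mod")),
                     outgroup = c("Puma", "Jaguarundi"), top_k = 10,
                     model = model)
  s <- rep$summary
  expect_equal(s$avg_date, s$best_date, tolerance = 1e-9)
  expect_equal(s$avg_lo, s$best_lo, tolerance = 1e-9)
  expect_equal(s$avg_hi, s$best_hi, tolerance = 1e-9)
  expect_true(s$best_lo <= s$best_date && s$best_date <= s$best_hi)
})
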