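test_that("two-taxon likelihood matches the JC closed form", {
  aln <- as_alignment(c(a = "AG", b = "AC"))
  tr <- ape::read.tree(text = "(a:0.1,b:0.2);")
  ll <- site_log_likelihoods(aln, tr, jc_model())
  pstay <- 1 / 4 + 3 / 4 * exp(-4 * 0.3 / 3)
  pmove <- (1 - pstay) / 3
  expect_equal(ll, c(log(0.25 * pstay), log(0.25 * pmove)), tolerance = 1e-10)
})

test_that("fully missing columns contribute zero log-likelihood", {
  aln <- as_alignment(c(a = "AN-", b = "ANN", c = "GN?"))
  tr <- ape::read.tree(text = "(a:0.1,b:0.2,c:0.05);")
  ll <- site_log_likelihoods(aln, tr, random_tn93(2))
  expect_equal(ll[2], 0, tolerance = 1e-12)
  expect_equal(ll[3], 0, tolerance = 1e-12)
})

test_that("pruning equals the exhaustive-internal-state oracle", {
  # 4 and 5 taxa, ambiguity and missing data included
  cases <- list(
    list(tr = "((a:0.12,b:0.3):0.08,c:0.2,d:0.15);", n = 4, seed = 11),
    list(tr = "(((a:0.05,b:0.07):0.04,c:0.3):0.1,d:0.2,e:0.12);", n = 5,
         seed = 12))
  for (cs in cases) {
    aln <- random_alignment(letters[seq_len(cs$n)], 20, cs$seed)
    tr <- ape::read.tree(text = cs$tr)
    model <- random_tn93(cs$seed)
    expect_equal(site_log_likelihoods(aln, tr, model),
                 exhaustive_site_loglik(aln, tr, model), tolerance = 1e-8)
  }
})

test_that("log-likelihood is invariant to root placement", {
  sim <- simulate_alignment(default_cheetah_scenario(seed = 5, length = 1000))
  model <- random_tn93(6)
  un <- ape::unroot(sim$subs_tree)
  base <- sum(site_log_likelihoods(sim$alignment, un, model))
  for (og in c("Puma", "NEAfrica", "SEAfrica_mod")) {
    r <- ape::root(un, outgroup = og, resolve.root = TRUE)
    expect_equal(sum(site_log_likelihoods(sim$alignment, r, model)), base,
                 tolerance = 1e-8)
  }
})

test_that("pruning agrees with an independent ML engine (phangorn)", {
  library(phangorn)
  sim <- simulate_alignment(default_cheetah_scenario(seed = 9, length = 2000))
  model <- tn93_params(c(0.31, 0.26, 0.13, 0.30), 12, 7, gamma_shape = 0.4)
  mine <- sum(site_log_likelihoods(sim$alignment, ape::unroot(sim$subs_tree),
                                   model))
  m <- do.call(rbind, strsplit(sim$alignment$seqs, ""))
  rownames(m) <- sim$alignment$taxa
  fitp <- phangorn::pml(ape::unroot(sim$subs_tree), phangorn::phyDat(m),
                        bf = c(0.31, 0.26, 0.13, 0.30), k = 5, shape = 0.4,
                        model = "TrN")
  fitp <- update(fitp, Q = c(1, 12, 1, 1, 7, 1))  # AC AG AT CG CT GT order
  expect_equal(mine, as.numeric(stats::logLik(fitp)), tolerance = 1e-4)
})

test_that("identical sequences collapse their cherry branch lengths", {
  set.seed(30)
  s <- paste0(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
              collapse = "")
  sim <- simulate_alignment(default_cheetah_scenario(seed = 3, length = 600))
  seqs <- sim$alignment$seqs
  names(seqs) <- sim$alignment$taxa
  seqs["SEAfrica_hist"] <- seqs["SEAfrica_mod"]  # force an identical cherry
  fit <- fit_no_clock(as_alignment(seqs), sim$subs_tree,
                      optimize_model = FALSE, model = random_tn93(1))
  cherry <- ape::getMRCA(fit$tree, c("SEAfrica_hist", "SEAfrica_mod"))
  # the two pendant edges of the identical pair go to ~0
  pend <- fit$tree$edge[, 1] == cherry &
    fit$tree$edge[, 2] <= length(fit$tree$tip.label)
  expect_lt(max(fit$tree$edge.length[pend]), 1e-6)
})

test_that("no-clock fit recovers simulated branch lengths and nests the clock", {
  nwk <- "((a:2e6,b:2e6):2e6,((c:1e6,d:1e6):1.5e6,e:2.5e6):1.5e6);"
  sc <- sim_scenario(ape::read.tree(text = nwk), 1e-8,
                     tn93_params(c(0.3, 0.25, 0.15, 0.3), 8, 6,
                                 gamma_shape = 0.8),
                     length = 10000, seed = 21)
  sim <- simulate_alignment(sc)
  fit <- fit_no_clock(sim$alignment, sim$subs_tree, optimize_model = TRUE)
  truth <- sim$subs_tree
  key <- function(phy) {
    tips <- lapply(seq_len(max(phy$edge)), function(v) {
      if (v <= 5) phy$tip.label[v] else
        sort(ape::extract.clade(phy, v)$tip.label)
    })
    vapply(phy$edge[, 2], function(v) paste(tips[[v]], collapse = ","), "")
  }
  est <- fit$tree$edge.length[match(key(ape::unroot(truth)),
                                    key(fit$tree))]
  tru <- ape::unroot(truth)$edge.length
  # ~3 SE: binomial-scale error on expected substitutions per edge
  se <- sqrt(pmax(tru, 1e-4) / 10000)
  expect_true(all(abs(est - tru) < 3.5 * se + 2e-4))
  # nesting: the clock fit cannot beat the free fit
  rooted <- root_with_outgroup(ape::unroot(truth), c("a", "b"))
  clock <- fit_strict_clock(sim$alignment, rooted, model = fit$model,
                            optimize_model = FALSE, compute_se = FALSE)
  expect_gte(fit$log_likelihood, clock$log_likelihood - 1e-4)
})

test_that("strict-clock fit recovers simulated node heights", {
  sim <- simulate_alignment(default_cheetah_scenario(seed = 17,
                                                     length = 10000))
  rooted <- root_with_outgroup(ape::unroot(sim$subs_tree),
                               c("Puma", "Jaguarundi"))
  fit <- fit_strict_clock(sim$alignment, rooted, optimize_model = TRUE)
  expect_true(abs(fit$root_height - 0.0492) < 3 * fit$root_height_se)
  # height ratio of the India/SE split to the root (true 72200 / 4.92e6)
  node <- ape::getMRCA(fit$tree, c("India", "SEAfrica_ref"))
  ratio <- fit$heights[node] / fit$root_height
  expect_gt(ratio, 0.4 * 72200 / 4.92e6)
  expect_lt(ratio, 2.5 * 72200 / 4.92e6)
})

test_that("identical sequences give a degenerate (zero-height) clock tree", {
  seqs <- stats::setNames(rep(paste0(rep("ACGT", 50), collapse = ""), 4),
                          c("a", "b", "c", "d"))
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  tr$edge.length <- NULL
  fit <- fit_strict_clock(as_alignment(seqs), tr, model = jc_model(5, 0.5),
                          optimize_model = FALSE, compute_se = FALSE)
  expect_lt(fit$root_height, 1e-6)
})

test_that("root-height SE behaves like inverse square-root information", {
  sim <- simulate_alignment(default_cheetah_scenario(seed = 23, length = 4000))
  rooted <- root_with_outgroup(ape::unroot(sim$subs_tree),
                               c("Puma", "Jaguarundi"))
  model <- tn93_params(c(0.31, 0.26, 0.13, 0.30), 30, 16, gamma_shape = 0.3)
  f1 <- fit_strict_clock(sim$alignment, rooted, model = model,
                         optimize_model = FALSE)
  doubled <- as_alignment(stats::setNames(
    paste0(sim$alignment$seqs, sim$alignment$seqs), sim$alignment$taxa))
  f2 <- fit_strict_clock(doubled, rooted, model = model,
                         optimize_model = FALSE)
  expect_equal(f2$root_height_se / f1$root_height_se, 1 / sqrt(2),
               tolerance = 0.12)
})

test_that("reported root-height SE calibrates against replicate scatter", {
  # 100 seeded replicates: SD of the ML root height should match the mean
  # reported SE within 30%
  nwk <- "((a:2e6,b:2e6):2.92e6,(c:1.5e6,(d:7e5,e:7e5):8e5):3.42e6);"
  model <- tn93_params(c(0.3, 0.25, 0.15, 0.3), 10, 8, gamma_shape = 0.6)
  hs <- ses <- numeric(100)
  for (r in 1:100) {
    sc <- sim_scenario(ape::read.tree(text = nwk), 1e-8, model,
                       length = 1500, seed = 400 + r)
    sim <- simulate_alignment(sc)
    rooted <- root_with_outgroup(ape::unroot(sim$subs_tree), c("a", "b"))
    fit <- fit_strict_clock(sim$alignment, rooted, model = model,
                            optimize_model = TRUE,
                            control = list(n_starts = 1))
    hs[r] <- fit$root_height
    ses[r] <- fit$root_height_se
  }
  expect_equal(stats::sd(hs) / mean(ses), 1, tolerance = 0.3)
})

test_that("clock LRT arithmetic, edge cases and quantile inversion", {
  expect_error(clock_lrt(-10, -5, 7), "optimization failed")
  eq <- clock_lrt(-1234.5, -1234.5, 7)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # statistic placed exactly at the chi-square(5) 95th percentile
  crit <- stats::qchisq(0.95, 5)
  at <- clock_lrt(-1000, -1000 - crit / 2, 7)
  expect_equal(at$p_value, 0.05, tolerance = 1e-10)
  expect_equal(clock_lrt(-5, -6, 10)$df, 8L)
})

test_that("ancestral states: constant columns, star-tree Bayes oracle", {
  aln <- as_alignment(c(a = "GGGG", b = "GGGG", c = "GGGG", d = "GGGG"))
  tr <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,c:0.01,d:0.01);")
  anc <- ancestral_states(aln, tr, jc_model(5, 0.5))
  expect_true(all(anc$map == "G"))
  for (p in anc$posterior) {
    expect_equal(colSums(p), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
  }
  # 3-taxon star: brute-force Bayes over the internal state
  model <- random_tn93(14)
  aln3 <- as_alignment(c(a = "A", b = "C", c = "A"))
  star <- ape::read.tree(text = "(a:0.15,b:0.4,c:0.08);")
  anc3 <- ancestral_states(aln3, star, model)
  g <- discretize_gamma(model$gamma_shape, 5)
  Q <- build_rate_matrix(model)
  joint <- rowSums(vapply(seq_along(g$rates), function(ci) {
    post <- model$base_freqs *
      expm_taylor(Q, 0.15 * g$rates[ci])[, 1] *
      expm_taylor(Q, 0.40 * g$rates[ci])[, 2] *
      expm_taylor(Q, 0.08 * g$rates[ci])[, 1]
    post * g$probs[ci]
  }, numeric(4)))
  expect_equal(as.numeric(anc3$posterior[[1]]), unname(joint / sum(joint)),
               tolerance = 1e-8)
})
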