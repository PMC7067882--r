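test_that("degenerate inputs: one topology, identical rows, bad matrices", {
  m <- matrix(rnorm(10), 1, 10, dimnames = list("t1", NULL))
  w <- bp_rell(m, n_bootstrap = 100, seed = 1)
  expect_equal(w$weight, 1)
  m2 <- rbind(t1 = rnorm(50), t2 = 0)
  m2["t2", ] <- m2["t1", ]
  w2 <- bp_rell(m2, n_bootstrap = 4000, seed = 2)
  expect_equal(w2$weight, c(0.5, 0.5), tolerance = 1e-12)  # exact ties split
  expect_error(bp_rell(matrix(numeric(0), 0, 0), seed = 1), "non-empty")
  expect_error(bp_rell(rbind(c(1, NA)), 10, seed = 1), "NA")
  expect_error(bp_rell(rbind(1), 10), "seed")
})

test_that("2x2 weights match the exhaustive-resample oracle", {
  m <- rbind(t1 = c(0, 0), t2 = c(-1, 1))
  # oracle: enumerate the 4 equiprobable resamples of size 2 (with ties split)
  wins <- c(t1 = 0, t2 = 0)
  for (i in 1:2) for (j in 1:2) {
    tot <- rowSums(m[, c(i, j)])
    top <- which(tot == max(tot))
    wins[top] <- wins[top] + 1 / length(top)
  }
  oracle <- wins / 4
  B <- 10000
  w <- bp_rell(m, n_bootstrap = B, seed = 11)
  se <- sqrt(oracle * (1 - oracle) / B)
  expect_true(all(abs(w$weight - oracle) <= 3 * pmax(se, 1e-3)))
})

test_that("weights are invariant to per-site shifts shared by all topologies", {
  set.seed(40)
  m <- matrix(rnorm(5 * 60), 5, 60,
              dimnames = list(paste0("t", 1:5), NULL))
  shift <- rnorm(60)
  w1 <- bp_rell(m, n_bootstrap = 500, seed = 9)
  w2 <- bp_rell(sweep(m, 2, shift, "+"), n_bootstrap = 500, seed = 9)
  expect_equal(w1$weight, w2$weight, tolerance = 1e-12)
})

test_that("fixed seed reproduces weights bit-identically", {
  set.seed(1)
  m <- matrix(rnorm(4 * 40), 4, 40, dimnames = list(paste0("t", 1:4), NULL))
  w1 <- bp_rell(m, n_bootstrap = 300, seed = 123)
  w2 <- bp_rell(m, n_bootstrap = 300, seed = 123)
  expect_identical(w1$weight, w2$weight)
})

test_that("top-k mass sorts, tie-breaks deterministically and sums", {
  w <- structure(data.frame(topology_id = c("b", "a", "c"),
                            weight = c(0.3, 0.5, 0.2)),
                 class = c("rell_weights", "data.frame"))
  expect_equal(top_k_mass(w, 3)$mass, 1.0)
  k2 <- top_k_mass(w, 2)
  expect_equal(k2$mass, 0.8)
  expect_identical(k2$topology_ids, c("a", "b"))
  wt <- structure(data.frame(topology_id = c("b", "a"), weight = c(0.5, 0.5)),
                  class = c("rell_weights", "data.frame"))
  expect_identical(top_k_mass(wt, 1)$topology_ids, "a")  # id breaks the tie
  expect_error(top_k_mass(w, 4), "out of range")
})

test_that("clade support sums the weights of topologies carrying the clade", {
  topos <- enumerate_topologies(LETTERS[1:5])
  with_clade <- vapply(topos, has_clade, TRUE, clade = c("A", "B"))
  ids <- names(topos)
  w <- structure(data.frame(topology_id = ids,
                            weight = rep(0, length(ids))),
                 class = c("rell_weights", "data.frame"))
  picks <- c(which(with_clade)[1:2], which(!with_clade)[1])
  w$weight[picks] <- c(0.6, 0.22, 0.18)
  expect_equal(clade_support(w, topos, c("A", "B")), 0.82, tolerance = 1e-12)
  expect_equal(clade_support(w, topos, LETTERS[1:5]), 1.0)
  expect_equal(clade_support(w, topos, c("A", "B", "C")),
               sum(w$weight[vapply(topos, has_clade, TRUE,
                                   clade = c("A", "B", "C"))]))
})

test_that("one strongly supported topology takes nearly all RELL mass", {
  sim <- simulate_alignment(default_cheetah_scenario(seed = 77,
                                                     length = 10000))
  topos <- enumerate_topologies(cheetah_taxa,
                                constraint = c("Puma", "Jaguarundi"))
  fits <- fit_topology_set(sim$alignment, topos)
  w <- bp_rell(site_loglik_matrix(fits), n_bootstrap = 1000, seed = 3)
  top <- top_k_mass(w, 1)
  expect_identical(top$topology_ids, topology_key(sim$subs_tree))
  expect_gt(top_k_mass(w, 10)$mass, 0.8)
})
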