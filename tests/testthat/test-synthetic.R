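test_that("zero mutation rate gives identical sequences (before masking)", {
  tr <- ape::read.tree(text = "((a:1e6,b:1e6):1e6,(c:1.5e6,d:1.5e6):5e5);")
  sc <- sim_scenario(tr, 0, jc_model(5, 0.5), length = 300, seed = 2)
  sim <- simulate_alignment(sc)
  expect_length(unique(sim$alignment$seqs), 1)
})

test_that("pairwise divergence follows the JC expectation", {
  tr <- ape::read.tree(text = "(a:5e6,b:5e6);")
  sc <- sim_scenario(tr, 1e-8, jc_model(1), length = 1e5, seed = 13)
  sim <- simulate_alignment(sc)  # expected path length 0.1 subs/site
  p_exp <- 3 / 4 * (1 - exp(-4 * 0.1 / 3))
  x <- strsplit(sim$alignment$seqs[1], "")[[1]]
  y <- strsplit(sim$alignment$seqs[2], "")[[1]]
  p_obs <- mean(x != y)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e5))
})

test_that("base composition matches the stationary frequencies", {
  tr <- ape::read.tree(text = "(a:1e6,b:1e6);")
  model <- tn93_params(c(0.31, 0.26, 0.13, 0.30), 30, 16, gamma_shape = 0.3)
  sc <- sim_scenario(tr, 1e-8, model, length = 1e5, seed = 19)
  sim <- simulate_alignment(sc)
  f <- base_frequencies(sim$alignment)
  se <- sqrt(model$base_freqs * (1 - model$base_freqs) / 2e5)
  expect_true(all(abs(f - model$base_freqs) < 3.5 * se))
})

test_that("expected substitutions scale with rate times duration", {
  # JC-corrected distances across several branch lengths track the truth
  for (yrs in c(1e6, 3e6, 6e6)) {
    tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", yrs, yrs))
    sc <- sim_scenario(tr, 1e-8, jc_model(1), length = 3e4, seed = yrs / 1e5)
    sim <- simulate_alignment(sc)
    x <- strsplit(sim$alignment$seqs[1], "")[[1]]
    y <- strsplit(sim$alignment$seqs[2], "")[[1]]
    d_jc <- -3 / 4 * log(1 - 4 / 3 * mean(x != y))
    truth <- 2 * yrs * 1e-8
    expect_equal(d_jc, truth, tolerance = 0.08)
  }
})

test_that("the default cheetah scenario states the documented world", {
  sc <- default_cheetah_scenario(seed = 4)
  expect_true(ape::is.ultrametric(sc$time_tree, tol = 1e-6))
  expect_length(sc$time_tree$tip.label, 7)
  expect_setequal(sc$time_tree$tip.label, cheetah_taxa)
  depth <- max(ape::node.depth.edgelength(sc$time_tree))
  expect_equal(depth, 4.92e6)
  tru <- attr(sc, "truth")
  expect_equal(tru$india_se_split, 72200)
  expect_equal(tru$ne_split, 138900)
  # India's mask leaves the documented number of called sites
  sim <- simulate_alignment(sc)
  india <- strsplit(sim$alignment$seqs[sim$alignment$taxa == "India"], "")[[1]]
  expect_equal(sum(india != "N"), 3675)
})

test_that("identical seeds give byte-identical FASTA; seeds matter", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(simulate_alignment(default_cheetah_scenario(seed = 8,
                                                          length = 800))$alignment, f1)
  write_fasta(simulate_alignment(default_cheetah_scenario(seed = 8,
                                                          length = 800))$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".fa")
  write_fasta(simulate_alignment(default_cheetah_scenario(seed = 9,
                                                          length = 800))$alignment, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("chimera truth records a plausible Binomial draw and edge cases", {
  s <- paste0(rep("ACGT", 500), collapse = "")
  c0 <- make_numt_chimera(s, c(100, 1100), divergence = 0, seed = 5)
  expect_identical(c0$sequence, s)
  expect_equal(c0$n_mutated, 0)
  c1 <- make_numt_chimera(s, c(100, 1100), divergence = 1e-6, seed = 5)
  expect_lte(c1$n_mutated, 1)
  c5 <- make_numt_chimera(s, c(100, 1100), divergence = 0.05, seed = 5)
  expect_gt(c5$n_mutated, qbinom(0.0005, 1000, 0.05))
  expect_lt(c5$n_mutated, qbinom(0.9995, 1000, 0.05))
  expect_true(all(c5$mutated_positions >= 100 & c5$mutated_positions < 1100))
  expect_error(make_numt_chimera(s, c(100, 3000), 0.05), "bounds")
  expect_error(make_numt_chimera(s, c(100, 200), 0.9), "0.75")
})

test_that("alignment IO round-trips FASTA and reads PHYLIP", {
  sim <- simulate_alignment(default_cheetah_scenario(seed = 3, length = 400))
  f <- tempfile(fileext = ".fa")
  write_fasta(sim$alignment, f)
  back <- read_alignment(f)
  expect_equal(back$seqs, sim$alignment$seqs)
  expect_equal(back$taxa, sim$alignment$taxa)
  p <- tempfile(fileext = ".phy")
  writeLines(c("3 8", "one       ACGTACGT", "two       ACGTACGA",
               "three     ACGTTCGA"), p)
  phy <- read_alignment(p)
  expect_equal(phy$length, 8)
  expect_equal(phy$taxa, c("one", "two", "three"))
})
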