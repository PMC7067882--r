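#' Simulation scenario for a clock-tree alignment
#'
#' Bundles everything the forward simulator needs: a rooted ultrametric time
#' tree (branch lengths in years), a mutation rate (substitutions/site/year),
#' a TN93+Gamma model, an alignment length, per-taxon missing-data masks
#' (0-based half-open intervals set to `N`, mimicking partial historical
#' sequences) and a seed.
#'
#' @param time_tree rooted ultrametric `phylo`, branch lengths in years.
#' @param mutation_rate substitutions/site/year (> 0).
#' @param model a [tn93_params()] object.
#' @param length alignment length in sites.
#' @param masks named list (by taxon) of 2-column matrices of `[start, end)`
#'   intervals to mask, or NULL.
#' @param seed integer RNG seed.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(time_tree, mutation_rate, model, length,
                         masks = NULL, seed = 1L) {
  stopifnot(inherits(time_tree, "phylo"), inherits(model, "tn93g"))
  if (!ape::is.rooted(time_tree)) stop("time tree must be rooted")
  if (!ape::is.ultrametric(time_tree, tol = 1e-6)) {
    stop("time tree must be ultrametric")
  }
  if (mutation_rate < 0) stop("mutation_rate must be non-negative")
  length <- as.integer(length)
  if (length < 1L) stop("length must be positive")
  for (nm in names(masks)) {
    if (!nm %in% time_tree$tip.label) stop("mask for unknown taxon: ", nm)
    m <- masks[[nm]]
    if (any(m[, 1] < 0 | m[, 2] > length | m[, 1] >= m[, 2])) {
      stop("mask intervals out of [0, length) for ", nm)
    }
  }
  structure(list(time_tree = time_tree, mutation_rate = mutation_rate,
                 model = model, length = length, masks = masks,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Default 7-taxon cheetah-like scenario
#'
#' The stated world of the study's dataset, used as generative truth for
#' recovery and coverage experiments: an outgroup cherry (puma + jaguarundi)
#' splitting from the cheetahs 4.92 My ago (the fossil calibration point,
#' intra-outgroup split 4.17 My), a Northeast-African lineage splitting
#' 138.9 ky ago, India splitting from the Southeast-African clade 72.2 ky ago,
#' and three Southeast-African sequences with shallow splits (24 and 10 ky).
#' Defaults: 15 kb of coding-like sequence at 1e-8 substitutions/site/year
#' under TN93 + G5, with contiguous missing-data masks leaving the India taxon
#' ~3675 called sites and the historical SE-African taxon about half called.
#'
#' @param seed RNG seed for the scenario (propagated to the simulator).
#' @param length alignment length (default 15000; masks scale with it).
#' @return a [sim_scenario()] whose `truth` attribute records the split times.
#' @export
default_cheetah_scenario <- function(seed = 1L, length = 15000L) {
  nwk <- paste0(
    "((Puma:4170000,Jaguarundi:4170000):750000,",
    "(NEAfrica:138900,(India:72200,(SEAfrica_ref:24000,",
    "(SEAfrica_hist:10000,SEAfrica_mod:10000):14000):48200):66700)",
    ":4781100);")
  tree <- ape::read.tree(text = nwk)
  model <- tn93_params(c(0.31, 0.26, 0.13, 0.30), rate_AG = 30, rate_CT = 16,
                       gamma_shape = 0.3, n_categories = 5L)
  length <- as.integer(length)
  sc <- function(x) as.integer(round(x / 15000 * length))  # scale to length
  masks <- list(
    # India keeps [2000,3500) + [6000,8175): 3675 called of 15000
    India = rbind(c(sc(0), sc(2000)), c(sc(3500), sc(6000)),
                  c(sc(8175), length)),
    # historical SE-African keeps [500,4500) + [9000,12300): 7300 called
    SEAfrica_hist = rbind(c(sc(0), sc(500)), c(sc(4500), sc(9000)),
                          c(sc(12300), length)))
  s <- sim_scenario(tree, mutation_rate = 1e-8, model = model,
                    length = length, masks = masks, seed = seed)
  attr(s, "truth") <- list(
    root_age = 4.92e6, outgroup_split = 4.17e6, ne_split = 138900,
    india_se_split = 72200, se_splits = c(24000, 10000),
    india_clade = c("India", "SEAfrica_ref", "SEAfrica_hist", "SEAfrica_mod"),
    ne_clade = c("NEAfrica", "India", "SEAfrica_ref", "SEAfrica_hist",
                 "SEAfrica_mod"))
  s
}

#' Forward-simulate an alignment down a clock tree
#'
#' Site-independent simulation under TN93 + discrete-Gamma: each site draws a
#' Gamma category, root states come from the stationary frequencies, and each
#' branch applies the per-category transition matrix for `rate * duration`
#' expected substitutions. Masks are applied last. Reproducible: the same
#' scenario (seed included) yields byte-identical sequences.
#'
#' @param scenario a [sim_scenario()].
#' @return list: `alignment` ([as_alignment()]), `time_tree` (years),
#'   `subs_tree` (`phylo` with branch lengths in expected
#'   substitutions/site), `truth` (scenario truth attribute plus seed, rate
#'   and mask spans).
#' @export
simulate_alignment <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(scenario$seed)
  phy <- stats::reorder(scenario$time_tree, "cladewise")
  ntip <- length(phy$tip.label)
  nnode <- max(phy$edge)
  L <- scenario$length
  model <- scenario$model
  eg <- tn93_eigen(model)
  crates <- discretize_gamma(model$gamma_shape, model$n_categories)$rates
  cat_of_site <- sample.int(length(crates), L, replace = TRUE)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  states <- matrix(0L, nnode, L)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = eg$pi)
  blen_subs <- phy$edge.length * scenario$mutation_rate
  for (e in seq_len(nrow(phy$edge))) {      # cladewise = parents first
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    for (c in seq_along(crates)) {
      P <- eg$U %*% (exp(eg$lambda * blen_subs[e] * crates[c]) * eg$Uinv)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      for (x in 1:4) {
        idx <- which(cat_of_site == c & states[par, ] == x)
        if (length(idx)) {
          states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                        prob = P[x, ])
        }
      }
    }
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(s) {
    paste0(DNA_BASES[s], collapse = "")
  })
  names(seqs) <- phy$tip.label
  for (nm in names(scenario$masks)) {
    ch <- strsplit(seqs[[nm]], "")[[1]]
    for (i in seq_len(nrow(scenario$masks[[nm]]))) {
      iv <- scenario$masks[[nm]][i, ]
      if (iv[2] > iv[1]) ch[(iv[1] + 1):iv[2]] <- "N"
    }
    seqs[[nm]] <- paste0(ch, collapse = "")
  }
  subs_tree <- phy
  subs_tree$edge.length <- blen_subs
  truth <- c(attr(scenario, "truth"),
             list(mutation_rate = scenario$mutation_rate,
                  seed = scenario$seed,
                  masks = scenario$masks))
  list(alignment = as_alignment(seqs), time_tree = phy, subs_tree = subs_tree,
       truth = truth)
}

#' Implant a numt-like diverged segment into a sequence
#'
#' Within `segment` (0-based half-open), each position independently mutates
#' with probability `divergence` to a uniformly chosen different base (only
#' A/C/G/T positions are eligible). The realized mutated positions are
#' recorded as truth.
#'
#' @param sequence character string.
#' @param segment integer c(start, end), 0-based half-open, within bounds.
#' @param divergence per-site mutation probability in `[0, 0.75]`.
#' @param seed RNG seed.
#' @return list: `sequence` (chimeric), `mutated_positions` (0-based),
#'   `n_mutated`.
#' @export
make_numt_chimera <- function(sequence, segment, divergence, seed = 1L) {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  if (segment[1] < 0 || segment[2] > L || segment[1] >= segment[2]) {
    stop("segment out of bounds")
  }
  if (divergence < 0 || divergence > 0.75) {
    stop("divergence must be in [0, 0.75]")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  idx <- (segment[1] + 1):segment[2]
  idx <- idx[ch[idx] %in% DNA_BASES]
  hit <- idx[stats::runif(length(idx)) < divergence]
  for (i in hit) {
    ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  }
  list(sequence = paste0(ch, collapse = ""), mutated_positions = hit - 1L,
       n_mutated = length(hit))
}
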