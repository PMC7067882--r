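#' Per-site log-likelihoods by Felsenstein pruning
#'
#' Computes the log-likelihood of every alignment column on a tree under the
#' TN93 + discrete-Gamma model, mixing the equal-probability rate categories:
#' `ll_s = log mean_c L_s(c)`. Ambiguity codes contribute partial likelihood 1
#' over their compatible states; `-`/`N` are fully missing (an all-missing
#' column has log-likelihood 0). The model is time-reversible, so the value is
#' invariant to root placement.
#'
#' @param aln alignment ([as_alignment()]).
#' @param tree `phylo` with branch lengths in expected substitutions/site, or
#'   a clock fit from [fit_strict_clock()]. Tree taxa must be a subset of the
#'   alignment's; the alignment is subset to the tree.
#' @param model a [tn93_params()] object.
#' @return numeric vector, one log-likelihood per site.
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  phy <- as_phylo_tree(tree)
  aln <- as_alignment(aln)
  pat <- alignment_patterns(aln)
  pll <- pattern_loglik(pat, phy, model)
  unname(pll[pat$site_index])
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "clock_fit")) return(tree$tree)
  if (inherits(tree, "mt_fit")) return(tree$tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo or a fit object")
  tree
}

# per-pattern log-likelihood (category-mixed); pat from alignment_patterns()
pattern_loglik <- function(pat, phy, model, eg = NULL, crates = NULL) {
  po <- prep_pruning(pat, phy)
  if (is.null(eg)) eg <- tn93_eigen(model)
  if (is.null(crates)) {
    crates <- discretize_gamma(model$gamma_shape, model$n_categories)$rates
  }
  as.numeric(pruning_siteloglik_cpp(po$cube, po$edge, po$blen, eg$U,
                                    eg$lambda, eg$Uinv, eg$pi, crates))
}

# postorder edge matrix + tip-partial cube in the tree's tip order
prep_pruning <- function(pat, phy) {
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  miss <- setdiff(phy$tip.label, pat$taxa)
  if (length(miss)) stop("tree taxa absent from alignment: ",
                         paste(miss, collapse = " "))
  phy <- stats::reorder(phy, "postorder")
  cube <- pat$cube[, , match(phy$tip.label, pat$taxa), drop = FALSE]
  list(cube = cube, edge = phy$edge, blen = phy$edge.length)
}

default_model_init <- function(aln) {
  tn93_params(base_frequencies(aln), rate_AG = 4, rate_CT = 4,
              gamma_shape = 0.5, n_categories = 5L)
}

with_model_params <- function(model, logpar) {
  tn93_params(model$base_freqs, exp(logpar[1]), exp(logpar[2]),
              gamma_shape = exp(logpar[3]), n_categories = model$n_categories)
}

MODEL_LOG_BOUNDS <- list(lower = c(log(1e-2), log(1e-2), log(2e-2)),
                         upper = c(log(1e3), log(1e3), log(1e2)))

#' Maximum-likelihood fit without a clock (free branch lengths)
#'
#' Optimizes all branch lengths of an unrooted topology (and, optionally, the
#' TN93 transition/transversion ratios and Gamma shape) by bounded
#' quasi-Newton search on log branch lengths, with two deterministic perturbed
#' restarts. Base frequencies stay empirical. Being the unconstrained parent
#' of the strict-clock model, its log-likelihood is never below a clock fit on
#' the same topology.
#'
#' @param aln alignment.
#' @param topology `phylo`; rooted input is unrooted first. Branch lengths, if
#'   present, seed the search.
#' @param model optional [tn93_params()] start (default: empirical
#'   frequencies, rates 4, shape 0.5).
#' @param optimize_model re-optimize rates and Gamma shape (default TRUE); if
#'   FALSE the supplied model is held fixed.
#' @param control list; `reltol` (default 1e-8) and `maxit` (default 500)
#'   passed to the optimizer.
#' @return object of class `mt_fit`: `tree` (with ML branch lengths), `model`,
#'   `log_likelihood`, `site_log_likelihoods`, `convergence`.
#' @export
fit_no_clock <- function(aln, topology, model = NULL, optimize_model = TRUE,
                         control = list()) {
  aln <- as_alignment(aln)
  if (is.null(model)) model <- default_model_init(aln)
  pat <- alignment_patterns(aln)
  fit <- fit_no_clock_core(pat, topology, model, optimize_model, control)
  fit$site_log_likelihoods <- fit$pattern_loglik[pat$site_index]
  fit$pattern_loglik <- NULL
  fit
}

# pattern-level workhorse shared by fit_no_clock() and fit_topology_set();
# all optimizer evaluations reuse one postorder structure and tip-partial cube
fit_no_clock_core <- function(pat, topology, model, optimize_model = TRUE,
                              control = list()) {
  phy <- stats::reorder(ape::unroot(as_phylo_tree(topology)), "postorder")
  if (length(phy$tip.label) < 3L) stop("need at least 3 taxa")
  miss <- setdiff(phy$tip.label, pat$taxa)
  if (length(miss)) stop("tree taxa absent from alignment: ",
                         paste(miss, collapse = " "))
  cube <- pat$cube[, , match(phy$tip.label, pat$taxa), drop = FALSE]
  nb <- nrow(phy$edge)
  b0 <- phy$edge.length
  if (is.null(b0)) b0 <- rep(0.05, nb)
  b0 <- pmax(b0, 1e-7)
  eg0 <- tn93_eigen(model)
  cr0 <- discretize_gamma(model$gamma_shape, model$n_categories)$rates
  w <- pat$weights

  negll <- function(x) {
    if (optimize_model) {
      m <- with_model_params(model, x[nb + 1:3])
      eg <- tn93_eigen(m)
      cr <- discretize_gamma(m$gamma_shape, m$n_categories)$rates
    } else {
      eg <- eg0; cr <- cr0
    }
    v <- pruning_siteloglik_cpp(cube, phy$edge, exp(x[seq_len(nb)]),
                                eg$U, eg$lambda, eg$Uinv, eg$pi, cr)
    s <- -sum(w * v)
    if (!is.finite(s)) 1e12 else s
  }
  # analytic gradient for branch lengths; short forward differences for the
  # three model parameters
  negll_grad <- function(x) {
    if (optimize_model) {
      m <- with_model_params(model, x[nb + 1:3])
      eg <- tn93_eigen(m)
      cr <- discretize_gamma(m$gamma_shape, m$n_categories)$rates
    } else {
      eg <- eg0; cr <- cr0
    }
    bl <- exp(x[seq_len(nb)])
    g <- pruning_grad_cpp(cube, phy$edge, bl, eg$U, eg$lambda, eg$Uinv,
                          eg$pi, cr, w)
    gb <- -g$gradient * bl
    if (any(!is.finite(gb))) gb <- numeric(nb)
    if (!optimize_model) return(gb)
    f0 <- -g$loglik
    gm <- numeric(3)
    if (is.finite(f0)) {
      for (i in 1:3) {
        xx <- x
        xx[nb + i] <- xx[nb + i] + 1e-5
        fv <- negll(xx)
        gm[i] <- if (fv < 1e11) (fv - f0) / 1e-5 else 0
      }
    }
    c(gb, gm)
  }
  lower <- rep(log(1e-9), nb)
  upper <- rep(log(10), nb)
  m0 <- c(log(model$rate_AG), log(model$rate_CT), log(model$gamma_shape))
  if (optimize_model) {
    lower <- c(lower, MODEL_LOG_BOUNDS$lower)
    upper <- c(upper, MODEL_LOG_BOUNDS$upper)
  }
  ctl <- list(maxit = control$maxit %||% 500,
              factr = (control$reltol %||% 1e-9) / .Machine$double.eps)
  n_starts <- control$n_starts %||% 3L
  starts <- list(b0, pmax(b0 * 0.2, 1e-8), pmin(b0 * 5, 5))[seq_len(n_starts)]
  best <- NULL
  for (s in starts) {
    x0 <- log(s)
    if (optimize_model) x0 <- c(x0, m0)
    opt <- stats::optim(pmin(pmax(x0, lower), upper), negll, negll_grad,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = ctl)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  phy$edge.length <- exp(best$par[seq_len(nb)])
  model_hat <- if (optimize_model) {
    with_model_params(model, best$par[nb + 1:3])
  } else model
  eg <- tn93_eigen(model_hat)
  cr <- discretize_gamma(model_hat$gamma_shape, model_hat$n_categories)$rates
  pll <- as.numeric(pruning_siteloglik_cpp(cube, phy$edge, phy$edge.length,
                                           eg$U, eg$lambda, eg$Uinv, eg$pi,
                                           cr))
  structure(list(tree = phy, model = model_hat, log_likelihood = -best$value,
                 pattern_loglik = pll, convergence = best$convergence),
            class = "mt_fit")
}

#' Fit every topology in a candidate set
#'
#' Shares the site-pattern compression and (optionally) the substitution model
#' across topologies, which is what makes exhaustive RELL analyses affordable:
#' the model is fitted once on a neighbor-joining starting tree, then each
#' candidate topology gets a branch-length-only fit unless
#' `reoptimize_model = TRUE`.
#'
#' @param aln alignment.
#' @param topologies named list / `multiPhylo` of candidate topologies.
#' @param model optional [tn93_params()]; fitted on an NJ topology if NULL.
#' @param reoptimize_model re-optimize model parameters per topology
#'   (default FALSE; the shared-model shortcut changes per-site
#'   log-likelihoods very little for near-identical candidate trees).
#' @param control optimizer control; `n_starts` (default 1 here) selects how
#'   many perturbed restarts each topology gets.
#' @return named list of `mt_fit` objects (an attribute `model` records the
#'   shared model).
#' @export
fit_topology_set <- function(aln, topologies, model = NULL,
                             reoptimize_model = FALSE, control = list()) {
  aln <- as_alignment(aln)
  pat <- alignment_patterns(aln)
  if (is.null(model)) {
    base <- fit_no_clock_core(pat, base_nj_topology(aln),
                              default_model_init(aln), TRUE, control)
    model <- base$model
  }
  control$n_starts <- control$n_starts %||% 1L
  fits <- lapply(topologies, function(tp) {
    f <- fit_no_clock_core(pat, tp, model, reoptimize_model, control)
    f$site_log_likelihoods <- f$pattern_loglik[pat$site_index]
    f$pattern_loglik <- NULL
    f
  })
  names(fits) <- names(topologies)
  attr(fits, "model") <- model
  fits
}

#' @export
print.mt_fit <- function(x, ...) {
  cat("no-clock ML fit:", length(x$tree$tip.label), "taxa, logL =",
      sprintf("%.4f", x$log_likelihood), "\n")
  invisible(x)
}

# ---- strict clock ----------------------------------------------------------

# parent index and preorder of internal nodes for a rooted binary phylo
clock_skeleton <- function(phy) {
  ntip <- length(phy$tip.label)
  if (!ape::is.rooted(phy)) stop("clock fit needs a rooted topology")
  if (!ape::is.binary(phy)) stop("clock fit needs a binary topology")
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  pre <- stats::reorder(phy, "cladewise")$edge[, 2]
  internal_pre <- pre[pre > ntip]          # preorder, excludes root
  list(ntip = ntip, nnode = max(phy$edge), root = root, parent = parent,
       internal_pre = internal_pre)
}

heights_from_par <- function(sk, hlog, fr_logit) {
  h <- numeric(sk$nnode)
  h[sk$root] <- exp(hlog)
  f <- stats::plogis(fr_logit)
  for (i in seq_along(sk$internal_pre)) {
    v <- sk$internal_pre[i]
    h[v] <- h[sk$parent[v]] * f[i]
  }
  h
}

# tips have height 0 (contemporaneous); edge length = parent minus child height
set_clock_blen <- function(phy, heights) {
  phy$edge.length <- heights[phy$edge[, 1]] - heights[phy$edge[, 2]]
  phy
}

# UPGMA-style initial heights from pairwise JC distances
init_heights <- function(aln, phy, sk) {
  m <- do.call(rbind, strsplit(as_alignment(aln)$seqs, ""))
  rownames(m) <- as_alignment(aln)$taxa
  d <- ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "JC69",
                     pairwise.deletion = TRUE, as.matrix = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 0.5)
  tipsets <- lapply(seq_len(max(phy$edge)), function(v) {
    if (v <= sk$ntip) phy$tip.label[v] else
      ape::extract.clade(phy, v)$tip.label
  })
  kids <- lapply(seq_len(max(phy$edge)), function(v) phy$edge[phy$edge[, 1] == v, 2])
  h <- numeric(max(phy$edge))
  for (v in c(rev(sk$internal_pre), sk$root)) {
    a <- tipsets[[kids[[v]][1]]]
    b <- tipsets[[kids[[v]][2]]]
    h[v] <- max(mean(d[a, b, drop = FALSE]) / 2, 1e-6)
  }
  # enforce parent > child for a feasible start
  for (v in sk$internal_pre) h[v] <- min(h[v], 0.95 * h[sk$parent[v]])
  h
}

#' Maximum-likelihood fit under a strict molecular clock
#'
#' Optimizes internal-node heights (expected substitutions/site, tips at 0) of
#' a rooted, outgroup-rooted topology so the tree is ultrametric, optionally
#' re-optimizing the substitution model. Heights are parameterized as the root
#' height times nested fractions in (0,1), guaranteeing ultrametricity
#' throughout the search. The root-height standard error is taken from the
#' curvature of the profile log-likelihood ([estimate_root_height_se()]).
#'
#' @inheritParams fit_no_clock
#' @param rooted_topology rooted binary `phylo`.
#' @param compute_se also estimate the root-height standard error
#'   (default TRUE).
#' @return object of class `clock_fit`: `tree` (ultrametric, with branch
#'   lengths), `heights` (per node id), `root_height`, `root_height_se`,
#'   `model`, `log_likelihood`, `site_log_likelihoods`, `convergence`.
#' @export
fit_strict_clock <- function(aln, rooted_topology, model = NULL,
                             optimize_model = TRUE, compute_se = TRUE,
                             control = list()) {
  aln <- as_alignment(aln)
  phy <- as_phylo_tree(rooted_topology)
  sk <- clock_skeleton(phy)
  if (is.null(model)) model <- default_model_init(aln)
  pat <- alignment_patterns(aln)
  nin <- length(sk$internal_pre)
  m0 <- c(log(model$rate_AG), log(model$rate_CT), log(model$gamma_shape))
  pp <- stats::reorder(phy, "postorder")
  miss <- setdiff(pp$tip.label, pat$taxa)
  if (length(miss)) stop("tree taxa absent from alignment: ",
                         paste(miss, collapse = " "))
  cube <- pat$cube[, , match(pp$tip.label, pat$taxa), drop = FALSE]
  eg0 <- tn93_eigen(model)
  cr0 <- discretize_gamma(model$gamma_shape, model$n_categories)$rates
  w <- pat$weights

  negll <- function(x) {
    h <- heights_from_par(sk, x[1], x[1 + seq_len(nin)])
    if (optimize_model) {
      m <- with_model_params(model, x[1 + nin + 1:3])
      eg <- tn93_eigen(m)
      cr <- discretize_gamma(m$gamma_shape, m$n_categories)$rates
    } else {
      eg <- eg0; cr <- cr0
    }
    v <- pruning_siteloglik_cpp(cube, pp$edge,
                                h[pp$edge[, 1]] - h[pp$edge[, 2]],
                                eg$U, eg$lambda, eg$Uinv, eg$pi, cr)
    s <- -sum(w * v)
    if (!is.finite(s)) 1e12 else s
  }
  # chain rule: d logL / d height from per-edge gradients, then through the
  # root-times-nested-fractions parameterization
  internals <- c(sk$root, sk$internal_pre)
  desc_mask <- matrix(FALSE, nin, length(internals))
  for (vi in seq_along(internals)) {
    u <- internals[vi]
    while (u != sk$root) {
      desc_mask[match(u, sk$internal_pre), vi] <- TRUE
      u <- sk$parent[u]
    }
  }
  negll_grad <- function(x) {
    h <- heights_from_par(sk, x[1], x[1 + seq_len(nin)])
    if (optimize_model) {
      m <- with_model_params(model, x[1 + nin + 1:3])
      eg <- tn93_eigen(m)
      cr <- discretize_gamma(m$gamma_shape, m$n_categories)$rates
    } else {
      eg <- eg0; cr <- cr0
    }
    g <- pruning_grad_cpp(cube, pp$edge,
                          h[pp$edge[, 1]] - h[pp$edge[, 2]],
                          eg$U, eg$lambda, eg$Uinv, eg$pi, cr, w)
    ge <- g$gradient
    if (any(!is.finite(ge))) return(numeric(length(x)))
    D <- numeric(sk$nnode)
    for (e in seq_along(ge)) {
      D[pp$edge[e, 1]] <- D[pp$edge[e, 1]] + ge[e]
      D[pp$edge[e, 2]] <- D[pp$edge[e, 2]] - ge[e]
    }
    Dh <- D[internals] * h[internals]
    f <- stats::plogis(x[1 + seq_len(nin)])
    gpar <- -c(sum(Dh),
               if (nin) (1 - f) * as.numeric(desc_mask %*% Dh) else NULL)
    if (!optimize_model) return(gpar)
    f0 <- -g$loglik
    gm <- numeric(3)
    if (is.finite(f0)) {
      for (i in 1:3) {
        xx <- x
        xx[1 + nin + i] <- xx[1 + nin + i] + 1e-5
        fv <- negll(xx)
        gm[i] <- if (fv < 1e11) (fv - f0) / 1e-5 else 0
      }
    }
    c(gpar, gm)
  }
  h0 <- init_heights(aln, phy, sk)
  f0 <- if (nin) stats::qlogis(pmin(pmax(
    h0[sk$internal_pre] / h0[sk$parent[sk$internal_pre]], 0.02), 0.98)) else numeric(0)
  lower <- c(log(1e-8), rep(-9, nin))
  upper <- c(log(10), rep(9, nin))
  if (optimize_model) {
    lower <- c(lower, MODEL_LOG_BOUNDS$lower)
    upper <- c(upper, MODEL_LOG_BOUNDS$upper)
  }
  ctl <- list(maxit = control$maxit %||% 500,
              factr = (control$reltol %||% 1e-8) / .Machine$double.eps)
  starts <- list(c(log(max(h0[sk$root], 1e-6)), f0),
                 c(log(max(h0[sk$root] * 3, 1e-6)), f0 * 0),
                 c(log(max(h0[sk$root] / 3, 1e-6)), f0 * 0 + 1))
  best <- NULL
  for (s in starts) {
    x0 <- if (optimize_model) c(s, m0) else s
    opt <- stats::optim(pmin(pmax(x0, lower), upper), negll, negll_grad,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = ctl)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  h <- heights_from_par(sk, best$par[1], best$par[1 + seq_len(nin)])
  model_hat <- if (optimize_model) {
    with_model_params(model, best$par[1 + nin + 1:3])
  } else model
  tree <- set_clock_blen(phy, h)
  sll <- site_log_likelihoods(aln, tree, model_hat)
  fit <- structure(list(tree = tree, heights = h, root_height = h[sk$root],
                        root_height_se = NA_real_, model = model_hat,
                        log_likelihood = -best$value,
                        site_log_likelihoods = sll,
                        convergence = best$convergence,
                        skeleton = sk, par = best$par, nin = nin),
                   class = "clock_fit")
  if (compute_se) fit$root_height_se <- estimate_root_height_se(aln, fit)
  fit
}

#' @export
print.clock_fit <- function(x, ...) {
  cat("strict-clock ML fit:", length(x$tree$tip.label), "taxa, logL =",
      sprintf("%.4f", x$log_likelihood), "\n")
  cat("  root height:", sprintf("%.6g", x$root_height),
      "+/-", sprintf("%.3g", x$root_height_se), "subs/site\n")
  invisible(x)
}

#' Root-height standard error from the profile log-likelihood
#'
#' Fixes the root height at `h - d`, `h`, `h + d`, re-optimizes the remaining
#' node-height fractions (and, by default, the free substitution-model
#' parameters, matching how reference ML engines report curvature standard
#' errors) at each point, and returns `(-d2 logLik / dh2)^(-1/2)` from the
#' second difference of the profile: the usual Wald standard error under a
#' locally normal likelihood. The step is refined once toward the estimated
#' SE.
#'
#' @param aln alignment used in the fit.
#' @param clock_fit result of [fit_strict_clock()].
#' @param rel_step initial step as a fraction of the root height.
#' @param profile_model also profile over the TN93 rates and Gamma shape
#'   (default TRUE); FALSE treats the model as known.
#' @return positive standard error (substitutions/site).
#' @export
estimate_root_height_se <- function(aln, clock_fit, rel_step = 0.05,
                                    profile_model = TRUE) {
  stopifnot(inherits(clock_fit, "clock_fit"))
  aln <- as_alignment(aln)
  pat <- alignment_patterns(aln)
  sk <- clock_fit$skeleton
  nin <- clock_fit$nin
  model <- clock_fit$model
  eg0 <- tn93_eigen(model)
  cr0 <- discretize_gamma(model$gamma_shape, model$n_categories)$rates
  pp <- stats::reorder(clock_fit$tree, "postorder")
  cube <- pat$cube[, , match(pp$tip.label, pat$taxa), drop = FALSE]
  w <- pat$weights
  p_hat <- clock_fit$par[1 + seq_len(nin)]
  if (profile_model) {
    p_hat <- c(p_hat, log(model$rate_AG), log(model$rate_CT),
               log(model$gamma_shape))
  }
  npar <- length(p_hat)

  prof <- function(hlog) {
    negll <- function(par) {
      h <- heights_from_par(sk, hlog, par[seq_len(nin)])
      if (profile_model) {
        m <- with_model_params(model, par[nin + 1:3])
        eg <- tn93_eigen(m)
        cr <- discretize_gamma(m$gamma_shape, m$n_categories)$rates
      } else {
        eg <- eg0; cr <- cr0
      }
      v <- pruning_siteloglik_cpp(cube, pp$edge,
                                  h[pp$edge[, 1]] - h[pp$edge[, 2]],
                                  eg$U, eg$lambda, eg$Uinv, eg$pi, cr)
      s <- -sum(w * v)
      if (!is.finite(s)) 1e12 else s
    }
    if (npar == 0) return(-negll(numeric(0)))
    lower <- c(rep(-9, nin), if (profile_model) MODEL_LOG_BOUNDS$lower)
    upper <- c(rep(9, nin), if (profile_model) MODEL_LOG_BOUNDS$upper)
    opt <- stats::optim(p_hat, negll, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 200))
    -opt$value
  }
  h_hat <- clock_fit$root_height
  # re-profile at the optimum too: if the fit held the model fixed while the
  # profile frees it, the profile baseline can sit above the fit's logLik
  l0 <- prof(clock_fit$par[1])
  se <- NA_real_
  step <- rel_step * h_hat
  for (pass in 1:2) {
    dl <- log1p(step / h_hat)  # symmetric step on the log scale, mapped back
    lp <- prof(clock_fit$par[1] + dl)
    lm <- prof(clock_fit$par[1] - dl)
    hp <- h_hat * exp(dl); hm <- h_hat * exp(-dl)
    # second derivative from 3 unequally spaced points
    d2 <- 2 * (lp * (h_hat - hm) - l0 * (hp - hm) + lm * (hp - h_hat)) /
      ((hp - h_hat) * (h_hat - hm) * (hp - hm))
    if (!is.finite(d2) || d2 >= 0) {
      stop("profile log-likelihood is not concave at the optimum; ",
           "cannot form a root-height standard error (d2 = ", signif(d2, 3), ")")
    }
    se <- 1 / sqrt(-d2)
    step <- max(min(se, 0.5 * h_hat), 1e-3 * h_hat)
  }
  se
}

#' Likelihood-ratio test of the strict molecular clock
#'
#' The no-clock model has `2n - 3` free branch lengths against `n - 1` node
#' heights for the clock, so the statistic `2 * (logL_free - logL_clock)` is
#' referred to a chi-square with `n - 2` degrees of freedom.
#'
#' @param loglik_no_clock,loglik_clock fitted log-likelihoods (nested models,
#'   so the free value may not be below the clock value beyond `tolerance`).
#' @param n_taxa number of taxa in both fits.
#' @param tolerance slack for tiny negative statistics from finite
#'   optimization (clamped to 0).
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' clock_lrt(-29341.106115, -29345.873227, n_taxa = 7)  # p ~ 0.09
#' @export
clock_lrt <- function(loglik_no_clock, loglik_clock, n_taxa,
                      tolerance = 1e-3) {
  stat <- 2 * (loglik_no_clock - loglik_clock)
  if (stat < -tolerance) {
    stop("no-clock log-likelihood below clock log-likelihood (",
         signif(stat, 4), "): an optimization failed")
  }
  stat <- max(stat, 0)
  df <- as.integer(n_taxa) - 2L
  if (df < 1L) stop("need at least 3 taxa")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# ---- marginal ancestral states --------------------------------------------

#' Marginal ancestral-state reconstruction
#'
#' Per internal node and site, the marginal posterior over A/C/G/T given the
#' fitted tree and model (mixing Gamma categories), and the
#' maximum-a-posteriori state (ties broken alphabetically).
#'
#' @param aln alignment.
#' @param tree fitted `phylo` (or fit object) with branch lengths.
#' @param model [tn93_params()] object (taken from a fit object if omitted).
#' @return list: `nodes` (internal node ids), `posterior` (list per node of
#'   4 x sites matrices, columns summing to 1), `map` (node x site character
#'   matrix).
#' @export
ancestral_states <- function(aln, tree, model = NULL) {
  if (is.null(model) && (inherits(tree, "mt_fit") || inherits(tree, "clock_fit"))) {
    model <- tree$model
  }
  phy <- stats::reorder(as_phylo_tree(tree), "postorder")
  aln <- as_alignment(aln)
  pat <- alignment_patterns(aln)
  po <- prep_pruning(pat, phy)
  ntip <- length(phy$tip.label)
  nnode <- max(phy$edge)
  P <- ncol(pat$cube)
  eg <- tn93_eigen(model)
  crates <- discretize_gamma(model$gamma_shape, model$n_categories)$rates
  root <- po$edge[nrow(po$edge), 1]
  internal <- sort(unique(po$edge[, 1]))

  post <- lapply(seq_len(nnode), function(i) matrix(0, 4, P))
  sitelik <- numeric(P)
  for (c in seq_along(crates)) {
    Pm <- lapply(seq_len(nrow(po$edge)), function(e) {
      M <- eg$U %*% (exp(eg$lambda * po$blen[e] * crates[c]) * eg$Uinv)
      M[M < 0] <- 0
      M
    })
    up <- lapply(seq_len(nnode), function(i) matrix(1, 4, P))
    for (i in seq_len(ntip)) up[[i]] <- po$cube[, , i]
    msg <- vector("list", nrow(po$edge))
    for (e in seq_len(nrow(po$edge))) {
      msg[[e]] <- Pm[[e]] %*% up[[po$edge[e, 2]]]
      up[[po$edge[e, 1]]] <- up[[po$edge[e, 1]]] * msg[[e]]
    }
    out <- vector("list", nnode)
    out[[root]] <- matrix(eg$pi, 4, P)
    for (e in rev(seq_len(nrow(po$edge)))) {  # preorder
      par <- po$edge[e, 1]; ch <- po$edge[e, 2]
      if (ch <= ntip) next
      sib <- out[[par]]
      for (e2 in which(po$edge[, 1] == par)) {
        if (e2 != e) sib <- sib * msg[[e2]]
      }
      out[[ch]] <- crossprod(Pm[[e]], sib)
    }
    sitelik <- sitelik + colSums(up[[root]] * eg$pi) / length(crates)
    for (v in internal) {
      post[[v]] <- post[[v]] + (up[[v]] * out[[v]]) / length(crates)
    }
  }
  posterior <- lapply(internal, function(v) {
    p <- post[[v]] / rep(colSums(post[[v]]), each = 4)
    rownames(p) <- DNA_BASES
    p[, pat$site_index, drop = FALSE]
  })
  names(posterior) <- internal
  map <- do.call(rbind, lapply(posterior, function(p) {
    DNA_BASES[apply(p, 2, which.max)]
  }))
  rownames(map) <- internal
  list(nodes = internal, posterior = posterior, map = map)
}
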