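#' Mutation-rate distribution from root height and calibration uncertainty
#'
#' The core of the dating method: lay a 2-D grid over root height `h`
#' (substitutions/site; normal with the fitted mean and standard error,
#' truncated at `max(h_hat - 5 se, eps)`) and calibration date `d` (years;
#' skew-normal), weight each cell by the product of the two densities,
#' compute the implied mutation rate `mu = h / d` per cell, and bin the
#' weighted cells into a normalized discrete rate distribution.
#'
#' @param root_height fitted root height (substitutions/site, > 0).
#' @param root_height_se its standard error (> 0).
#' @param calibration a [fit_skew_normal()] object (dates in years).
#' @param grid list of grid settings: `n_h`, `n_d` (default 400 x 400),
#'   `n_rate` log-spaced rate bins (default 2000), `h_span` (half-width in
#'   SEs, default 5), `d_q` calibration quantile range (default 0.001-0.999).
#' @return a [disc_dist()] over mutation rate (substitutions/site/year).
#' @export
rate_distribution <- function(root_height, root_height_se, calibration,
                              grid = list()) {
  stopifnot(inherits(calibration, "calibration_spec"))
  if (!(root_height > 0) || !(root_height_se > 0)) {
    stop("root height and its SE must be positive")
  }
  g <- utils::modifyList(list(n_h = 400L, n_d = 400L, n_rate = 2000L,
                              h_span = 5, d_q = c(0.001, 0.999)), grid)
  if (g$n_h < 2L || g$n_d < 2L) stop("degenerate grid (need > 1 cell per axis)")
  h <- seq(max(root_height - g$h_span * root_height_se, 1e-12 * root_height),
           root_height + g$h_span * root_height_se, length.out = g$n_h)
  dq <- qskewnorm(g$d_q, calibration$xi, calibration$omega, calibration$a)
  if (dq[1] <= 0) dq[1] <- 1e-6 * dq[2]
  d <- seq(dq[1], dq[2], length.out = g$n_d)
  w_h <- stats::dnorm(h, root_height, root_height_se)
  w_d <- dskewnorm(d, calibration$xi, calibration$omega, calibration$a)
  w <- outer(w_h, w_d)                     # n_h x n_d
  mu <- outer(h, d, "/")
  # log-spaced binning of the weighted (h, d) cells
  lmu <- log(mu)
  br <- seq(min(lmu), max(lmu), length.out = g$n_rate + 1L)
  bin <- findInterval(lmu, br, rightmost.closed = TRUE)
  mass <- vapply(seq_len(g$n_rate), function(i) 0, 0)
  tb <- tapply(as.numeric(w), as.integer(bin), sum)
  mass[as.integer(names(tb))] <- as.numeric(tb)
  mid <- exp((br[-1] + br[-length(br)]) / 2)
  keep <- mass > 0
  disc_dist(mid[keep], mass[keep])
}

#' Divergence-date distribution for one node
#'
#' Propagates a node height through the mutation-rate distribution:
#' `date = node_height / mu` (years) with the rate distribution's masses.
#'
#' @param node_height node height in substitutions/site (>= 0).
#' @param rates a [rate_distribution()] result.
#' @return a [disc_dist()] over age in years.
#' @export
node_date_distribution <- function(node_height, rates) {
  stopifnot(inherits(rates, "disc_dist"))
  if (node_height < 0) stop("node_height must be non-negative")
  if (node_height == 0) return(disc_dist(0, 1))
  disc_dist(node_height / rates$x, rates$p)
}

#' Topology-averaged date distribution
#'
#' Mixes per-topology date distributions for one clade by their (renormalized)
#' topology weights. Topologies in which the queried taxa are not monophyletic
#' contribute through the date of their most recent common ancestor, so every
#' topology supplies a distribution.
#'
#' @param dists named list of [disc_dist()] objects (one per topology).
#' @param weights numeric weights, same names/order; renormalized to sum to 1.
#' @return a [disc_dist()] mixture.
#' @export
combine_topologies <- function(dists, weights) {
  if (length(dists) != length(weights) || length(dists) == 0) {
    stop("need one weight per distribution")
  }
  w <- weights / sum(weights)
  disc_dist(unlist(lapply(dists, `[[`, "x")),
            unlist(mapply(function(d, wi) d$p * wi, dists, w,
                          SIMPLIFY = FALSE)))
}

#' End-to-end divergence-date report
#'
#' For each queried clade: per-topology strict-clock fits of the top-k
#' topologies, a mutation-rate distribution per topology (root height +/- SE
#' times the calibration density), node-date distributions from the clade's
#' MRCA height, and the bp-RELL-weighted mixture across topologies. Reports
#' the best-topology date and the topology-averaged date, each with an
#' equal-tail 95% interval.
#'
#' @param aln alignment.
#' @param topologies named `multiPhylo` of candidate topologies (unrooted).
#' @param weights a [bp_rell()] result over those topologies.
#' @param calibration a [fit_skew_normal()] object (years).
#' @param clades named list of character vectors (taxon labels per query).
#' @param outgroup character vector used to root each topology; topologies in
#'   which it is not monophyletic are dropped (with a message) before dating.
#' @param top_k number of topologies mixed (default 10).
#' @param model optional fixed [tn93_params()]; default refits per topology.
#' @param grid passed to [rate_distribution()].
#' @param control optimizer control forwarded to [fit_strict_clock()].
#' @return object of class `date_report`: `summary` data.frame (clade,
#'   best_date, best_lo, best_hi, avg_date, avg_lo, avg_hi, in years),
#'   `distributions` (per clade: `best`, `averaged`, and per-topology list),
#'   `clock_fits`, `used_weights`.
#' @export
date_report <- function(aln, topologies, weights, calibration, clades,
                        outgroup, top_k = 10L, model = NULL, grid = list(),
                        control = list()) {
  stopifnot(inherits(calibration, "calibration_spec"))
  aln <- as_alignment(aln)
  top <- top_k_mass(weights, min(top_k, nrow(weights)))
  ids <- top$topology_ids
  rootable <- vapply(topologies[ids], has_clade, TRUE, clade = outgroup)
  if (!all(rootable)) {
    message(sum(!rootable), " of top-", length(ids),
            " topologies drop out (outgroup not monophyletic)")
    ids <- ids[rootable]
  }
  if (!length(ids)) stop("no rootable topology among the top-k")
  w <- weights$weight[match(ids, weights$topology_id)]
  w <- w / sum(w)

  clock_fits <- lapply(ids, function(id) {
    rooted <- root_with_outgroup(topologies[[id]], outgroup)
    fit_strict_clock(aln, rooted, model = model,
                     optimize_model = is.null(model), compute_se = TRUE,
                     control = control)
  })
  names(clock_fits) <- ids
  rate_dists <- lapply(clock_fits, function(f) {
    rate_distribution(f$root_height, f$root_height_se, calibration, grid)
  })

  per_clade <- lapply(clades, function(taxa) {
    dd <- mapply(function(f, rd) {
      node <- if (length(taxa) == 1L) {
        match(taxa, f$tree$tip.label)
      } else {
        ape::getMRCA(f$tree, taxa)
      }
      node_date_distribution(f$heights[node], rd)
    }, clock_fits, rate_dists, SIMPLIFY = FALSE)
    list(best = dd[[1]], averaged = combine_topologies(dd, w),
         per_topology = dd)
  })
  qs <- function(d) dist_quantile(d, c(0.5, 0.025, 0.975))
  summ <- do.call(rbind, lapply(names(per_clade), function(nm) {
    b <- qs(per_clade[[nm]]$best); a <- qs(per_clade[[nm]]$averaged)
    data.frame(clade = nm, best_date = b[1], best_lo = b[2], best_hi = b[3],
               avg_date = a[1], avg_lo = a[2], avg_hi = a[3])
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, distributions = per_clade,
                 clock_fits = clock_fits, used_weights =
                   stats::setNames(w, ids)),
            class = "date_report")
}

#' @export
print.date_report <- function(x, ...) {
  s <- x$summary
  cat("divergence-date report (ky, median [95% equal-tail]):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-24s best %.1f [%.1f-%.1f]  averaged %.1f [%.1f-%.1f]\n",
                s$clade[i], s$best_date[i] / 1e3, s$best_lo[i] / 1e3,
                s$best_hi[i] / 1e3, s$avg_date[i] / 1e3, s$avg_lo[i] / 1e3,
                s$avg_hi[i] / 1e3))
  }
  invisible(x)
}
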