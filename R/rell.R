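#' Per-site log-likelihood matrix across candidate topologies
#'
#' Stacks the `site_log_likelihoods` of a list of fits into the
#' topologies x sites matrix consumed by [bp_rell()]. Row names are the
#' topology ids (names of `fits`, or canonical keys of the fitted trees).
#'
#' @param fits list of [fit_no_clock()] / [fit_strict_clock()] results.
#' @return numeric matrix, rows = topologies, columns = sites.
#' @export
site_loglik_matrix <- function(fits) {
  m <- do.call(rbind, lapply(fits, `[[`, "site_log_likelihoods"))
  ids <- names(fits)
  if (is.null(ids)) {
    ids <- vapply(fits, function(f) topology_key(f$tree), "")
  }
  rownames(m) <- ids
  m
}

#' bp-RELL topology weights
#'
#' Bootstrap proportions by Resampling Estimated Log-Likelihoods (Kishino et
#' al.): sites are resampled with replacement `n_bootstrap` times, each
#' replicate's winner is the topology with the highest resampled total
#' log-likelihood (exact ties split equally), and a topology's weight is its
#' share of wins. These are the "posterior weights" used to mix divergence
#' dates across topologies; they are bootstrap proportions, not Bayesian
#' posteriors.
#'
#' @param matrix topologies x sites matrix of per-site log-likelihoods
#'   (e.g. from [site_loglik_matrix()]); row names are topology ids.
#' @param n_bootstrap number of bootstrap replicates (default 10000).
#' @param seed mandatory RNG seed; identical seeds give identical weights.
#' @return object of class `rell_weights`: data.frame with `topology_id`,
#'   `weight`, plus attributes `n_bootstrap` and `seed`.
#' @export
bp_rell <- function(matrix, n_bootstrap = 10000L, seed) {
  if (missing(seed)) stop("bp_rell requires an explicit seed")
  if (!is.matrix(matrix) || nrow(matrix) < 1L || ncol(matrix) < 1L) {
    stop("need a non-empty topologies x sites matrix")
  }
  if (anyNA(matrix)) stop("NA/NaN entries in site log-likelihood matrix")
  n_bootstrap <- as.integer(n_bootstrap)
  if (n_bootstrap < 1L) stop("n_bootstrap must be >= 1")
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(matrix)))
  S <- ncol(matrix)
  wins <- numeric(nrow(matrix))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  done <- 0L
  chunk <- max(1L, min(n_bootstrap, as.integer(2e7 / S)))
  while (done < n_bootstrap) {
    b <- min(chunk, n_bootstrap - done)
    counts <- stats::rmultinom(b, S, rep(1 / S, S))
    totals <- matrix %*% counts                      # topologies x b
    mx <- apply(totals, 2, max)
    # ties at a tiny relative tolerance so equal-likelihood topologies split
    # the win regardless of floating-point summation order
    tol <- pmax(1e-9, 1e-12 * abs(mx))
    tie <- totals >= rep(mx - tol, each = nrow(totals))
    wins <- wins + rowSums(tie / rep(colSums(tie), each = nrow(tie)))
    done <- done + b
  }
  structure(data.frame(topology_id = ids, weight = wins / n_bootstrap,
                       stringsAsFactors = FALSE),
            n_bootstrap = n_bootstrap, seed = seed,
            class = c("rell_weights", "data.frame"))
}

#' Top-k topologies and their cumulative weight
#'
#' @param weights a [bp_rell()] result (or data.frame with `topology_id`,
#'   `weight`).
#' @param k how many topologies to keep (descending weight, ties broken by
#'   topology id).
#' @return list with `topology_ids` (length k) and `mass` (summed weight).
#' @export
top_k_mass <- function(weights, k) {
  k <- as.integer(k)
  if (k < 1L || k > nrow(weights)) stop("k out of range")
  ord <- order(-weights$weight, weights$topology_id)
  ids <- weights$topology_id[ord][seq_len(k)]
  list(topology_ids = ids, mass = sum(weights$weight[ord][seq_len(k)]))
}

#' Aggregate support for a clade across weighted topologies
#'
#' Sums the weights of all topologies that contain the clade as a bipartition.
#'
#' @param weights a [bp_rell()] result.
#' @param topologies named `multiPhylo`/list of `phylo`; names must match
#'   `weights$topology_id`.
#' @param clade character vector of tip labels.
#' @return probability in `[0, 1]`.
#' @export
clade_support <- function(weights, topologies, clade) {
  idx <- match(weights$topology_id, names(topologies))
  if (anyNA(idx)) stop("weights refer to topologies not supplied")
  has <- vapply(topologies[idx], has_clade, TRUE, clade = clade)
  sum(weights$weight[has])
}

#' Write / read topology weights as TSV
#'
#' Columns: topology_id, weight, rank (descending weight).
#'
#' @param weights a [bp_rell()] result.
#' @param path file path.
#' @param header_lines optional comment lines (prefixed `#`) for provenance.
#' @return `path` invisibly / a data.frame.
#' @export
write_weights <- function(weights, path, header_lines = character(0)) {
  ord <- order(-weights$weight, weights$topology_id)
  out <- data.frame(topology_id = weights$topology_id[ord],
                    weight = weights$weight[ord],
                    rank = seq_along(ord))
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(colnames(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(out, format_plain), sep = "\t")), con)
  invisible(path)
}

format_plain <- function(x) {
  if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
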