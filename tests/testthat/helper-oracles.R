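# Independent oracles used across the suite. These deliberately avoid the
# package's eigendecomposition/pruning code paths: matrix exponentials come
# from scaling-and-squaring Taylor series, likelihoods from explicit sums
# over internal-node state assignments.

expm_taylor <- function(A, t) {
  B <- A * t
  s <- max(0L, ceiling(log2(max(1, max(abs(B))))) + 4L)
  B <- B / 2^s
  P <- diag(4)
  term <- diag(4)
  for (k in 1:25) {
    term <- term %*% B / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# site log-likelihoods by exhaustive enumeration of internal states
exhaustive_site_loglik <- function(aln, phy, model) {
  aln <- as_alignment(aln)
  phy <- stats::reorder(phy, "postorder")
  iup <- mitodate:::iupac_partials
  g <- discretize_gamma(model$gamma_shape, model$n_categories)
  Q <- build_rate_matrix(model)
  pi <- model$base_freqs
  edges <- phy$edge
  ntip <- length(phy$tip.label)
  internals <- sort(unique(edges[, 1]))
  root <- edges[nrow(edges), 1]
  k <- length(internals)
  node_pos <- match(internals, internals)
  seqm <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(seqm) <- aln$taxa
  seqm <- seqm[phy$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:4), k)))
  vapply(seq_len(aln$length), function(s) {
    tot <- 0
    for (ci in seq_along(g$rates)) {
      Ps <- lapply(seq_len(nrow(edges)), function(e) {
        expm_taylor(Q, phy$edge.length[e] * g$rates[ci])
      })
      for (a in seq_len(nrow(grid))) {
        st <- grid[a, ]
        pr <- pi[st[match(root, internals)]]
        for (e in seq_len(nrow(edges))) {
          par_state <- st[match(edges[e, 1], internals)]
          ch <- edges[e, 2]
          pr <- pr * if (ch <= ntip) {
            sum(Ps[[e]][par_state, ] * iup[, seqm[ch, s]])
          } else {
            Ps[[e]][par_state, st[match(ch, internals)]]
          }
        }
        tot <- tot + pr * g$probs[ci]
      }
    }
    log(tot)
  }, 0)
}

jc_model <- function(n_categories = 1L, gamma_shape = 1) {
  tn93_params(rep(0.25, 4), 1, 1, 1, gamma_shape = gamma_shape,
              n_categories = n_categories)
}

random_tn93 <- function(seed) {
  set.seed(seed)
  f <- stats::runif(4, 0.5, 2)
  tn93_params(f / sum(f), stats::runif(1, 0.5, 20), stats::runif(1, 0.5, 20),
              gamma_shape = stats::runif(1, 0.2, 2), n_categories = 5L)
}

# random alignment over ACGT plus occasional ambiguity/missing symbols
random_alignment <- function(taxa, n_sites, seed, p_missing = 0.1) {
  set.seed(seed)
  symbols <- c("A", "C", "G", "T")
  extra <- c("N", "-", "R", "Y", "M")
  seqs <- vapply(taxa, function(i) {
    s <- sample(symbols, n_sites, replace = TRUE)
    miss <- stats::runif(n_sites) < p_missing
    s[miss] <- sample(extra, sum(miss), replace = TRUE)
    paste0(s, collapse = "")
  }, "")
  as_alignment(seqs)
}

cheetah_taxa <- c("Puma", "Jaguarundi", "NEAfrica", "India", "SEAfrica_ref",
                  "SEAfrica_hist", "SEAfrica_mod")
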