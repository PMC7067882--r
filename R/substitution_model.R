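#' TN93 + discrete-Gamma substitution model parameters
#'
#' Constructs and validates the parameter set of the Tamura–Nei (1993)
#' nucleotide substitution model with discrete-Gamma rate heterogeneity:
#' stationary base frequencies, separate purine (A<->G) and pyrimidine (C<->T)
#' transition rates, a shared transversion rate, and a Gamma shape parameter
#' discretized into `n_categories` equal-probability rate classes. Rates are
#' stored relative to the transversion rate; only the normalized rate matrix
#' (mean substitution rate 1 at stationarity) is ever exposed.
#'
#' @param base_freqs numeric(4), stationary frequencies in A, C, G, T order;
#'   must be positive and sum to 1 (renormalized if within 1e-8).
#' @param rate_AG purine transition rate (relative to transversions).
#' @param rate_CT pyrimidine transition rate (relative to transversions).
#' @param rate_transversion shared transversion rate (usually 1).
#' @param gamma_shape positive Gamma shape (alpha); smaller means stronger
#'   among-site rate heterogeneity.
#' @param n_categories number of discrete Gamma categories (default 5).
#' @return an object of class `tn93g`.
#' @examples
#' m <- tn93_params(c(.31, .26, .13, .30), rate_AG = 30, rate_CT = 16,
#'                  gamma_shape = 0.3)
#' build_rate_matrix(m)
#' @export
tn93_params <- function(base_freqs, rate_AG, rate_CT, rate_transversion = 1,
                        gamma_shape = 1, n_categories = 5L) {
  base_freqs <- as.numeric(base_freqs)
  if (length(base_freqs) != 4L || any(!is.finite(base_freqs)) ||
      any(base_freqs <= 0)) {
    stop("base_freqs must be 4 positive finite values (A, C, G, T)")
  }
  if (abs(sum(base_freqs) - 1) > 1e-8) {
    stop("base_freqs must sum to 1")
  }
  base_freqs <- base_freqs / sum(base_freqs)
  rates <- c(rate_AG = rate_AG, rate_CT = rate_CT,
             rate_transversion = rate_transversion)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("substitution rates must be positive and finite")
  }
  if (!is.finite(gamma_shape) || gamma_shape <= 0) {
    stop("gamma_shape must be positive")
  }
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 1L) {
    stop("n_categories must be a positive integer")
  }
  structure(list(base_freqs = stats::setNames(base_freqs, DNA_BASES),
                 rate_AG = rate_AG / rate_transversion,
                 rate_CT = rate_CT / rate_transversion,
                 rate_transversion = 1,
                 gamma_shape = gamma_shape,
                 n_categories = n_categories),
            class = "tn93g")
}

#' @export
print.tn93g <- function(x, ...) {
  cat("TN93 + G", x$n_categories, " substitution model\n", sep = "")
  cat("  base freqs (ACGT):", sprintf("%.4f", x$base_freqs), "\n")
  cat("  rates AG/CT/tv:", sprintf("%.4g", c(x$rate_AG, x$rate_CT, 1)), "\n")
  cat("  gamma shape:", sprintf("%.4g", x$gamma_shape), "\n")
  invisible(x)
}

#' Normalized TN93 instantaneous rate matrix
#'
#' Builds the 4x4 generator Q of the TN93 model: `Q[i, j] = s[i, j] * pi[j]`
#' for `i != j`, where `s` is the purine-transition, pyrimidine-transition or
#' transversion rate as appropriate, diagonals make rows sum to zero, and the
#' whole matrix is rescaled so the mean substitution rate at stationarity,
#' `-sum(pi * diag(Q))`, equals 1 (branch lengths are then expected
#' substitutions per site). The model is time-reversible: `pi[i] * Q[i, j] =
#' pi[j] * Q[j, i]`.
#'
#' @param params a [tn93_params()] object.
#' @return 4x4 numeric matrix with dimnames A, C, G, T.
#' @export
build_rate_matrix <- function(params) {
  stopifnot(inherits(params, "tn93g"))
  pi <- params$base_freqs
  s <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  s["A", "G"] <- s["G", "A"] <- params$rate_AG
  s["C", "T"] <- s["T", "C"] <- params$rate_CT
  Q <- s * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  beta <- -sum(pi * diag(Q))
  if (!is.finite(beta) || beta <= 0) stop("rate matrix is not normalizable")
  Q / beta
}

#' Discrete-Gamma rate categories (Yang 1994)
#'
#' Splits a Gamma(shape, rate = shape) distribution (mean 1) into `n`
#' equal-probability bands and represents each band by its conditional mean.
#' The category rates therefore average exactly 1.
#'
#' @param shape positive Gamma shape (alpha).
#' @param n_categories number of categories.
#' @return list with `rates` (length n, mean 1) and `probs` (all `1/n`).
#' @export
discretize_gamma <- function(shape, n_categories) {
  if (!is.finite(shape) || shape <= 0) stop("gamma shape must be positive")
  n <- as.integer(n_categories)
  if (is.na(n) || n < 1L) stop("n_categories must be a positive integer")
  if (n == 1L) return(list(rates = 1, probs = 1))
  breaks <- stats::qgamma(seq(0, 1, length.out = n + 1), shape, rate = shape)
  # E[X | a < X < b] * P(a < X < b) = pgamma(b, shape+1) - pgamma(a, shape+1)
  # for Gamma(shape, rate = shape), whose mean is 1
  cum <- stats::pgamma(breaks, shape + 1, rate = shape)
  rates <- n * diff(cum)
  list(rates = rates, probs = rep(1 / n, n))
}

# Eigendecomposition of the reversible generator via the symmetrized form
# diag(sqrt(pi)) Q diag(1/sqrt(pi)); exact and stable for 4x4.
tn93_eigen <- function(params) {
  Q <- build_rate_matrix(params)
  pi <- params$base_freqs
  sp <- sqrt(pi)
  B <- (Q * rep(sp, 4)) * rep(1 / sp, each = 4)  # diag(sp) %*% Q %*% diag(1/sp)
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  list(U = es$vectors / sp, lambda = es$values, Uinv = t(es$vectors) * rep(sp, each = 4),
       pi = pi, Q = Q)
}

#' Transition probability matrices per Gamma category
#'
#' Computes `P(t) = exp(Q * t * r_c)` for each discrete-Gamma category rate
#' `r_c`, via eigendecomposition of the reversible generator.
#'
#' @param params a [tn93_params()] object.
#' @param branch_length expected substitutions per site (>= 0).
#' @return list of `n_categories` row-stochastic 4x4 matrices.
#' @export
transition_probabilities <- function(params, branch_length) {
  stopifnot(inherits(params, "tn93g"))
  if (!is.finite(branch_length) || branch_length < 0) {
    stop("branch_length must be non-negative")
  }
  eg <- tn93_eigen(params)
  rates <- discretize_gamma(params$gamma_shape, params$n_categories)$rates
  lapply(rates, function(r) {
    P <- eg$U %*% (exp(eg$lambda * branch_length * r) * eg$Uinv)
    P[P < 0] <- 0
    P <- P / rowSums(P)
    dimnames(P) <- list(DNA_BASES, DNA_BASES)
    P
  })
}

#' Serialize / parse model parameters as a key-value config block
#'
#' @param params a [tn93_params()] object.
#' @return `model_to_config()`: a plain named list (JSON-ready);
#'   `model_from_config()`: a `tn93g` object.
#' @export
model_to_config <- function(params) {
  stopifnot(inherits(params, "tn93g"))
  list(base_freqs = unname(params$base_freqs), rate_AG = params$rate_AG,
       rate_CT = params$rate_CT, rate_transversion = 1,
       gamma_shape = params$gamma_shape, n_categories = params$n_categories)
}

#' @rdname model_to_config
#' @param config named list as produced by `model_to_config()`.
#' @export
model_from_config <- function(config) {
  tn93_params(config$base_freqs, config$rate_AG, config$rate_CT,
              config$rate_transversion %||% 1, config$gamma_shape,
              config$n_categories %||% 5L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
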