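# GTR-family substitution models with discrete-Gamma rate heterogeneity.
#
# Bases are ordered A, C, G, T. Exchangeabilities are ordered
# AC, AG, AT, CG, CT, GT with GT fixed to 1. The rate matrix Q is scaled so
# the expected number of substitutions per unit branch length is 1; with
# Gamma heterogeneity the discrete category rates (quantile midpoints of a
# mean-1 Gamma with shape alpha) are renormalized to average 1.

.bases <- c("A", "C", "G", "T")
.rate_names <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Construct a substitution model
#'
#' @param family One of `"JC69"`, `"K80"`, `"HKY85"`, `"GTR"`. Constrained
#'   families overwrite `rates`/`freqs` as needed: JC69 and K80 force equal
#'   base frequencies; JC69 forces all rates equal; K80 and HKY85 use a
#'   single transition/transversion ratio `kappa`.
#' @param rates Six exchangeabilities (AC, AG, AT, CG, CT, GT); GT is
#'   rescaled to 1.
#' @param freqs Base frequencies (A, C, G, T); normalized to sum to 1.
#' @param kappa Transition/transversion ratio for K80/HKY85.
#' @param alpha Gamma shape for among-site rate variation, or `NULL` for
#'   rate homogeneity.
#' @param ncat Number of discrete Gamma categories (default 4).
#' @return A `sub_model` object with cached eigendecomposition of Q.
#' @export
sub_model <- function(family = c("GTR", "JC69", "K80", "HKY85"),
                      rates = rep(1, 6), freqs = rep(0.25, 4),
                      kappa = NULL, alpha = NULL, ncat = 4L) {
  family <- match.arg(family)
  rates <- as.numeric(rates)
  freqs <- as.numeric(freqs)
  if (family %in% c("K80", "HKY85")) {
    k <- kappa %||% rates[2L]
    rates <- c(1, k, 1, 1, k, 1)
  }
  if (family == "JC69") rates <- rep(1, 6)
  if (family %in% c("JC69", "K80")) freqs <- rep(0.25, 4)
  if (any(rates < 0) || any(freqs <= 0)) stop2("Rates must be >= 0 and frequencies > 0")
  rates <- rates / rates[6L]
  freqs <- freqs / sum(freqs)
  if (!is.null(alpha) && alpha <= 0) stop2("Gamma shape must be > 0")

  m <- structure(list(family = family, rates = setNames(rates, .rate_names),
                      freqs = setNames(freqs, .bases), alpha = alpha,
                      ncat = as.integer(ncat)),
                 class = "sub_model")
  m$eig <- .q_eigen(rates, freqs)
  m$free_parameter_count <- switch(family, JC69 = 0L, K80 = 1L,
                                   HKY85 = 4L, GTR = 8L) +
    (!is.null(alpha))
  m
}

# Build the scaled reversible Q and its symmetric eigendecomposition.
.q_eigen <- function(rates, freqs) {
  R <- matrix(0, 4, 4, dimnames = list(.bases, .bases))
  R[1, 2] <- R[2, 1] <- rates[1]; R[1, 3] <- R[3, 1] <- rates[2]
  R[1, 4] <- R[4, 1] <- rates[3]; R[2, 3] <- R[3, 2] <- rates[4]
  R[2, 4] <- R[4, 2] <- rates[5]; R[3, 4] <- R[4, 3] <- rates[6]
  Q <- R %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / d) %*% e$vectors,
       left = t(e$vectors) %*% diag(d),
       Q = Q)
}

#' Discrete-Gamma category rates
#'
#' Equiprobable categories with rates at the quantile midpoints of a
#' Gamma(shape = alpha, rate = alpha) distribution, renormalized to mean 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param ncat Number of categories.
#' @return Numeric vector of `ncat` rates averaging 1.
#' @export
gamma_rates <- function(alpha, ncat = 4L) {
  if (is.null(alpha)) return(1)
  p <- (2 * seq_len(ncat) - 1) / (2 * ncat)
  r <- qgamma(p, shape = alpha, rate = alpha)
  r / mean(r)
}

#' Transition probability matrix P(t)
#'
#' Computed from the cached eigendecomposition of the scaled reversible Q;
#' `rate` multiplies the branch length (Gamma category or partition rate
#' multiplier).
#'
#' @param model A `sub_model`.
#' @param t Branch length in expected substitutions/site (>= 0).
#' @param rate Rate multiplier (default 1).
#' @return A 4x4 row-stochastic matrix over A, C, G, T.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (!is.finite(t) || t < 0) stop2("Branch length must be finite and >= 0")
  e <- model$eig
  P <- e$right %*% (exp(e$values * t * rate) * e$left)
  P[P < 0] <- 0
  dimnames(P) <- list(.bases, .bases)
  P
}
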