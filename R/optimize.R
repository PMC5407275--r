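# Parameter optimization and BIC model/partition selection.
#
# Optimization is coordinate ascent: Brent line searches on each branch
# length (bounds 1e-8 .. 10) alternating with Nelder-Mead over the model
# parameters in unconstrained space (log exchangeabilities, log-ratio
# frequencies, log Gamma shape, log subset rate multipliers renormalized to
# weighted mean 1), until the round improves lnL by < `tol` or `max_rounds`
# is hit.

.bl_min <- 1e-8
.bl_max <- 10

lnL_po <- function(tree_po, lik_data, scheme) {
  total <- 0
  for (s in seq_along(lik_data)) {
    total <- total + .partition_loglik(tree_po, lik_data[[s]],
                                       scheme$models[[s]],
                                       scheme$rate_multipliers[s])
  }
  total
}

as_postorder <- function(tree) {
  tr <- if (length(tree$tip.label) > 2L) ape::unroot(tree) else tree
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  ape::reorder.phylo(tr, "postorder")
}

optimize_blens_po <- function(tree_po, lik_data, scheme, rounds = 2L,
                              edges = NULL, tol = 1e-4) {
  ek <- edges %||% seq_len(nrow(tree_po$edge))
  for (r in seq_len(rounds)) {
    for (k in ek) {
      f <- function(x) {
        tree_po$edge.length[k] <- x
        -lnL_po(tree_po, lik_data, scheme)
      }
      opt <- stats::optimize(f, interval = c(.bl_min, .bl_max), tol = tol)
      tree_po$edge.length[k] <- opt$minimum
    }
  }
  tree_po
}

# ---- model-parameter packing ----------------------------------------------

pack_model <- function(m) {
  th <- numeric(0)
  if (m$family == "K80") th <- c(th, log(m$rates[2L]))
  if (m$family == "HKY85") th <- c(th, log(m$rates[2L]),
                                   log(m$freqs[1:3] / m$freqs[4L]))
  if (m$family == "GTR") th <- c(th, log(m$rates[1:5]),
                                 log(m$freqs[1:3] / m$freqs[4L]))
  if (!is.null(m$alpha)) th <- c(th, log(m$alpha))
  th
}

unpack_model <- function(m, th) {
  i <- 0L
  rates <- m$rates; freqs <- m$freqs; kappa <- NULL
  if (m$family == "K80") { kappa <- exp(th[1L]); i <- 1L }
  if (m$family == "HKY85") {
    kappa <- exp(th[1L])
    e <- exp(th[2:4]); freqs <- c(e, 1) / (sum(e) + 1)
    i <- 4L
  }
  if (m$family == "GTR") {
    rates <- c(exp(th[1:5]), 1)
    e <- exp(th[6:8]); freqs <- c(e, 1) / (sum(e) + 1)
    i <- 8L
  }
  alpha <- NULL
  if (!is.null(m$alpha)) {
    alpha <- min(max(exp(th[i + 1L]), 0.05), 50)
  }
  sub_model(m$family, rates = rates, freqs = freqs, kappa = kappa,
            alpha = alpha, ncat = m$ncat)
}

pack_scheme <- function(scheme) {
  th <- unlist(lapply(scheme$models, pack_model), use.names = FALSE)
  if (length(scheme$subsets) > 1L) {
    th <- c(th, log(scheme$rate_multipliers[-1L] /
                    scheme$rate_multipliers[1L]))
  }
  th
}

unpack_scheme <- function(scheme, th) {
  i <- 0L
  for (s in seq_along(scheme$models)) {
    np <- length(pack_model(scheme$models[[s]]))
    scheme$models[[s]] <- unpack_model(scheme$models[[s]],
                                       th[i + seq_len(np)])
    i <- i + np
  }
  if (length(scheme$subsets) > 1L) {
    rel <- c(1, exp(th[i + seq_len(length(scheme$subsets) - 1L)]))
    scheme$rate_multipliers <- normalize_multipliers(rel,
                                                     lengths(scheme$subsets))
  }
  scheme
}

#' Number of free parameters of a partitioned fit
#'
#' Counts branch lengths (2n - 3), per-subset substitution-model parameters
#' (JC69: 0, K80: 1, HKY85: 4, GTR: 8; +1 for a Gamma shape) and the free
#' subset rate multipliers (number of subsets - 1).
#'
#' @param scheme A `partition_scheme`.
#' @param n_tips Number of alignment rows.
#' @return Integer parameter count.
#' @export
count_parameters <- function(scheme, n_tips) {
  blens <- if (n_tips > 2L) 2L * n_tips - 3L else 1L
  blens + sum(vapply(scheme$models, function(m) m$free_parameter_count,
                     integer(1L))) + (length(scheme$subsets) - 1L)
}

#' Bayesian Information Criterion
#' @param lnL Log-likelihood.
#' @param k Free parameter count.
#' @param n Sample size (alignment columns).
#' @return `k * ln(n) - 2 * lnL`.
#' @export
bic_score <- function(lnL, k, n) k * log(n) - 2 * lnL

#' Optimize branch lengths and/or model parameters
#'
#' @param tree A `phylo` starting tree.
#' @param scheme A `partition_scheme` with starting models.
#' @param matrix An `aligned_matrix`.
#' @param what `"branch_lengths"`, `"model"`, or `"both"`.
#' @param tol Convergence tolerance on lnL improvement per round.
#' @param max_rounds Maximum coordinate-ascent rounds.
#' @return A `model_fit`: list with `tree` (optimized branch lengths),
#'   `scheme`, `logLik`, `k`, `n`, `bic`, `converged`.
#' @export
optimize_fit <- function(tree, scheme, matrix,
                         what = c("both", "branch_lengths", "model"),
                         tol = 1e-6, max_rounds = 200L) {
  what <- match.arg(what)
  lik_data <- make_lik_data(matrix, scheme)
  tree_po <- as_postorder(tree)
  cur <- lnL_po(tree_po, lik_data, scheme)
  start_lnL <- cur
  converged <- FALSE
  for (r in seq_len(max_rounds)) {
    if (what %in% c("both", "branch_lengths")) {
      tree_po <- optimize_blens_po(tree_po, lik_data, scheme,
                                   rounds = 1L)
    }
    if (what %in% c("both", "model")) {
      th0 <- pack_scheme(scheme)
      if (length(th0)) {
        obj <- function(th) {
          sc <- try(unpack_scheme(scheme, th), silent = TRUE)
          if (inherits(sc, "try-error")) return(1e10)
          -lnL_po(tree_po, lik_data, sc)
        }
        op <- if (length(th0) == 1L) {
          optim(th0, obj, method = "Brent", lower = th0 - 8, upper = th0 + 8)
        } else {
          optim(th0, obj, method = "Nelder-Mead",
                control = list(maxit = 500L))
        }
        scheme <- unpack_scheme(scheme, op$par)
      }
    }
    new <- lnL_po(tree_po, lik_data, scheme)
    if (new - cur < tol) { cur <- max(new, cur); converged <- TRUE; break }
    cur <- new
  }
  k <- count_parameters(scheme, length(tree_po$tip.label))
  n <- if (inherits(matrix, "aligned_matrix")) matrix$length else
    sum(vapply(lik_data, function(p) sum(p$counts), numeric(1L)))
  structure(list(tree = tree_po, scheme = scheme, logLik = cur,
                 start_logLik = start_lnL, k = k, n = n,
                 bic = bic_score(cur, k, n), converged = converged,
                 rounds = r),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: lnL = %.4f, k = %d, n = %d, BIC = %.2f (%s)\n",
              x$logLik, x$k, x$n, x$bic,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Select a substitution model and partition scheme by BIC
#'
#' Fits every candidate in the grid {unpartitioned, by codon position} x
#' {JC69, K80, HKY85, GTR} x {without Gamma, with Gamma} on the fixed tree
#' topology (branch lengths and model parameters optimized per candidate)
#' and returns the minimum-BIC fit along with the full score table.
#'
#' @param matrix An `aligned_matrix`.
#' @param tree A fixed `phylo` topology.
#' @param families Candidate model families.
#' @param schemes Candidate partition schemes.
#' @param gamma Candidate Gamma settings.
#' @param max_rounds Optimization rounds per candidate.
#' @return List with `best` (a `model_fit`) and `table` (data frame of
#'   scheme, family, gamma, lnL, k, n, BIC, sorted by BIC).
#' @export
select_model <- function(matrix, tree,
                         families = c("JC69", "K80", "HKY85", "GTR"),
                         schemes = c("none", "codon"),
                         gamma = c(FALSE, TRUE), max_rounds = 20L) {
  rows <- list(); fits <- list()
  for (sc in schemes) {
    for (fam in families) {
      for (g in gamma) {
        model <- sub_model(fam, freqs = empirical_freqs(matrix),
                           alpha = if (g) 1 else NULL)
        part <- partition_scheme(matrix, sc, model = model)
        fit <- optimize_fit(tree, part, matrix, "both",
                            max_rounds = max_rounds)
        tag <- paste0(sc, "/", fam, if (g) "+G" else "")
        fits[[tag]] <- fit
        rows[[tag]] <- data.frame(scheme = sc, family = fam, gamma = g,
                                  lnL = fit$logLik, k = fit$k, n = fit$n,
                                  bic = fit$bic, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$bic), ]
  list(best = fits[[rownames(tab)[1L]]], table = tab)
}
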