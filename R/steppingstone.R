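# Stepping-stone marginal-likelihood estimation and Bayes-factor tests.
#
# The power ladder runs from beta = 1 (posterior) down to beta = 0 (prior)
# at the quantiles of a Beta(0.3, 1) distribution, the standard choice that
# concentrates steps near the prior where the integrand changes fastest.
# Writing b_0 = 1 > b_1 > ... > b_K = 0, each ratio z(b_{j-1}) / z(b_j) is
# estimated from samples drawn at the LOWER power b_j via
#   log r_j = logmeanexp( (b_{j-1} - b_j) * logL_i ),
# and the marginal log-likelihood is the telescoping sum of the log ratios
# (the prior is proper, so z(0) = 1). Independent runs give a Monte Carlo
# standard error from the across-run dispersion.

#' Power ladder for stepping-stone sampling
#' @param K Number of steps (>= 2).
#' @param shape Beta-distribution shape (default 0.3).
#' @return Decreasing vector `b_0 = 1, ..., b_K = 0` of length `K + 1`.
#' @export
ss_powers <- function(K, shape = 0.3) {
  stopifnot(K >= 2L)
  (seq(K, 0) / K)^(1 / shape)
}

# Generic single-run stepping-stone pass over a user-supplied sampler.
# `sample_at(beta, state, n)` must return list(state, logLik = numeric(n'))
# with samples drawn from prior x likelihood^beta starting at `state`.
.ss_one_run <- function(sample_at, init_state, powers, gens_per_step,
                        discard_first = TRUE, step_burn_fraction = 0.25) {
  state <- init_state
  if (discard_first) {
    # initial sampling at beta = 1, discarded as burn-in
    state <- sample_at(powers[1L], state, gens_per_step)$state
  }
  K <- length(powers) - 1L
  step_log_ratio <- numeric(K)
  step_mean_logL <- numeric(K)
  for (j in seq_len(K)) {
    b_hi <- powers[j]; b_lo <- powers[j + 1L]
    res <- sample_at(b_lo, state, gens_per_step)
    state <- res$state
    ll <- res$logLik
    # drop the leading samples of each step: the chain arrives from the
    # previous (higher) power and needs to re-equilibrate
    ll <- ll[-seq_len(floor(step_burn_fraction * length(ll)))]
    step_log_ratio[j] <- logsumexp((b_hi - b_lo) * ll) - log(length(ll))
    step_mean_logL[j] <- mean(ll)
  }
  list(marginal_lnL = sum(step_log_ratio), step_log_ratio = step_log_ratio,
       step_mean_logL = step_mean_logL)
}

#' Stepping-stone estimate of the marginal log-likelihood
#'
#' Runs the constrained tree MCMC at each power of the ladder, annealing
#' from the posterior toward the prior; the first step (at beta = 1) is
#' discarded as burn-in. With `config$n_runs` independent runs the estimate
#' is the mean of the per-run estimates and `mc_error` their standard error.
#'
#' @param matrix An `aligned_matrix`.
#' @param scheme A `partition_scheme` (starting model; parameters are
#'   sampled if `update` includes `"model"`).
#' @param config An `mcmc_config`; `generations` is interpreted as
#'   generations per step.
#' @param constraint A `topology_constraint` or `NULL`.
#' @param K Number of stepping stones (default 10 at desk scale; the
#'   published-analysis scale is 50).
#' @param update Which state blocks to sample (see [mcmc_sample()]).
#' @param start_tree Optional starting `phylo` (e.g. with fixed branch
#'   lengths when `update` excludes `"blens"`).
#' @return A `stepping_stone_run`: `marginal_lnL`, `mc_error`, `powers`,
#'   `per_run` (per-run estimates), `step_mean_logL`.
#' @export
stepping_stone <- function(matrix, scheme, config, constraint = NULL,
                           K = 10L,
                           update = c("topology", "blens", "model"),
                           start_tree = NULL) {
  ctx <- make_mcmc_ctx(matrix, scheme, constraint, update)
  powers <- ss_powers(K)
  start <- as_postorder(start_tree %||%
                          constrained_start_tree(matrix$ids, constraint))
  if (!check_constraint(start, constraint)) {
    stop2("Starting tree violates the constraint")
  }
  per_run <- numeric(config$n_runs)
  step_means <- matrix(0, config$n_runs, K)
  for (r in seq_len(config$n_runs)) {
    res <- with_seed(config$seed + 1000L * r, function() {
      sample_at <- function(beta, state, n) {
        cfg <- config
        cfg$n_chains_per_run <- 1L  # stepping stones use the cold chain
        out <- .run_chain(ctx, cfg, beta, n,
                          state %||% list(tree = start, scheme = scheme),
                          record_trees = FALSE)
        list(state = out$final_state, logLik = out$logLik)
      }
      .ss_one_run(sample_at, NULL, powers, config$generations)
    })
    if (any(!is.finite(res$marginal_lnL))) stop2("Degenerate likelihood in stepping-stone run")
    per_run[r] <- res$marginal_lnL
    step_means[r, ] <- res$step_mean_logL
  }
  structure(list(marginal_lnL = mean(per_run),
                 mc_error = if (config$n_runs > 1L)
                   stats::sd(per_run) / sqrt(config$n_runs) else NA_real_,
                 per_run = per_run, powers = powers,
                 step_mean_logL = colMeans(step_means),
                 K = K, constraint = constraint),
            class = "stepping_stone_run")
}

#' @export
print.stepping_stone_run <- function(x, ...) {
  cat(sprintf("stepping-stone: marginal lnL = %.2f (MC error %.3f, K = %d)\n",
              x$marginal_lnL, x$mc_error, x$K))
  invisible(x)
}

#' Generic stepping-stone estimator for a user-supplied model
#'
#' The same estimator as [stepping_stone()] but over an arbitrary
#' Metropolis-Hastings target: supply an initial state, a symmetric-or-
#' corrected proposal, and log-prior/log-likelihood functions. Useful for
#' validating the estimator against closed-form marginals.
#'
#' @param init Initial state (any R object).
#' @param propose Function `(state) -> list(state, log_hastings)` or `NULL`
#'   for an auto-rejected proposal.
#' @param log_prior,log_lik Functions of the state.
#' @param K Number of steps.
#' @param gens_per_step Proposals per step.
#' @param sample_every Thinning.
#' @param n_runs Independent runs.
#' @param seed Integer seed.
#' @return A `stepping_stone_run`.
#' @export
stepping_stone_generic <- function(init, propose, log_prior, log_lik,
                                   K = 10L, gens_per_step = 5000L,
                                   sample_every = 5L, n_runs = 2L,
                                   seed = 1L) {
  powers <- ss_powers(K)
  per_run <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    res <- with_seed(seed + 1000L * r, function() {
      cur <- init; cur_ll <- log_lik(cur); cur_lp <- log_prior(cur)
      sample_at <- function(beta, state, n) {
        if (!is.null(state)) {
          cur <<- state; cur_ll <<- log_lik(cur); cur_lp <<- log_prior(cur)
        }
        lls <- numeric(n %/% sample_every)
        i <- 0L
        for (g in seq_len(n)) {
          prop <- propose(cur)
          if (!is.null(prop)) {
            ll2 <- log_lik(prop$state); lp2 <- log_prior(prop$state)
            la <- beta * (ll2 - cur_ll) + lp2 - cur_lp + prop$log_hastings
            if (is.finite(la) && log(runif(1)) < la) {
              cur <<- prop$state; cur_ll <<- ll2; cur_lp <<- lp2
            }
          }
          if (g %% sample_every == 0L) { i <- i + 1L; lls[i] <- cur_ll }
        }
        list(state = cur, logLik = lls[seq_len(i)])
      }
      .ss_one_run(sample_at, NULL, powers, gens_per_step)
    })
    per_run[r] <- res$marginal_lnL
  }
  structure(list(marginal_lnL = mean(per_run),
                 mc_error = if (n_runs > 1L) stats::sd(per_run) / sqrt(n_runs)
                            else NA_real_,
                 per_run = per_run, powers = powers, K = K,
                 constraint = NULL),
            class = "stepping_stone_run")
}

#' Bayes-factor comparison of two hypotheses
#'
#' The reported statistic is the log Bayes factor, the difference of the two
#' marginal log-likelihoods; |log BF| > `threshold` (default 5) is read as
#' strong support for the better hypothesis.
#'
#' @param run_a,run_b `stepping_stone_run` objects, or bare marginal
#'   log-likelihood values.
#' @param label_a,label_b Hypothesis names.
#' @param threshold Strong-support threshold on |log BF|.
#' @return A `hypothesis_test`: `log_bayes_factor`, `verdict` (one of
#'   `"strong support for a"`, `"strong support for b"`, `"inconclusive"`),
#'   the two marginal lnLs and labels.
#' @export
bayes_factor <- function(run_a, run_b, label_a = "a", label_b = "b",
                         threshold = 5) {
  ml <- function(x) if (inherits(x, "stepping_stone_run")) x$marginal_lnL
                    else as.numeric(x)
  a <- ml(run_a); b <- ml(run_b)
  lbf <- a - b
  verdict <- if (abs(lbf) > threshold) {
    if (lbf > 0) "strong support for a" else "strong support for b"
  } else "inconclusive"
  structure(list(label_a = label_a, label_b = label_b,
                 marginal_lnL_a = a, marginal_lnL_b = b,
                 log_bayes_factor = lbf, threshold = threshold,
                 verdict = verdict),
            class = "hypothesis_test")
}

#' @export
print.hypothesis_test <- function(x, ...) {
  cat(sprintf("log BF (%s vs %s) = %.2f -> %s\n", x$label_a, x$label_b,
              x$log_bayes_factor, x$verdict))
  invisible(x)
}
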