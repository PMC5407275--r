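# Constrained tree MCMC, convergence diagnostics, stepping-stone sampling
# and Bayes factors.

test_that("constrained samplers emit only constraint-satisfying trees", {
  fx <- sim_fixture(5, 20, seed = 201)
  cons <- topology_constraint(c("t1", "t2"), "monophyletic")
  cfg <- mcmc_config(n_runs = 1, n_chains_per_run = 1, generations = 1200,
                     sample_every = 2, seed = 5)
  tr <- mcmc_sample(fx$am, fx$scheme, cfg, constraint = cons, power = 1,
                    update = c("topology", "blens"))
  ok <- vapply(tr$runs[[1]]$trees, check_constraint, logical(1),
               constraint = cons)
  expect_true(all(ok))

  neg <- topology_constraint(c("t1", "t2"), "not_monophyletic")
  tr2 <- mcmc_sample(fx$am, fx$scheme, cfg, constraint = neg, power = 0,
                     update = "topology")
  ok2 <- vapply(tr2$runs[[1]]$trees, check_constraint, logical(1),
                constraint = neg)
  expect_true(all(ok2))
})

test_that("prior-only sampling is uniform over the satisfying topologies", {
  skip_if_not_installed("phangorn")
  fx <- sim_fixture(5, 10, seed = 205)
  cons <- topology_constraint(c("t1", "t2"))
  cfg <- mcmc_config(n_runs = 1, n_chains_per_run = 1, generations = 4000,
                     sample_every = 1, seed = 17)
  tr <- mcmc_sample(fx$am, fx$scheme, cfg, constraint = cons, power = 0,
                    update = "topology")
  keys <- vapply(tr$runs[[1]]$trees, topology_key, character(1))
  # enumerate the satisfying set independently
  at <- phangorn::allTrees(5, tip.label = fx$am$ids)
  sat <- Filter(function(t) mono_oracle(t, c("t1", "t2")),
                lapply(seq_along(at), function(i) {
                  t <- at[[i]]; t$edge.length <- rep(1, nrow(t$edge)); t
                }))
  sat_keys <- vapply(sat, topology_key, character(1))
  expect_length(sat_keys, 3L)
  expect_true(all(keys %in% sat_keys))
  counts <- table(factor(keys, levels = sat_keys))
  # thinned-chain goodness of fit vs uniform (conservative threshold)
  p <- stats::chisq.test(counts[seq_along(sat_keys)])$p.value
  expect_gt(p, 0.001)
})

test_that("posterior sampling concentrates on a strongly supported split", {
  fx <- sim_fixture(5, 150, seed = 211, divergence = 0.3)
  cfg <- mcmc_config(n_runs = 1, n_chains_per_run = 1, generations = 3000,
                     sample_every = 3, seed = 23)
  tr <- mcmc_sample(fx$am, fx$scheme, cfg, power = 1,
                    update = c("topology", "blens"))
  burn <- 100
  trees <- tr$runs[[1]]$trees[-seq_len(burn)]
  true_splits <- names(tree_splits(fx$tree))
  freq <- sapply(true_splits, function(k) {
    mean(vapply(trees, function(t) k %in% names(tree_splits(t)),
                logical(1)))
  })
  expect_gt(max(freq), 0.95)
})

test_that("ESS is near n for white noise and ASDSF is zero for identical runs", {
  set.seed(3)
  x <- rnorm(4000)
  expect_lt(abs(ess(x) - 4000) / 4000, 0.15)
  skip_if_not_installed("coda")
  expect_lt(abs(ess(x) - as.numeric(coda::effectiveSize(x))) / 4000, 0.1)
  # strongly autocorrelated chain has much smaller ESS
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 4000))
  expect_lt(ess(ar), 1500)

  fx <- sim_fixture(5, 20, seed = 221)
  cfg <- mcmc_config(n_runs = 2, n_chains_per_run = 1, generations = 400,
                     sample_every = 2, seed = 31)
  tr <- mcmc_sample(fx$am, fx$scheme, cfg, power = 0, update = "topology")
  tr$runs[[2]] <- tr$runs[[1]]  # identical traces
  d <- mcmc_diagnostics(tr, ess_floor = 1)
  expect_equal(d$asdsf, 0)
})

test_that("ASDSF of independent draws from one distribution is small", {
  fx <- sim_fixture(5, 30, seed = 231)
  cfg <- mcmc_config(n_runs = 2, n_chains_per_run = 1, generations = 6000,
                     sample_every = 2, seed = 37)
  tr <- mcmc_sample(fx$am, fx$scheme, cfg, power = 0, update = "topology")
  d <- mcmc_diagnostics(tr, ess_floor = 1)
  expect_lt(d$asdsf, 0.02)
  single <- tr; single$runs <- single$runs[1]
  expect_warning(d1 <- mcmc_diagnostics(single, ess_floor = 1), "single run")
  expect_true(is.na(d1$asdsf))
})

test_that("stepping stone is exact for a constant likelihood at any K", {
  for (K in c(2, 5, 10)) {
    r <- stepping_stone_generic(
      init = 0,
      propose = function(s) list(state = s + rnorm(1, 0, 0.5),
                                 log_hastings = 0),
      log_prior = function(s) stats::dnorm(s, 0, 1, log = TRUE),
      log_lik = function(s) -2.5,
      K = K, gens_per_step = 300, sample_every = 3, n_runs = 1, seed = K)
    expect_equal(r$marginal_lnL, -2.5, tolerance = 1e-12)
  }
})

test_that("stepping stone recovers the conjugate-normal marginal", {
  y <- 0.5; sd_lik <- 0.7
  truth <- stats::dnorm(y, 0, sqrt(1 + sd_lik^2), log = TRUE)
  r <- stepping_stone_generic(
    init = 0,
    propose = function(s) list(state = s + rnorm(1, 0, 0.8),
                               log_hastings = 0),
    log_prior = function(s) stats::dnorm(s, 0, 1, log = TRUE),
    log_lik = function(s) stats::dnorm(y, s, sd_lik, log = TRUE),
    K = 10, gens_per_step = 4000, sample_every = 5, n_runs = 4, seed = 2)
  expect_lt(abs(r$marginal_lnL - truth), 3 * r$mc_error)
})

test_that("the power ladder is a decreasing Beta(0.3, 1) quantile grid", {
  p <- ss_powers(50)
  expect_equal(p[1], 1)
  expect_equal(p[51], 0)
  expect_true(all(diff(p) < 0))
  expect_equal(p[26], (25 / 50)^(1 / 0.3))
})

test_that("bayes_factor reproduces printed comparisons and is antisymmetric", {
  bf <- bayes_factor(-5463.35, -5471.71)
  expect_equal(bf$log_bayes_factor, 8.36)
  expect_equal(bf$verdict, "strong support for a")

  bf2 <- bayes_factor(-5471.55, -5492.50)
  expect_equal(bf2$log_bayes_factor, 20.95)

  expect_equal(bayes_factor(10, 7)$verdict, "inconclusive")
  expect_equal(bayes_factor(-3, -3)$log_bayes_factor, 0)
  expect_equal(bayes_factor(-5463.35, -5471.71)$log_bayes_factor,
               -bayes_factor(-5471.71, -5463.35)$log_bayes_factor)
})

test_that("config validation enforces the run-design invariants", {
  expect_error(mcmc_config(seed = NULL), "seed")
  expect_error(mcmc_config(burn_in_fraction = 1, seed = 1))
  cfg <- mcmc_config(seed = 1)
  expect_equal(cfg$n_runs, 4L)
  expect_error(ss_powers(1), "K >= 2")
})
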