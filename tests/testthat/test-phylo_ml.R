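# Substitution models, likelihood, optimization, model selection, ML search.

test_that("transition probabilities satisfy the stochastic-matrix laws", {
  models <- list(sub_model("JC69"),
                 sub_model("HKY85", kappa = 3, freqs = c(.3, .2, .3, .2)),
                 sub_model("GTR", rates = c(1.5, 4, .8, 1.2, 5, 1),
                           freqs = c(.3, .2, .25, .25)))
  for (m in models) {
    expect_equal(transition_probabilities(m, 0), diag(4),
                 ignore_attr = TRUE, tolerance = 1e-12)
    for (t in c(0.01, 0.3, 2)) {
      P <- transition_probabilities(m, t)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
      # time reversibility: pi_i P_ij = pi_j P_ji
      F <- m$freqs * P
      expect_lt(max(abs(F - t(F))), 1e-10)
    }
    # long-branch limit: rows approach the stationary frequencies
    Pinf <- transition_probabilities(m, 50)
    expect_lt(max(abs(sweep(Pinf, 2, m$freqs))), 1e-8)
  }
  expect_error(transition_probabilities(models[[1]], NA), "finite")
})

test_that("JC69 transition probabilities match the closed form", {
  m <- sub_model("JC69")
  for (t in c(0.05, 0.1, 0.7)) {
    P <- transition_probabilities(m, t)
    expect_equal(unname(diag(P)), rep(1 / 4 + 3 / 4 * exp(-4 * t / 3), 4),
                 tolerance = 1e-12)
  }
})

test_that("GTR transition probabilities match a series matrix exponential", {
  set.seed(9)
  for (i in 1:3) {
    m <- sub_model("GTR", rates = c(runif(5, 0.3, 4), 1),
                   freqs = runif(4, 0.1, 1))
    P <- transition_probabilities(m, 0.3)
    expect_lt(max(abs(P - expm_series(m$eig$Q, 0.3))), 1e-10)
  }
})

test_that("discrete-Gamma category rates average one", {
  for (a in c(0.2, 0.5, 1, 5)) {
    r <- gamma_rates(a, 4)
    expect_equal(mean(r), 1)
    expect_true(all(diff(r) > 0))
  }
})

test_that("two-taxon likelihood matches the closed form", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  am <- as_aligned_matrix(barcode_set(c("a", "b"), sequence = c("A", "A")))
  sch <- partition_scheme(am, "none", model = sub_model("JC69"))
  t <- 0.1
  expect_equal(log_likelihood(tr, sch, am),
               log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3))),
               tolerance = 1e-12)
})

test_that("pruning equals the enumeration oracle on small trees", {
  for (cfg in list(list(n = 4, seed = 41), list(n = 5, seed = 42))) {
    m <- sub_model("HKY85", kappa = 3, freqs = c(.3, .2, .3, .2),
                   alpha = 0.7)
    fx <- sim_fixture(cfg$n, 10, seed = cfg$seed, model = m)
    expect_equal(log_likelihood(fx$tree, fx$scheme, fx$am),
                 enum_loglik(fx$tree, m, fx$am), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to rerooting and child order", {
  fx <- sim_fixture(6, 20, seed = 51)
  l0 <- log_likelihood(fx$tree, fx$scheme, fx$am)
  rerooted <- ape::root(ape::unroot(fx$tree), outgroup = "t3",
                        resolve.root = TRUE)
  expect_equal(log_likelihood(rerooted, fx$scheme, fx$am), l0,
               tolerance = 1e-9)
  rot <- ape::rotate(ape::unroot(fx$tree),
                     node = length(fx$tree$tip.label) + 2L)
  expect_equal(log_likelihood(rot, fx$scheme, fx$am), l0, tolerance = 1e-9)
})

test_that("all-gap and N columns contribute zero log-likelihood", {
  fx <- sim_fixture(4, 10, seed = 61)
  l0 <- log_likelihood(fx$tree, fx$scheme, fx$am)
  aug <- fx$am
  aug$matrix <- cbind(aug$matrix, rep("-", 4), rep("N", 4))
  aug$length <- ncol(aug$matrix)
  aug$codon_pos <- rep_len(1:3, aug$length)
  sch <- partition_scheme(aug, "none", model = fx$scheme$models[[1]])
  expect_equal(log_likelihood(fx$tree, sch, aug), l0, tolerance = 1e-9)
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  fx <- sim_fixture(6, 40, seed = 71)
  m <- sub_model("GTR", rates = c(1.5, 4, .8, 1.2, 5, 1),
                 freqs = c(.3, .2, .25, .25))
  sch <- partition_scheme(fx$am, "none", model = m)
  pd <- phangorn::phyDat(fx$am$matrix, type = "DNA")
  fit <- phangorn::pml(ape::unroot(fx$tree), pd, model = "GTR",
                       bf = c(.3, .2, .25, .25),
                       Q = c(1.5, 4, .8, 1.2, 5, 1))
  expect_equal(log_likelihood(fx$tree, sch, fx$am), fit$logLik,
               tolerance = 1e-6)
})

test_that("BIC recomputes exactly from (k, n, lnL)", {
  expect_equal(bic_score(-5000, 10, 699), 10 * log(699) + 10000)
  expect_equal(round(bic_score(-5000, 10, 699), 2), 10065.5)
})

test_that("optimization improves lnL and is idempotent at the optimum", {
  fx <- sim_fixture(5, 60, seed = 81,
                    model = sub_model("HKY85", kappa = 2,
                                      freqs = rep(0.25, 4)))
  fit <- optimize_fit(fx$tree, fx$scheme, fx$am, "both", max_rounds = 25)
  expect_gte(fit$logLik, fit$start_logLik)
  expect_equal(fit$bic, bic_score(fit$logLik, fit$k, fit$n))
  fit2 <- optimize_fit(fit$tree, fit$scheme, fx$am, "both", max_rounds = 5)
  expect_lt(abs(fit2$logLik - fit$logLik), 1e-4)
})

test_that("parameter counts follow the family and partition structure", {
  fx <- sim_fixture(6, 30, seed = 91)
  n <- 6
  sch_jc <- partition_scheme(fx$am, "none", model = sub_model("JC69"))
  expect_equal(count_parameters(sch_jc, n), 2 * n - 3)
  sch_gtrg <- partition_scheme(fx$am, "none",
                               model = sub_model("GTR", alpha = 1))
  expect_equal(count_parameters(sch_gtrg, n), 2 * n - 3 + 9)
  sch_codon <- partition_scheme(fx$am, "codon",
                                model = sub_model("HKY85", kappa = 2))
  expect_equal(count_parameters(sch_codon, n), 2 * n - 3 + 3 * 4 + 2)
})

test_that("BIC prefers a JC-compatible family on JC data", {
  wins <- 0L
  jc <- sub_model("JC69")
  for (seed in c(3, 4, 5)) {
    spec <- simulation_spec(5, divergence = 0.2, length_codons = 100,
                            seed = seed, models = list(jc, jc, jc),
                            rate_multipliers = c(1, 1, 1))
    tr <- simulate_tree(spec)
    am <- simulate_alignment(tr, spec)
    sel <- select_model(am, tr, families = c("JC69", "GTR"),
                        schemes = "none", gamma = FALSE, max_rounds = 6)
    if (sel$table$family[1] == "JC69") wins <- wins + 1L
    expect_equal(sel$best$bic, min(sel$table$bic))
  }
  expect_gte(wins, 2L)
})

test_that("three-taxon search returns the single unrooted topology", {
  fx <- sim_fixture(3, 30, seed = 101)
  res <- ml_search(fx$am, fx$scheme, n_starts = 5, seed = 1)
  expect_equal(sort(res$tree$tip.label), c("t1", "t2", "t3"))
  expect_equal(res$tree$Nnode, 1L)
})

test_that("more starts never lower the best lnL on the same seed stream", {
  fx <- sim_fixture(6, 50, seed = 111)
  r1 <- ml_search(fx$am, fx$scheme, n_starts = 1, seed = 7)
  r3 <- ml_search(fx$am, fx$scheme, n_starts = 3, seed = 7)
  expect_gte(r3$logLik + 1e-9, r1$logLik)
})

test_that("bootstrap supports are percentages on multiples of 100/R", {
  fx <- sim_fixture(5, 60, seed = 121, divergence = 0.3)
  res <- ml_search(fx$am, fx$scheme, n_starts = 1, seed = 1)
  bs <- bootstrap_support(fx$am, fx$scheme, res$tree, replicates = 10,
                          seed = 3, search = "nj")
  expect_true(all(bs$supports$bootstrap >= 0 & bs$supports$bootstrap <= 100))
  expect_true(all(bs$supports$bootstrap * 10 / 100 ==
                  round(bs$supports$bootstrap * 10 / 100)))
  bs2 <- bootstrap_support(fx$am, fx$scheme, res$tree, replicates = 10,
                           seed = 3, search = "nj")
  expect_identical(bs$supports, bs2$supports)
})

test_that("query placement reports species clades, sisters and supports", {
  tr <- ape::read.tree(
    text = "((q:0.01,(r1:0.01,r2:0.01):0.02):0.1,(s1:0.05,s2:0.05):0.1,o:0.2);")
  taxa <- c(r1 = "Alpha one", r2 = "Alpha one", s1 = "Alpha two",
            s2 = "Alpha two", o = "Beta three")
  ann <- structure(list(tree = tr, supports = data.frame(
    key = names(tree_splits(tr)), stringsAsFactors = FALSE)),
    class = "annotated_tree")
  ann$supports$bootstrap <- 98
  ann$supports$posterior <- 1.0
  pl <- place_query(ann, "q", taxa)
  expect_equal(pl$species, "Alpha one")
  expect_equal(pl$level, "species")
  expect_equal(pl$label, "98/100")
  expect_setequal(pl$sister_taxa, c("r1", "r2"))

  # mixed-species sister set -> genus-or-higher with both species listed
  taxa2 <- c(r1 = "Alpha one", r2 = "Alpha two", s1 = "Alpha two",
             s2 = "Alpha two", o = "Beta three")
  pl2 <- place_query(ann, "q", taxa2)
  expect_equal(pl2$level, "genus-or-higher")
  expect_setequal(pl2$sister_species, c("Alpha one", "Alpha two"))

  star <- ape::read.tree(text = "(a:1,b:1,c:1,q:1);")
  pl3 <- place_query(structure(list(tree = star, supports = data.frame(
    key = character(0))), class = "annotated_tree"), "q",
    c(a = "A a", b = "B b", c = "C c"))
  expect_equal(pl3$level, "unresolved")
  expect_error(place_query(ann, "zz", taxa), "not in tree")
})
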