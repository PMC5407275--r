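# Simulators: determinism, model calibration, keys and scenarios.

test_that("tree simulation is deterministic and respects the divergence scale", {
  spec <- simulation_spec(8, divergence = 0.25, length_codons = 10, seed = 1)
  t1 <- simulate_tree(spec); t2 <- simulate_tree(spec)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 8L)
  expect_true(all(t1$edge.length >= spec$min_edge))
  expect_error(simulation_spec(8, birth = -1, seed = 1), "positive")
  expect_error(simulation_spec(2, seed = 1), "n_taxa")
  expect_error(simulation_spec(8), "seed")
})

test_that("three-taxon trees have the single unrooted shape", {
  spec <- simulation_spec(3, seed = 2)
  tr <- simulate_tree(spec)
  expect_equal(length(tree_splits(ape::unroot(tr))), 0L)
})

test_that("four-taxon labeled topologies appear with near-equal frequency", {
  keys <- character(300)
  for (i in seq_len(300)) {
    spec <- simulation_spec(4, seed = 10000 + i, length_codons = 1)
    tr <- simulate_tree(spec)
    tr$tip.label <- paste0("t", sample(4))  # exchangeable relabeling
    keys[i] <- topology_key(ape::unroot(tr))
  }
  counts <- table(keys)
  expect_equal(length(counts), 3L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("alignment simulation is deterministic, gapless and stop-free", {
  spec <- simulation_spec(6, divergence = 0.2, length_codons = 60, seed = 3)
  tr <- simulate_tree(spec)
  a1 <- simulate_alignment(tr, spec)
  a2 <- simulate_alignment(tr, spec)
  expect_identical(a1$matrix, a2$matrix)
  expect_equal(a1$length, 180L)
  expect_false(any(a1$matrix == "-"))
  expect_true(all(numt_screen(a1)$passed))
})

test_that("zero-length tree yields identical sequences", {
  spec <- simulation_spec(4, divergence = 0.3, length_codons = 20, seed = 4,
                          min_edge = 0)
  tr <- simulate_tree(spec)
  tr$edge.length <- rep(0, nrow(tr$edge))
  am <- simulate_alignment(tr, spec)
  seqs <- apply(am$matrix, 1, paste, collapse = "")
  expect_equal(length(unique(seqs)), 1L)
})

test_that("pairwise divergence matches the Jukes-Cantor expectation", {
  jc <- sub_model("JC69")
  spec <- simulation_spec(3, divergence = 1, length_codons = 6000, seed = 5,
                          min_edge = 0, models = list(jc, jc, jc),
                          rate_multipliers = c(1, 1, 1),
                          forbid_stops = FALSE)
  tr <- ape::read.tree(text = "(t1:0.05,t2:0.05,t3:0.05);")
  am <- simulate_alignment(tr, spec)
  d <- 0.1  # t1-t2 path length
  p_expect <- 3 / 4 * (1 - exp(-4 * d / 3))
  p_obs <- mean(am$matrix["t1", ] != am$matrix["t2", ])
  se <- sqrt(p_expect * (1 - p_expect) / am$length)
  expect_lt(abs(p_obs - p_expect), 3 * se)
})

test_that("empirical base frequencies converge to the stationary distribution", {
  m <- sub_model("HKY85", kappa = 3, freqs = c(0.4, 0.25, 0.15, 0.2))
  spec <- simulation_spec(3, divergence = 0.05, length_codons = 16000,
                          seed = 6, min_edge = 0, models = list(m, m, m),
                          rate_multipliers = c(1, 1, 1),
                          forbid_stops = FALSE)
  tr <- simulate_tree(spec)
  am <- simulate_alignment(tr, spec)
  f <- empirical_freqs(am)
  expect_lt(max(abs(f - m$freqs)), 0.01)
})

test_that("panel keys are diagnostic and self-consistent", {
  fx <- sim_fixture(6, 80, seed = 7, divergence = 0.3)
  # diagnostic positions constructed by hand on top of the panel
  panel <- fx$am
  panel$taxa <- panel$ids
  pos <- seq(3, 42, by = 3)
  for (i in seq_along(panel$ids)) {
    # base-4 encoding of the species index over the first two positions
    states <- rep("A", length(pos))
    states[1] <- c("A", "C", "G", "T")[(i - 1) %% 4 + 1]
    states[2] <- c("A", "C", "G", "T")[(i - 1) %/% 4 + 1]
    panel$matrix[i, pos] <- states
  }
  key <- make_key(panel, pos)
  expect_length(key$positions, 14L)
  for (i in seq_along(panel$ids)) {
    prof <- paste(panel$matrix[i, pos], collapse = "")
    expect_equal(match_profile(prof, key)$best_species, panel$ids[i])
    expect_equal(match_profile(prof, key)$mismatches, 0L)
  }
  # collision: two species identical at all key positions
  panel$matrix[2, pos] <- panel$matrix[1, pos]
  expect_error(make_key(panel, pos), "colliding")
})

test_that("scenarios honor their mislabel flags and reject inconsistent ones", {
  spec <- simulation_spec(5, divergence = 0.3, length_codons = 80, seed = 8)
  qdf <- data.frame(true_species = c("sp1", "sp2", "sp3"),
                    mislabel = c(FALSE, TRUE, FALSE))
  sc <- make_scenario(5, qdf, spec)
  expect_equal(nrow(sc$refs), 10L)
  expect_equal(sc$truth$mislabel, qdf$mislabel)
  # mislabeled listing's rule excludes the truth
  for (i in which(sc$truth$mislabel)) {
    r <- sc$rules[[sc$truth$listing[i]]]
    expect_false(sc$truth$true_species[i] %in% r$acceptable_taxa)
  }
  expect_error(make_scenario(5, data.frame(true_species = "spX",
                                           mislabel = FALSE), spec),
               "must be in the panel")
})

test_that("scenario files are written when requested", {
  spec <- simulation_spec(4, divergence = 0.3, length_codons = 40, seed = 9)
  qdf <- data.frame(true_species = c("sp1", "sp2"),
                    mislabel = c(FALSE, TRUE))
  dir <- withr::local_tempdir()
  sc <- make_scenario(4, qdf, spec, out_dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("references.fasta", "queries.fasta", "species_tree.nwk",
      "rules.yaml", "truth.tsv")))))
  refs <- read_fasta(file.path(dir, "references.fasta"), "reference")
  expect_equal(refs$sequence, sc$refs$sequence)
})

test_that("scenario pipeline recovers the planted truth", {
  spec <- simulation_spec(6, divergence = 0.3, length_codons = 120,
                          seed = 10)
  qdf <- data.frame(true_species = paste0("sp", c(1:6, 1:6)),
                    mislabel = rep(c(FALSE, TRUE), 6))
  sc <- make_scenario(6, qdf, spec)
  res <- run_scenario_audit(sc)
  expect_equal(res$report$n_mislabeled, sum(qdf$mislabel))
  expect_equal(unname(res$final_species[sc$truth$query_id]),
               sc$truth$true_species)
})
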