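# Seeded simulators: birth-death trees, codon-structured COI-like alignments
# (no in-frame stop codons), reference panels, diagnostic keys and
# end-to-end mislabeling scenarios with known truth.

#' Simulation specification
#'
#' @param n_taxa Number of tips (>= 3).
#' @param birth,death Birth-death rates for the tree process.
#' @param divergence Mean root-to-tip path length after rescaling, in
#'   expected substitutions/site. The default 0.2 gives a family-level
#'   ("deep") panel; use ~0.01 for a *Thunnus*-like shallow panel.
#' @param length_codons Number of codons simulated.
#' @param models List of three `sub_model`s, one per codon position.
#' @param rate_multipliers Relative rates of codon positions 1..3; default
#'   third position 5x faster; renormalized to mean 1.
#' @param min_edge Minimum branch length after rescaling (substitutions per
#'   site). Birth-death draws can contain effectively zero internal
#'   branches, which make the topology unidentifiable at barcode lengths;
#'   the floor keeps simulated species distinct, matching the divergent
#'   panels the pipeline is meant for.
#' @param genetic_code NCBI translation table id used for the stop-codon
#'   screen during simulation.
#' @param forbid_stops Redraw codons that would produce an in-frame stop in
#'   any tip sequence (default `TRUE`).
#' @param seed Integer seed (mandatory).
#' @return A `simulation_spec`.
#' @export
simulation_spec <- function(n_taxa, birth = 1, death = 0, divergence = 0.2,
                            length_codons = 220L,
                            models = NULL,
                            rate_multipliers = c(1, 1, 5),
                            min_edge = 0.03,
                            genetic_code = 2, forbid_stops = TRUE,
                            seed) {
  if (missing(seed) || is.null(seed)) stop2("A seed is mandatory")
  if (n_taxa < 3L) stop2("n_taxa must be >= 3")
  if (birth <= 0 || death < 0) stop2("Rates must be positive (birth) and >= 0 (death)")
  if (length_codons <= 0L) stop2("length_codons must be positive")
  if (is.null(models)) {
    models <- list(
      sub_model("HKY85", kappa = 4, freqs = c(0.28, 0.26, 0.18, 0.28)),
      sub_model("HKY85", kappa = 4, freqs = c(0.20, 0.28, 0.20, 0.32)),
      sub_model("HKY85", kappa = 8, freqs = c(0.35, 0.30, 0.05, 0.30),
                alpha = 0.8))
  }
  rm <- rate_multipliers / mean(rate_multipliers)
  structure(list(n_taxa = as.integer(n_taxa), birth = birth, death = death,
                 divergence = divergence,
                 length_codons = as.integer(length_codons),
                 models = models, rate_multipliers = rm,
                 min_edge = min_edge,
                 genetic_code = genetic_code, forbid_stops = forbid_stops,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a birth-death tree
#'
#' Branch lengths are rescaled so the mean root-to-tip path equals
#' `spec$divergence` substitutions/site. Deterministic given `spec$seed`.
#'
#' @param spec A `simulation_spec`.
#' @return A `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(spec) {
  with_seed(spec$seed, function() {
    tr <- ape::rphylo(spec$n_taxa, birth = spec$birth, death = spec$death,
                      fossils = FALSE)
    tr$tip.label <- paste0("t", seq_len(spec$n_taxa))
    depths <- ape::node.depth.edgelength(tr)[seq_len(spec$n_taxa)]
    tr$edge.length <- tr$edge.length * spec$divergence / mean(depths)
    tr$edge.length <- pmax(tr$edge.length, spec$min_edge)
    tr
  })
}

# evolve a single site down the tree; returns states at all nodes (1..4)
.evolve_site <- function(tree_pre, root_state, model, rate) {
  nn <- length(tree_pre$tip.label) + tree_pre$Nnode
  states <- integer(nn)
  root <- tree_pre$edge[1L, 1L]
  states[root] <- root_state
  e <- model$eig
  for (k in seq_len(nrow(tree_pre$edge))) {
    p <- tree_pre$edge[k, 1L]; ch <- tree_pre$edge[k, 2L]
    P <- e$right %*% (exp(e$values * tree_pre$edge.length[k] * rate) * e$left)
    pr <- pmax(P[states[p], ], 0)
    states[ch] <- sample.int(4L, 1L, prob = pr)
  }
  states
}

#' Simulate a codon-structured alignment on a tree
#'
#' Root states are drawn from each position model's stationary frequencies;
#' states evolve along branches under the position model, a per-position
#' rate multiplier, and (where the model has a Gamma shape) a per-site
#' continuous Gamma(alpha, alpha) rate draw. When `forbid_stops` is set,
#' any codon producing an in-frame stop in a tip sequence is redrawn, so
#' output is always a valid gapless coding alignment.
#'
#' @param tree A `phylo` (e.g. from [simulate_tree()]).
#' @param spec A `simulation_spec`.
#' @param seed Optional override of `spec$seed` (so several alignments can
#'   be drawn on one tree).
#' @return An `aligned_matrix` with taxa equal to tip labels.
#' @export
simulate_alignment <- function(tree, spec, seed = spec$seed) {
  tree_pre <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree_pre$tip.label)
  tab <- genetic_code_table(spec$genetic_code)
  stops <- names(tab)[tab == "*"]
  with_seed(seed, function() {
    sim_codon <- function() {
      cols <- matrix(0L, ntip, 3L)
      for (p in 1:3) {
        m <- spec$models[[p]]
        rate <- spec$rate_multipliers[p] *
          if (is.null(m$alpha)) 1 else rgamma(1L, m$alpha, m$alpha)
        root <- sample.int(4L, 1L, prob = m$freqs)
        st <- .evolve_site(tree_pre, root, m, rate)
        cols[, p] <- st[seq_len(ntip)]
      }
      cols
    }
    out <- matrix("", ntip, 3L * spec$length_codons)
    for (j in seq_len(spec$length_codons)) {
      for (try in 1:200) {
        cols <- sim_codon()
        cod <- paste0(.bases[cols[, 1L]], .bases[cols[, 2L]],
                      .bases[cols[, 3L]])
        if (!spec$forbid_stops || !any(cod %in% stops)) break
        if (try == 200L) stop2("Could not draw a stop-free codon")
      }
      out[, (3L * j - 2L):(3L * j)] <- .bases[cols]
    }
    recs <- barcode_set(tree_pre$tip.label, taxon = tree_pre$tip.label,
                        sequence = apply(out, 1L, paste, collapse = ""),
                        role = "reference",
                        genetic_code = spec$genetic_code)
    as_aligned_matrix(recs)
  })
}

#' Build a diagnostic key from a panel alignment
#'
#' Takes the consensus state of each species at the requested positions.
#' Every row of a species must agree at those positions, and no two species
#' may share a complete profile.
#'
#' @param panel An `aligned_matrix` whose `taxa` give the species of each
#'   row.
#' @param positions 1-based column positions to use.
#' @return A `diagnostic_key`.
#' @export
make_key <- function(panel, positions) {
  species <- unique(panel$taxa)
  prof <- character(length(species))
  for (i in seq_along(species)) {
    rows <- panel$matrix[panel$taxa == species[i], positions, drop = FALSE]
    if (any(apply(rows, 2L, function(col) length(unique(col)) != 1L))) {
      stop2("Species ", species[i], " is polymorphic at a key position")
    }
    st <- rows[1L, ]
    if (!all(st %in% c("A", "C", "G", "T"))) {
      stop2("Non-ACGT state at a key position for ", species[i])
    }
    prof[i] <- paste(st, collapse = "")
  }
  names(prof) <- species
  if (anyDuplicated(prof)) {
    dup <- species[prof %in% prof[duplicated(prof)]]
    stop2("Non-diagnostic position set; colliding species: ",
          paste(dup, collapse = ", "))
  }
  diagnostic_key(positions, prof)
}

#' Generate an end-to-end mislabeling scenario with known truth
#'
#' Simulates a divergent reference panel (>= 2 sequences per species as
#' shallow descendants of each species' ancestral sequence), query sequences
#' as further descendants of their true species, a menu-rules list in which
#' each species has its own acceptable listing, and the truth table.
#' Mislabeled queries are paired with a listing whose rule excludes their
#' true species.
#'
#' @param n_species Number of panel species.
#' @param queries Data frame with columns `true_species` (e.g. `"sp3"`) and
#'   `mislabel` (logical); listings are assigned accordingly.
#' @param spec A `simulation_spec` for the species tree/panel (its `n_taxa`
#'   must equal `n_species`).
#' @param within_divergence Divergence between a species' ancestor and each
#'   reference/query copy (substitutions/site).
#' @param out_dir Optional directory; when given, the reference/query FASTA
#'   files, species tree (Newick), rules YAML and truth TSV are written
#'   there.
#' @return List: `refs`, `queries` (both `barcode_set`), `rules` (menu-rule
#'   list), `truth` (data frame with `query_id`, `listing`, `true_species`,
#'   `mislabel`).
#' @export
make_scenario <- function(n_species, queries, spec,
                          within_divergence = 0.004, out_dir = NULL) {
  stopifnot(spec$n_taxa == n_species)
  species <- paste0("sp", seq_len(n_species))
  if (!all(queries$true_species %in% species)) {
    stop2("Every true_species must be in the panel")
  }
  tree <- simulate_tree(spec)
  anc <- simulate_alignment(tree, spec)  # one ancestral sequence per species
  # rules: each species is acceptable only for its own dish
  rules <- lapply(species, function(s) {
    structure(list(listing_pattern = normalize_listing(paste0("dish of ", s)),
                   acceptable_taxa = s, species_specific = TRUE),
              class = "menu_rule")
  })
  names(rules) <- vapply(rules, `[[`, character(1L), "listing_pattern")
  listing_of <- setNames(names(rules), species)
  # consistency: a mislabeled query must carry a listing excluding its truth
  other_listing <- function(s) listing_of[species[species != s][1L]]

  tab <- genetic_code_table(spec$genetic_code)
  stops <- names(tab)[tab == "*"]
  descend <- function(anc_seq, dv, seed) {
    # evolve each codon of the ancestor a further dv along a single branch
    with_seed(seed, function() {
      s <- seq_chars(anc_seq)
      n <- length(s)
      out <- s
      for (p in 1:3) {
        m <- spec$models[[p]]
        idx <- seq(p, n, by = 3L)
        P <- transition_probabilities(m, dv, spec$rate_multipliers[p])
        from <- match(s[idx], .bases)
        out[idx] <- .bases[vapply(from, function(f)
          sample.int(4L, 1L, prob = P[f, ]), integer(1L))]
      }
      # keep coding: revert any codon that became a stop
      for (j in seq(1L, n - 2L, by = 3L)) {
        if (paste(out[j:(j + 2L)], collapse = "") %in% stops) {
          out[j:(j + 2L)] <- s[j:(j + 2L)]
        }
      }
      paste(out, collapse = "")
    })
  }

  anc_seqs <- setNames(apply(anc$matrix, 1L, paste, collapse = ""), species)
  ref_ids <- c(); ref_taxa <- c(); ref_seqs <- c()
  for (i in seq_along(species)) {
    for (cp in 1:2) {
      ref_ids <- c(ref_ids, paste0(species[i], "_ref", cp))
      ref_taxa <- c(ref_taxa, species[i])
      ref_seqs <- c(ref_seqs, descend(anc_seqs[i], within_divergence,
                                      spec$seed + 1000L * i + cp))
    }
  }
  refs <- barcode_set(ref_ids, ref_taxa, ref_seqs, "reference",
                      spec$genetic_code)

  nq <- nrow(queries)
  q_ids <- paste0("q", seq_len(nq))
  q_seqs <- character(nq); listings <- character(nq)
  for (i in seq_len(nq)) {
    s <- queries$true_species[i]
    q_seqs[i] <- descend(anc_seqs[s], within_divergence,
                         spec$seed + 77777L + i)
    listings[i] <- if (queries$mislabel[i]) other_listing(s) else
      listing_of[s]
    if (queries$mislabel[i] && s %in% rules[[listings[i]]]$acceptable_taxa) {
      stop2("Inconsistent mislabel request: listing accepts the true species")
    }
  }
  qset <- barcode_set(q_ids, NA_character_, q_seqs, "query",
                      spec$genetic_code)
  truth <- data.frame(query_id = q_ids, listing = listings,
                      true_species = queries$true_species,
                      mislabel = queries$mislabel, stringsAsFactors = FALSE)
  out <- list(refs = refs, queries = qset, rules = rules, truth = truth,
              tree = tree)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(refs, file.path(out_dir, "references.fasta"))
    write_fasta(qset, file.path(out_dir, "queries.fasta"))
    ape::write.tree(tree, file.path(out_dir, "species_tree.nwk"))
    yaml::write_yaml(list(rules = lapply(rules, function(r) {
      list(acceptable = as.list(r$acceptable_taxa),
           species_specific = r$species_specific)
    })), file.path(out_dir, "rules.yaml"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
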