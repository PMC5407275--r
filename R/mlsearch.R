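# Maximum-likelihood tree search (NJ start + NNI hill climbing), bootstrap
# support, posterior annotation of ML nodes, and query placement.

#' Maximum-likelihood pairwise distances
#'
#' For each pair of rows, the two-sequence log-likelihood under the first
#' subset's model is maximized over the total separating branch length.
#'
#' @param matrix An `aligned_matrix`.
#' @param model A `sub_model` (default JC69).
#' @return A `dist` object over the row ids.
#' @export
ml_distances <- function(matrix, model = sub_model("JC69")) {
  ids <- matrix$ids
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pair <- new_aligned_matrix(matrix$matrix[c(i, j), , drop = FALSE],
                                 ids[c(i, j)], matrix$taxa[c(i, j)],
                                 matrix$genetic_code, matrix$frame_offset)
      sch <- structure(list(subsets = list(all = seq_len(pair$length)),
                            models = list(all = model),
                            rate_multipliers = c(all = 1), type = "none"),
                       class = "partition_scheme")
      lik_data <- make_lik_data(pair, sch)
      tr <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L,
                                         byrow = TRUE),
                           edge.length = c(0.05, 0.05), Nnode = 1L,
                           tip.label = ids[c(i, j)]), class = "phylo")
      f <- function(t) {
        tr$edge.length <- c(t / 2, t / 2)
        -lnL_po(ape::reorder.phylo(tr, "postorder"), lik_data, sch)
      }
      D[i, j] <- D[j, i] <- stats::optimize(f, c(.bl_min, .bl_max),
                                            tol = 1e-6)$minimum
    }
  }
  stats::as.dist(D)
}

# NNI hill climb from a starting tree. `score_edges = "central"` scores each
# neighbor by re-optimizing only the branch created by the rearrangement
# (fast, used in bootstrap); "all" runs a full branch-length pass.
nni_hill_climb <- function(tree, lik_data, scheme, max_iter = 30L,
                           score_edges = c("all", "central"), tol = 1e-6) {
  score_edges <- match.arg(score_edges)
  tree_po <- optimize_blens_po(as_postorder(tree), lik_data, scheme,
                               rounds = 2L)
  cur_lnL <- lnL_po(tree_po, lik_data, scheme)
  if (length(tree_po$tip.label) < 4L) {
    return(list(tree = tree_po, logLik = cur_lnL))
  }
  for (it in seq_len(max_iter)) {
    nbs <- nni_neighbors(tree_po)
    best_lnL <- -Inf; best_tree <- NULL
    for (nb in nbs) {
      nb_po <- as_postorder(nb)
      nb_po <- if (score_edges == "all") {
        optimize_blens_po(nb_po, lik_data, scheme, rounds = 1L)
      } else {
        # re-optimize the internal edges only
        ie <- which(nb_po$edge[, 2L] > length(nb_po$tip.label))
        optimize_blens_po(nb_po, lik_data, scheme, rounds = 1L, edges = ie)
      }
      l <- lnL_po(nb_po, lik_data, scheme)
      if (l > best_lnL + 1e-12 ||
          (abs(l - best_lnL) <= 1e-12 && !is.null(best_tree) &&
           topology_key(nb_po) < topology_key(best_tree))) {
        best_lnL <- l; best_tree <- nb_po
      }
    }
    if (best_lnL > cur_lnL + tol) {
      tree_po <- optimize_blens_po(best_tree, lik_data, scheme, rounds = 1L)
      cur_lnL <- lnL_po(tree_po, lik_data, scheme)
    } else break
  }
  list(tree = tree_po, logLik = cur_lnL)
}

#' Maximum-likelihood tree search
#'
#' Hill-climbing NNI search from multiple starting trees: one
#' neighbor-joining tree built from ML pairwise distances plus
#' `n_starts - 1` random topologies. The best-lnL local optimum wins;
#' deterministic given `seed`.
#'
#' @param matrix An `aligned_matrix`.
#' @param scheme A `partition_scheme`.
#' @param n_starts Number of starting trees (default 10).
#' @param seed Integer seed for the random starts.
#' @param max_iter NNI iterations per start.
#' @return List with `tree` (the ML tree, branch lengths optimized),
#'   `logLik`, and `start_logLik` per start.
#' @export
ml_search <- function(matrix, scheme, n_starts = 10L, seed = 1L,
                      max_iter = 30L) {
  ids <- matrix$ids
  if (length(ids) < 4L) {
    # single unrooted topology: star / the only shape
    tr <- constrained_start_tree(ids, NULL)
    lik_data <- make_lik_data(matrix, scheme)
    tr <- optimize_blens_po(as_postorder(tr), lik_data, scheme, rounds = 3L)
    return(list(tree = tr, logLik = lnL_po(tr, lik_data, scheme),
                start_logLik = NA_real_))
  }
  lik_data <- make_lik_data(matrix, scheme)
  nj_tree <- ape::nj(ml_distances(matrix, scheme$models[[1L]]))
  nj_tree$edge.length[nj_tree$edge.length < .bl_min] <- .bl_min
  starts <- list(nj_tree)
  if (n_starts > 1L) {
    rand <- with_seed(seed, function() {
      lapply(seq_len(n_starts - 1L), function(i) random_topology(ids))
    })
    starts <- c(starts, rand)
  }
  best <- NULL; lnls <- numeric(length(starts))
  for (i in seq_along(starts)) {
    res <- nni_hill_climb(starts[[i]], lik_data, scheme,
                          max_iter = max_iter)
    lnls[i] <- res$logLik
    if (is.null(best) || res$logLik > best$logLik) best <- res
  }
  list(tree = best$tree, logLik = best$logLik, start_logLik = lnls)
}

#' Nonparametric bootstrap support for the ML tree
#'
#' Columns are resampled with replacement within each partition subset; each
#' replicate is searched by NNI from its own NJ tree (fast central-edge
#' scoring). Support for each ML-tree bipartition is the percentage of
#' replicate trees containing it.
#'
#' @param matrix An `aligned_matrix`.
#' @param scheme A `partition_scheme`.
#' @param ml_tree The tree to annotate (a `phylo`).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param search `"nni"` (default) or `"nj"` (distance tree only, faster).
#' @return An `annotated_tree`: list with `tree` and `supports` (data frame:
#'   split key, member taxa, bootstrap percentage).
#' @export
bootstrap_support <- function(matrix, scheme, ml_tree, replicates = 1000L,
                              seed = 1L, search = c("nni", "nj")) {
  search <- match.arg(search)
  stopifnot(replicates >= 1L)
  target <- tree_splits(ml_tree)
  counts <- setNames(numeric(length(target)), names(target))
  with_seed(seed, function() {
    for (r in seq_len(replicates)) {
      cols <- unlist(lapply(scheme$subsets, function(cs) {
        sample(cs, length(cs), replace = TRUE)
      }), use.names = FALSE)
      rep_mat <- new_aligned_matrix(
        matrix$matrix[, cols, drop = FALSE], matrix$ids, matrix$taxa,
        matrix$genetic_code, 0L)
      rep_scheme <- scheme
      # subsets keep their sizes, in resampled column order
      off <- 0L
      for (s in seq_along(scheme$subsets)) {
        rep_scheme$subsets[[s]] <- off + seq_along(scheme$subsets[[s]])
        off <- off + length(scheme$subsets[[s]])
      }
      tr <- ape::nj(ml_distances(rep_mat, scheme$models[[1L]]))
      tr$edge.length[tr$edge.length < .bl_min] <- .bl_min
      if (search == "nni" && length(matrix$ids) >= 4L) {
        ld <- make_lik_data(rep_mat, rep_scheme)
        tr <- nni_hill_climb(tr, ld, rep_scheme, max_iter = 10L,
                             score_edges = "central")$tree
      }
      got <- names(tree_splits(tr))
      hit <- intersect(got, names(counts))
      counts[hit] <<- counts[hit] + 1
    }
  })
  supports <- data.frame(
    key = names(target),
    taxa = vapply(target, paste, character(1L), collapse = ","),
    bootstrap = round(100 * as.numeric(counts) / replicates, 1),
    stringsAsFactors = FALSE)
  structure(list(tree = ml_tree, supports = supports),
            class = "annotated_tree")
}

#' Add posterior clade probabilities to an annotated tree
#'
#' @param annotated An `annotated_tree` from [bootstrap_support()] (or a bare
#'   `phylo`).
#' @param sampled_trees List of posterior tree samples (`phylo` objects).
#' @return The `annotated_tree` with a `posterior` column (clade probability
#'   in `[0, 1]`).
#' @export
annotate_posterior <- function(annotated, sampled_trees) {
  if (inherits(annotated, "phylo")) {
    target <- tree_splits(annotated)
    annotated <- structure(list(tree = annotated, supports = data.frame(
      key = names(target),
      taxa = vapply(target, paste, character(1L), collapse = ","),
      stringsAsFactors = FALSE)), class = "annotated_tree")
  }
  counts <- setNames(numeric(nrow(annotated$supports)),
                     annotated$supports$key)
  for (tr in sampled_trees) {
    hit <- intersect(names(tree_splits(tr)), names(counts))
    counts[hit] <- counts[hit] + 1
  }
  annotated$supports$posterior <- as.numeric(counts) / length(sampled_trees)
  annotated
}

#' Report the phylogenetic placement of a query
#'
#' Finds the query's sister taxon set and the smallest non-trivial clade
#' containing the query whose other members all share one species label, and
#' reports that clade's bootstrap/posterior annotations (the "ID
#' (support/PP)" convention; both printed as integers).
#'
#' @param annotated An `annotated_tree`.
#' @param query_id Tip label of the query.
#' @param taxa Named character vector mapping tip labels to species labels
#'   (query may be absent).
#' @return A list: `query_id`, `species` (or `NA`), `level`
#'   (`"species"`, `"genus-or-higher"` or `"unresolved"`), `members`,
#'   `sister_taxa`, `bootstrap`, `posterior`, `label` (e.g. `"98/100"`).
#' @export
place_query <- function(annotated, query_id, taxa) {
  tree <- annotated$tree
  if (!query_id %in% tree$tip.label) stop2("Query not in tree: ", query_id)
  splits <- tree_splits(tree)
  n <- length(tree$tip.label)
  # sides (clades) containing the query, smallest first; both orientations
  clades <- list()
  for (key in names(splits)) {
    side <- splits[[key]]
    other <- setdiff(tree$tip.label, side)
    for (cl in list(side, other)) {
      if (query_id %in% cl && length(cl) >= 2L && length(cl) <= n - 2L) {
        clades[[length(clades) + 1L]] <- list(key = key, members = cl)
      }
    }
  }
  if (length(clades) == 0L) {
    return(list(query_id = query_id, species = NA_character_,
                level = "unresolved", members = character(0),
                sister_taxa = character(0), bootstrap = NA_real_,
                posterior = NA_real_, label = "unresolved"))
  }
  sizes <- vapply(clades, function(cl) length(cl$members), integer(1L))
  ord <- order(sizes)
  ann <- function(key) {
    row <- annotated$supports[annotated$supports$key == key, , drop = FALSE]
    boot <- if ("bootstrap" %in% names(row) && nrow(row)) row$bootstrap else NA_real_
    pp <- if ("posterior" %in% names(row) && nrow(row)) row$posterior else NA_real_
    list(boot = boot, pp = pp)
  }
  smallest <- clades[[ord[1L]]]
  sister <- setdiff(smallest$members, query_id)
  for (cl in clades[ord]) {
    others <- setdiff(cl$members, query_id)
    sp <- unique(taxa[others])
    sp <- sp[!is.na(sp)]
    if (length(sp) == 1L) {
      a <- ann(cl$key)
      lab <- paste0(round(a$boot %||% NA_real_),
                    "/", round(100 * (a$pp %||% NA_real_)))
      return(list(query_id = query_id, species = sp, level = "species",
                  members = cl$members, sister_taxa = sister,
                  bootstrap = a$boot, posterior = a$pp, label = lab))
    }
  }
  a <- ann(smallest$key)
  sp <- sort(unique(taxa[sister]))
  list(query_id = query_id, species = NA_character_,
       level = "genus-or-higher", members = smallest$members,
       sister_taxa = sister, sister_species = sp, bootstrap = a$boot,
       posterior = a$pp, label = paste(sp, collapse = ", "))
}

#' Write an annotated tree as Newick with "boot/pp" node labels
#'
#' @param annotated An `annotated_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(annotated, path) {
  tree <- annotated$tree
  tree <- ape::makeNodeLabel(tree, method = "number", prefix = "")
  # label internal nodes by matching their split keys
  splits <- tree_splits(tree)
  lab <- rep("", tree$Nnode)
  eo <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", length(tree$tip.label) + tree$Nnode)
  for (i in seq_along(tree$tip.label)) desc[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ntip <- length(tree$tip.label)
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    key <- split_key(desc[[nd]], tree$tip.label)
    row <- annotated$supports[annotated$supports$key == key, , drop = FALSE]
    if (nrow(row)) {
      b <- if ("bootstrap" %in% names(row)) round(row$bootstrap) else NA
      p <- if ("posterior" %in% names(row)) round(100 * row$posterior) else NA
      lab[nd - ntip] <- paste0(b, "/", p)
    }
  }
  tree$node.label <- lab
  ape::write.tree(tree, file = path)
  invisible(path)
}
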