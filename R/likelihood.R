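# Partitioned phylogenetic likelihood by Felsenstein pruning.
#
# Likelihood model: per-partition GTR-family model with optional discrete-
# Gamma rate heterogeneity (equiprobable categories), linked branch lengths
# across partitions with per-partition rate multipliers constrained to a
# size-weighted mean of 1. Gaps and ambiguity codes contribute partial
# likelihood 1 for every compatible state (fully missing for '-'/'N').
# Site patterns are compressed per partition; compression does not change
# the likelihood value.

#' Partition scheme over an aligned matrix
#'
#' @param matrix An `aligned_matrix`.
#' @param type `"none"` (one subset spanning all columns) or `"codon"`
#'   (three subsets by position in codon).
#' @param model A `sub_model` used for every subset (recycled), or a list of
#'   one model per subset.
#' @param rate_multipliers Per-subset branch-length multipliers; renormalized
#'   to a size-weighted mean of 1.
#' @return A `partition_scheme`: list with `subsets` (named column-index
#'   lists), `models`, `rate_multipliers`.
#' @export
partition_scheme <- function(matrix, type = c("none", "codon"),
                             model = sub_model("GTR",
                                               freqs = empirical_freqs(matrix),
                                               alpha = 1),
                             rate_multipliers = NULL) {
  type <- match.arg(type)
  subsets <- if (type == "none") {
    list(all = seq_len(matrix$length))
  } else {
    list(pos1 = which(matrix$codon_pos == 1L),
         pos2 = which(matrix$codon_pos == 2L),
         pos3 = which(matrix$codon_pos == 3L))
  }
  subsets <- subsets[lengths(subsets) > 0L]
  models <- if (inherits(model, "sub_model")) {
    rep(list(model), length(subsets))
  } else model
  names(models) <- names(subsets)
  rm <- rate_multipliers %||% rep(1, length(subsets))
  structure(list(subsets = subsets, models = models,
                 rate_multipliers = normalize_multipliers(rm, lengths(subsets)),
                 type = type),
            class = "partition_scheme")
}

normalize_multipliers <- function(m, sizes) {
  w <- sizes / sum(sizes)
  setNames(m / sum(w * m), names(sizes))
}

#' Empirical base frequencies of an alignment
#' @param matrix An `aligned_matrix`.
#' @param cols Optional column subset.
#' @return Frequencies of A, C, G, T among unambiguous bases.
#' @export
empirical_freqs <- function(matrix, cols = NULL) {
  m <- if (is.null(cols)) matrix$matrix else matrix$matrix[, cols, drop = FALSE]
  counts <- vapply(.bases, function(b) sum(m == b), numeric(1L))
  if (all(counts == 0)) return(setNames(rep(0.25, 4), .bases))
  counts <- pmax(counts, 0.5)  # guard degenerate compositions
  counts / sum(counts)
}

# tip partial-likelihood vector for one character
.char_partial <- local({
  cache <- new.env(parent = emptyenv())
  function(ch) {
    v <- cache[[ch]]
    if (is.null(v)) {
      v <- if (ch %in% names(.iupac)) as.numeric(.bases %in% .iupac[[ch]])
           else rep(1, 4)  # gap or unknown: missing
      if (ch == "N") v <- rep(1, 4)
      cache[[ch]] <- v
    }
    v
  }
})

# Compress one subset of columns into patterns + per-tip partials.
# Returns list(tipL = list per tip of 4 x npat, counts).
compress_partition <- function(matrix, cols) {
  sub <- matrix$matrix[, cols, drop = FALSE]
  keys <- apply(sub, 2L, paste, collapse = "")
  uk <- unique(keys)
  counts <- as.numeric(table(factor(keys, levels = uk)))
  first <- match(uk, keys)
  pat <- sub[, first, drop = FALSE]
  tipL <- lapply(seq_len(nrow(pat)), function(i) {
    vapply(pat[i, ], .char_partial, numeric(4L))
  })
  names(tipL) <- matrix$ids
  list(tipL = tipL, counts = counts, npat = length(uk))
}

# Precompute pruning data for all subsets of a scheme.
make_lik_data <- function(matrix, scheme) {
  lapply(scheme$subsets, function(cols) compress_partition(matrix, cols))
}

# Pruning over one partition for a given model and branch multiplier.
.partition_loglik <- function(tree_po, part, model, mult) {
  rates <- gamma_rates(model$alpha, model$ncat)
  ncat <- length(rates)
  edges <- tree_po$edge
  el <- tree_po$edge.length
  ntip <- length(tree_po$tip.label)
  nn <- ntip + tree_po$Nnode
  root <- edges[nrow(edges), 1L]
  npat <- part$npat
  sitel <- matrix(0, ncat, npat)
  tipidx <- match(tree_po$tip.label, names(part$tipL))
  for (ci in seq_len(ncat)) {
    L <- vector("list", nn)
    for (k in seq_len(nrow(edges))) {
      p <- edges[k, 1L]; ch <- edges[k, 2L]
      P <- transition_probabilities(model, el[k], rates[ci] * mult)
      Lc <- if (ch <= ntip) part$tipL[[tipidx[ch]]] else L[[ch]]
      contrib <- P %*% Lc
      L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
    }
    sitel[ci, ] <- as.numeric(model$freqs %*% L[[root]])
  }
  persite <- colMeans(sitel)
  sum(part$counts * log(persite))
}

#' Partitioned log-likelihood of a tree
#'
#' @param tree A `phylo` object whose tips match the alignment rows.
#' @param scheme A `partition_scheme`.
#' @param matrix An `aligned_matrix`, or precomputed data from an earlier
#'   call (internal use).
#' @return Total log-likelihood (sum over subsets).
#' @export
log_likelihood <- function(tree, scheme, matrix) {
  lik_data <- if (inherits(matrix, "aligned_matrix")) {
    if (!setequal(tree$tip.label, matrix$ids)) {
      stop2("Tree tips do not match alignment rows")
    }
    make_lik_data(matrix, scheme)
  } else matrix
  tree_po <- if (length(tree$tip.label) > 2L) ape::unroot(tree) else tree
  tree_po <- ape::reorder.phylo(tree_po, "postorder")
  if (is.null(tree_po$edge.length)) stop2("Tree has no branch lengths")
  total <- 0
  for (s in seq_along(lik_data)) {
    total <- total + .partition_loglik(tree_po, lik_data[[s]],
                                       scheme$models[[s]],
                                       scheme$rate_multipliers[s])
  }
  total
}
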