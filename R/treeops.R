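# Unrooted tree utilities: splits, constraint checks, NNI rearrangements,
# random topologies. Public trees are ape "phylo" objects; rearrangements
# use an internal adjacency representation.

# ---- splits ----------------------------------------------------------------

split_key <- function(side, labels) {
  # canonical key: the side not containing the lexicographically first label
  ref <- min(labels)
  if (ref %in% side) side <- setdiff(labels, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' @param tree A `phylo` object.
#' @return Named list: canonical split key -> tip labels of the side not
#'   containing the alphabetically first tip.
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  out <- list()
  for (k in seq_len(nrow(eo$edge))) {
    side <- desc[[eo$edge[k, 2L]]]
    if (length(side) >= 2L && length(side) <= n - 2L) {
      key <- split_key(side, tree$tip.label)
      out[[key]] <- strsplit(key, "|", fixed = TRUE)[[1L]]
    }
  }
  out
}

#' Does a tree contain the bipartition separating `taxa`?
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels.
#' @return `TRUE` iff removing one branch separates exactly `taxa` from the
#'   rest. Trivial splits (singletons, complements of singletons) are always
#'   present.
#' @export
has_split <- function(tree, taxa) {
  labels <- tree$tip.label
  if (!all(taxa %in% labels)) stop2("Constraint taxa not in tree: ",
                                    paste(setdiff(taxa, labels), collapse = ", "))
  k <- length(taxa); n <- length(labels)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  split_key(taxa, labels) %in% names(tree_splits(tree))
}

#' Topology constraint
#'
#' @param taxa Constrained leaf set (2 <= size < number of leaves).
#' @param mode `"monophyletic"` or `"not_monophyletic"`.
#' @return A `topology_constraint`.
#' @export
topology_constraint <- function(taxa, mode = c("monophyletic",
                                               "not_monophyletic")) {
  mode <- match.arg(mode)
  if (length(taxa) < 2L) stop2("Constraint needs >= 2 taxa")
  structure(list(taxa = sort(unique(taxa)), mode = mode),
            class = "topology_constraint")
}

#' Check a tree against a topology constraint
#'
#' On an unrooted tree, monophyly of a taxon set is equivalent to the
#' existence of the bipartition separating exactly that set.
#'
#' @param tree A `phylo` object.
#' @param constraint A `topology_constraint` (or `NULL`, always satisfied).
#' @return Logical.
#' @export
check_constraint <- function(tree, constraint) {
  if (is.null(constraint)) return(TRUE)
  mono <- has_split(tree, constraint$taxa)
  if (constraint$mode == "monophyletic") mono else !mono
}

#' Robinson-Foulds distance between two unrooted trees
#' @param t1,t2 `phylo` objects over the same tip labels.
#' @return Number of bipartitions present in exactly one tree.
#' @export
rf_dist <- function(t1, t2) {
  s1 <- names(tree_splits(t1)); s2 <- names(tree_splits(t2))
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

topology_key <- function(tree) {
  paste(sort(names(tree_splits(tree))), collapse = ";")
}

# ---- adjacency representation ---------------------------------------------

# graph: list(labels, n_tips, adj = list of integer neighbor vectors,
#             len = named numeric, names "i-j" with i < j)
edge_name <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))

phylo_to_graph <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  adj <- vector("list", nn)
  len <- numeric(0)
  el <- tree$edge.length %||% rep(0.1, nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    len[edge_name(a, b)] <- el[k]
  }
  list(labels = tree$tip.label, n_tips = n,
       adj = lapply(adj, sort), len = len)
}

graph_to_phylo <- function(g) {
  n <- g$n_tips
  nn <- length(g$adj)
  root <- if (nn > n) n + 1L else 1L
  # renumber: tips keep 1..n; internals numbered in DFS preorder from root
  newid <- integer(nn)
  newid[seq_len(n)] <- seq_len(n)
  counter <- n
  edges <- matrix(0L, 0L, 2L); elen <- numeric(0)
  stack <- list(c(root, 0L))
  order_nodes <- integer(0)
  # iterative DFS assigning ids and collecting edges
  visit <- function(node, parent) {
    if (node > n) {
      counter <<- counter + 1L
      newid[node] <<- counter
    }
    for (nb in g$adj[[node]]) {
      if (nb != parent) {
        visit(nb, node)
        edges <<- rbind(edges, c(node, nb))
        elen <<- c(elen, g$len[[edge_name(node, nb)]])
      }
    }
  }
  visit(root, 0L)
  edge <- cbind(newid[edges[, 1L]], newid[edges[, 2L]])
  tr <- list(edge = edge, edge.length = elen, Nnode = nn - n,
             tip.label = g$labels)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

# internal edges of a graph (both endpoints internal), deterministic order
internal_edges <- function(g) {
  out <- matrix(0L, 0L, 2L)
  for (u in (g$n_tips + 1L):length(g$adj)) {
    for (v in g$adj[[u]]) {
      if (v > g$n_tips && u < v) out <- rbind(out, c(u, v))
    }
  }
  out
}

# one NNI rearrangement: across internal edge (u,v), swap subtree at
# u-neighbor `x` with subtree at v-neighbor `y`
nni_apply <- function(g, u, v, x, y) {
  g$adj[[u]] <- sort(c(setdiff(g$adj[[u]], x), y))
  g$adj[[v]] <- sort(c(setdiff(g$adj[[v]], y), x))
  g$adj[[x]] <- sort(c(setdiff(g$adj[[x]], u), v))
  g$adj[[y]] <- sort(c(setdiff(g$adj[[y]], v), u))
  lx <- g$len[[edge_name(u, x)]]; ly <- g$len[[edge_name(v, y)]]
  g$len <- g$len[setdiff(names(g$len), c(edge_name(u, x), edge_name(v, y)))]
  g$len[edge_name(u, y)] <- ly
  g$len[edge_name(v, x)] <- lx
  g
}

# all NNI neighbors of an unrooted binary tree (2 per internal edge)
nni_neighbors <- function(tree) {
  g <- phylo_to_graph(tree)
  ie <- internal_edges(g)
  out <- list()
  for (k in seq_len(nrow(ie))) {
    u <- ie[k, 1L]; v <- ie[k, 2L]
    a <- setdiff(g$adj[[u]], v)
    cd <- setdiff(g$adj[[v]], u)
    # swapping a[2] with each neighbor of v gives both alternative topologies
    for (y in cd) {
      out[[length(out) + 1L]] <- graph_to_phylo(nni_apply(g, u, v, a[2L], y))
    }
  }
  out
}

# ---- topology generators ---------------------------------------------------

#' Random unrooted binary topology by sequential addition
#'
#' Tips are attached in random order to uniformly chosen edges; branch
#' lengths are drawn from an exponential distribution.
#'
#' @param labels Tip labels (>= 3).
#' @param mean_edge Mean of the exponential edge-length draw.
#' @return A `phylo` object.
#' @export
random_topology <- function(labels, mean_edge = 0.1) {
  n <- length(labels)
  stopifnot(n >= 3L)
  ord <- sample.int(n)
  # start from the 3-tip star
  g <- list(labels = labels, n_tips = n, adj = vector("list", n + 1L),
            len = numeric(0))
  center <- n + 1L
  g$adj[[center]] <- sort(ord[1:3])
  for (t in ord[1:3]) {
    g$adj[[t]] <- center
    g$len[edge_name(t, center)] <- rexp(1, 1 / mean_edge)
  }
  next_int <- n + 1L
  for (i in seq(4L, length.out = n - 3L)) {
    tip <- ord[i]
    # choose an existing edge uniformly
    enames <- sort(names(g$len))
    pick <- enames[sample.int(length(enames), 1L)]
    uv <- as.integer(strsplit(pick, "-", fixed = TRUE)[[1L]])
    u <- uv[1L]; v <- uv[2L]
    next_int <- next_int + 1L
    w <- next_int
    lo <- g$len[[pick]]
    g$len <- g$len[setdiff(names(g$len), pick)]
    g$adj[[u]] <- sort(c(setdiff(g$adj[[u]], v), w))
    g$adj[[v]] <- sort(c(setdiff(g$adj[[v]], u), w))
    g$adj[[w]] <- sort(c(u, v, tip))
    g$adj[[tip]] <- w
    frac <- runif(1)
    g$len[edge_name(u, w)] <- lo * frac
    g$len[edge_name(v, w)] <- lo * (1 - frac)
    g$len[edge_name(tip, w)] <- rexp(1, 1 / mean_edge)
  }
  graph_to_phylo(g)
}

#' Build a tree satisfying a monophyly-type constraint
#'
#' Deterministic construction: for a monophyly constraint, a caterpillar of
#' the constrained taxa attached next to a caterpillar of the rest; for
#' non-monophyly, an alternating arrangement that breaks the split.
#'
#' @param labels All tip labels.
#' @param constraint A `topology_constraint` or `NULL`.
#' @param edge Branch length used throughout.
#' @return A `phylo` object satisfying the constraint.
#' @export
constrained_start_tree <- function(labels, constraint, edge = 0.05) {
  labels <- sort(labels)
  mk <- function(ordered) {
    # caterpillar over ordered labels
    nwk <- paste0(ordered[1L], ":", edge)
    for (i in 2:length(ordered)) {
      nwk <- paste0("(", nwk, ",", ordered[i], ":", edge, "):", edge)
    }
    ape::unroot(ape::read.tree(text = paste0(nwk, ";")))
  }
  if (is.null(constraint)) return(mk(labels))
  inside <- sort(constraint$taxa)
  outside <- sort(setdiff(labels, inside))
  if (constraint$mode == "monophyletic") {
    tr <- mk(c(inside, outside))
    if (!check_constraint(tr, constraint)) stop2("Could not build constrained start tree")
    return(tr)
  }
  if (length(outside) == 0L) stop2("No tree can violate monophyly of all taxa")
  # interleave so the constrained set is broken up
  ord <- c(inside[1L], outside[1L], inside[-1L], outside[-1L])
  tr <- mk(ord)
  if (!check_constraint(tr, constraint)) {
    stop2("Could not build a non-monophyletic start tree for this taxon set")
  }
  tr
}
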