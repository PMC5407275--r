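# Shared helpers: independent likelihood oracles and small fixtures.

# matrix exponential by plain series summation (independent of the
# eigendecomposition used in the package)
expm_series <- function(Q, t, terms = 80L) {
  S <- diag(4); term <- diag(4)
  for (k in seq_len(terms)) {
    term <- term %*% (Q * t) / k
    S <- S + term
  }
  S
}

# brute-force tree likelihood: enumerate all internal-node state
# assignments per site; transition matrices via expm_series; discrete-Gamma
# categories averaged with equal weights
enum_loglik <- function(tree, model, amatrix) {
  tree <- if (length(tree$tip.label) > 2) ape::unroot(tree) else tree
  eo <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(eo$tip.label)
  nn <- ntip + eo$Nnode
  root <- eo$edge[nrow(eo$edge), 1]
  internals <- sort(unique(as.vector(eo$edge[eo$edge > ntip])))
  rates <- gamma_rates(model$alpha, model$ncat)
  Q <- model$eig$Q
  pi <- model$freqs
  bases <- c("A", "C", "G", "T")
  iupac <- list(A="A",C="C",G="G",T="T",R=c("A","G"),Y=c("C","T"),
                S=c("C","G"),W=c("A","T"),K=c("G","T"),M=c("A","C"),
                B=c("C","G","T"),D=c("A","G","T"),H=c("A","C","T"),
                V=c("A","C","G"),N=bases)
  tipsets <- lapply(seq_len(ntip), function(i) {
    lapply(amatrix$matrix[eo$tip.label[i], ], function(ch) {
      if (ch == "-") bases else iupac[[ch]]
    })
  })
  total <- 0
  for (site in seq_len(amatrix$length)) {
    site_lik <- 0
    for (r in rates) {
      P <- lapply(seq_len(nrow(eo$edge)), function(k)
        expm_series(Q, eo$edge.length[k] * r))
      grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign <- integer(nn)
        assign[internals] <- grid[g, ]
        term <- unname(pi[assign[root]])
        for (k in seq_len(nrow(eo$edge))) {
          p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
          if (ch <= ntip) {
            ok <- match(tipsets[[ch]][[site]], bases)
            term <- term * sum(P[[k]][assign[p], ok])
          } else {
            term <- term * P[[k]][assign[p], assign[ch]]
          }
        }
        lik <- lik + term
      }
      site_lik <- site_lik + lik / length(rates)
    }
    total <- total + log(site_lik)
  }
  total
}

# quick simulated alignment + scheme fixture
sim_fixture <- function(n_taxa, codons, seed, divergence = 0.2,
                        scheme_type = "none", model = sub_model("JC69")) {
  spec <- simulation_spec(n_taxa, divergence = divergence,
                          length_codons = codons, seed = seed)
  tr <- simulate_tree(spec)
  am <- simulate_alignment(tr, spec)
  sch <- partition_scheme(am, scheme_type, model = model)
  list(tree = tr, am = am, scheme = sch, spec = spec)
}

# independent monophyly oracle: root at an outgroup tip and compare the
# MRCA's descendant set with the taxon set
mono_oracle <- function(tree, taxa) {
  out <- setdiff(tree$tip.label, taxa)
  rooted <- ape::root(tree, outgroup = out[1], resolve.root = TRUE)
  mrca <- ape::getMRCA(rooted, taxa)
  desc <- ape::extract.clade(rooted, mrca)$tip.label
  setequal(desc, taxa)
}

# all unrooted binary topologies over the given labels, by recursive tip
# addition to every edge (15 trees for 5 labels), all edges set to `edge`
all_topologies <- function(labels, edge = 0.05) {
  stopifnot(length(labels) >= 4)
  base <- ape::unroot(ape::read.tree(
    text = sprintf("((%s,%s),%s);", labels[1], labels[2], labels[3])))
  base$edge.length <- rep(edge, nrow(base$edge))
  trees <- list(base)
  for (lab in labels[-(1:3)]) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        tip <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                              tip.label = lab, edge.length = edge,
                              Nnode = 1L), class = "phylo")
        t2 <- ape::bind.tree(tr, tip, where = tr$edge[e, 2],
                             position = edge / 2)
        t2 <- ape::unroot(t2)
        t2$edge.length <- rep(edge, nrow(t2$edge))
        nxt[[length(nxt) + 1]] <- t2
      }
    }
    trees <- nxt
  }
  keys <- vapply(trees, barcodeaudit:::topology_key, character(1))
  trees[!duplicated(keys)]
}
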