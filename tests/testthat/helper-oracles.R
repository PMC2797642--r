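# Independent oracles used across the suite.  These deliberately avoid
# the package's own computational paths: rate matrices are rebuilt from
# their definition, matrix exponentials come from Matrix::expm, tree
# likelihoods from exhaustive enumeration over internal states, and SPR
# neighborhoods from a plain loop over edges deduplicated by
# phangorn::RF.dist.

# Q_ij = S_ij pi_j, rows sum to zero, mean rate 1 -- straight from the
# definition, no shared code with build_rate_matrix().
oracle_Q <- function(S, pi) {
  Q <- sweep(S, 2, pi, "*")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

oracle_pmat <- function(model, t) {
  Q <- oracle_Q(model$S, model$pi)
  as.matrix(Matrix::expm(Q * t))
}

# Exhaustive-state tree likelihood: sums over all assignments of internal
# node states, per rate category, then applies the +I mixture.  Feasible
# for <= 3 internal nodes (unrooted trees of <= 5 taxa).
oracle_site_ll <- function(tree, aln, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  stopifnot(nint <= 3)
  states <- aln$states[tree$tip.label, , drop = FALSE]
  nsites <- ncol(states)
  rates <- if (model$gamma) discrete_gamma_rates(model$alpha, model$k) else 1
  root <- tree$edge[nrow(tree$edge), 1]
  grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
  colnames(grid) <- NULL
  site_ll <- numeric(nsites)
  Ls <- matrix(0, length(rates), nsites)
  for (ci in seq_along(rates)) {
    P <- lapply(tree$edge.length, function(el)
      oracle_pmat(model, rates[ci] * el))
    for (s in seq_len(nsites)) {
      f <- model$pi[grid[, root - ntip]]
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        pstate <- grid[, par - ntip]
        if (ch <= ntip) {
          obs <- states[ch, s]
          f <- f * if (is.na(obs)) 1 else P[[e]][cbind(pstate, obs)]
        } else {
          f <- f * P[[e]][cbind(pstate, grid[, ch - ntip])]
        }
      }
      Ls[ci, s] <- sum(f)
    }
  }
  inv <- apply(states, 2, function(col) {
    obs <- unique(col[!is.na(col)])
    if (length(obs) == 0) 1 else if (length(obs) == 1) model$pi[obs] else 0
  })
  log(model$p_inv * inv + (1 - model$p_inv) * colMeans(Ls))
}

# All distinct topologies obtainable by regrafting `focal` onto any edge
# of the backbone, deduplicated by Robinson-Foulds distance.
oracle_regraft_count <- function(tree, focal) {
  ext <- extract_clade(tree, focal)
  pruned <- ape::reorder.phylo(ext$pruned, "postorder")
  cands <- list()
  for (e in seq_len(nrow(pruned$edge))) {
    cands[[e]] <- graft_clade(pruned, ext$focal_tree, e)
  }
  keep <- list()
  for (cand in cands) {
    dup_base <- phangorn::RF.dist(ape::unroot(cand),
                                  ape::unroot(tree)) == 0
    dup_prev <- any(vapply(keep, function(k)
      phangorn::RF.dist(ape::unroot(cand), ape::unroot(k)) == 0, TRUE))
    if (!dup_base && !dup_prev) keep[[length(keep) + 1]] <- cand
  }
  length(keep)
}

# random binary unrooted tree over given labels with uniform(0.05, 0.5)
# branch lengths -- small fixture factory for property tests
rand_tree <- function(labels, min_len = 0.05, max_len = 0.5) {
  tr <- ape::unroot(ape::rtree(length(labels), tip.label = labels))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

rand_aln <- function(labels, nsites) {
  m <- matrix(sample(1:20, length(labels) * nsites, replace = TRUE),
              nrow = length(labels))
  rownames(m) <- labels
  aa_alignment(m)
}

# every clade of an unrooted tree = each bipartition side
all_clades <- function(tree) {
  els <- lgtplace:::edge_leaf_sets(tree)
  labs <- tree$tip.label
  sides <- c(els$child_sets,
             lapply(els$child_sets, function(s) sort(setdiff(labs, s))))
  unique(sides)
}
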