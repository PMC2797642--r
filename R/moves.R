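# Clade extraction and constrained regrafting: the machinery that turns
# one base tree plus a focal clade into the set of alternative placements
# a topology test compares.  All semantics are unrooted; ape's rooted
# edge-matrix representation is only an encoding.

# Leaf labels below each edge (child side), in the tree's own edge order.
edge_leaf_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  list(tree = tree,
       child_sets = lapply(tree$edge[, 2], function(n) sort(sets[[n]])))
}

# Canonical keys of all non-trivial bipartitions of an unrooted tree.
tree_split_keys <- function(tree) {
  els <- edge_leaf_sets(tree)
  labels <- sort(tree$tip.label)
  ref <- labels[1]
  keys <- vapply(els$child_sets, function(s) {
    if (length(s) <= 1L || length(s) >= length(labels) - 1L) return(NA_character_)
    side <- if (ref %in% s) s else setdiff(labels, s)
    paste(sort(side), collapse = "\r")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees; zero iff the topologies are identical.
#'
#' @param tree1,tree2 `phylo` objects over the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label) ||
      length(tree1$tip.label) != length(tree2$tip.label))
    stop("trees have different leaf sets")
  s1 <- tree_split_keys(tree1)
  s2 <- tree_split_keys(tree2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Is a taxon set monophyletic (unrooted sense)?
#'
#' True iff some edge of the tree bipartitions `taxa` against all other
#' leaves.  Singletons, the full leaf set and complements of singletons
#' are trivially monophyletic.
#'
#' @param tree a `phylo`.
#' @param taxa character vector of leaf labels.
#' @return logical scalar.
#' @export
check_monophyly <- function(tree, taxa) {
  taxa <- unique(taxa)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("missing taxon in tree: ", paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  k <- length(taxa)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  els <- edge_leaf_sets(tree)
  sizes <- lengths(els$child_sets)
  for (i in which(sizes == k | sizes == n - k)) {
    s <- els$child_sets[[i]]
    # either side of the bipartition may carry the set (note k may equal
    # n - k, so both tests must run)
    if (length(s) == k && all(s %in% taxa)) return(TRUE)
    if (length(s) == n - k && !any(s %in% taxa)) return(TRUE)
  }
  FALSE
}

# Root the tree at a leaf outside `taxa` so the set, if monophyletic,
# appears as the child side of a single edge.
root_outside <- function(tree, taxa) {
  out <- setdiff(tree$tip.label, taxa)
  if (!length(out)) stop("taxon set spans the whole tree")
  ape::root(tree, outgroup = out[1], resolve.root = TRUE)
}

#' Extract a focal clade from a tree
#'
#' Splits a tree into the focal subtree and the backbone ("pruned") tree.
#' The degree-2 node left behind is suppressed and its two incident edge
#' lengths are summed.  The focal set must be exactly monophyletic; a set
#' that is not a clade is an error (no silent MRCA superset).
#'
#' @param tree a `phylo`.
#' @param focal character vector of leaf labels forming a clade.
#' @return list with `focal_tree` (a `phylo`, possibly single-tip),
#'   `pruned` (unrooted backbone), `stem_length` (the focal stem branch),
#'   and `attachment_split` (leaf labels on the pruned-tree side of the
#'   edge where the clade was attached; regrafting there regenerates the
#'   base topology).
#' @export
extract_clade <- function(tree, focal) {
  focal <- unique(focal)
  if (!check_monophyly(tree, focal))
    stop("invalid clade: focal taxa are not monophyletic")
  n <- length(tree$tip.label)
  if (length(focal) >= n - 1L)
    stop("focal clade must leave at least 2 backbone leaves")
  rt <- root_outside(tree, focal)
  els <- edge_leaf_sets(rt)
  rt <- els$tree
  hit <- which(vapply(els$child_sets, function(s)
    length(s) == length(focal) && all(s %in% focal), TRUE))
  if (!length(hit)) stop("invalid clade: focal taxa are not monophyletic")
  e <- hit[1]
  stem_length <- rt$edge.length[e]
  node <- rt$edge[e, 2]
  focal_tree <- if (length(focal) == 1L) {
    structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = focal,
                   edge.length = stem_length, Nnode = 1L),
              class = "phylo")
  } else ape::extract.clade(rt, node)
  pruned <- ape::unroot(ape::drop.tip(rt, focal))
  # the merged edge: the split induced by the old attachment point
  sib <- setdiff(els$child_sets[[which(rt$edge[, 2] == rt$edge[e, 1])[1]]],
                 focal)
  if (!length(sib)) { # focal hung off the root: take any root-child side
    root_node <- setdiff(rt$edge[, 1], rt$edge[, 2])
    kids <- which(rt$edge[, 1] == root_node)
    kids <- setdiff(kids, e)
    sib <- setdiff(els$child_sets[[kids[1]]], focal)
  }
  list(focal_tree = focal_tree, pruned = pruned, stem_length = stem_length,
       attachment_split = sort(sib))
}

#' Regraft a subtree onto an edge of a backbone tree
#'
#' Splits the target edge at its midpoint (by default) and attaches the
#' subtree there with a stem of half the broken edge's length, the
#' initialization used throughout this package (branch lengths are
#' typically re-optimized downstream).
#'
#' @param backbone a `phylo`.
#' @param subtree a `phylo` (may be single-tip).
#' @param edge index of the target edge row in `backbone$edge`.
#' @param stem_length graft stem length; default half the broken edge.
#' @return a `phylo` over the union of the two leaf sets.
#' @export
graft_clade <- function(backbone, subtree, edge,
                        stem_length = backbone$edge.length[edge] / 2) {
  el <- backbone$edge.length[edge]
  child <- backbone$edge[edge, 2]
  if (length(subtree$tip.label) == 1L) {
    subtree$edge.length <- stem_length + subtree$edge.length
    subtree$root.edge <- NULL
  } else {
    subtree$root.edge <- stem_length
  }
  ape::bind.tree(backbone, subtree, where = child, position = el / 2)
}

#' Placement constraints
#'
#' @param protected list of leaf-label sets that must stay monophyletic;
#'   no attachment is allowed strictly inside them (their stem edge is a
#'   legal attachment point).
#' @param support_threshold edges carrying a support label at or above
#'   this value may not be used as attachment points; default 70, the
#'   common "strongly supported" bootstrap convention.
#' @param scope optional leaf-label set: only edges within (or the stem
#'   of) the clade spanned by these leaves are candidates.
#' @return an object of class `placement_constraints`.
#' @export
placement_constraints <- function(protected = list(),
                                  support_threshold = 70, scope = NULL) {
  stopifnot(is.list(protected), is.numeric(support_threshold),
            is.finite(support_threshold))
  structure(list(protected = lapply(protected, unique),
                 support_threshold = support_threshold,
                 scope = if (is.null(scope)) NULL else unique(scope)),
            class = "placement_constraints")
}

# numeric support value carried by each edge (label of its child node),
# NA for pendant edges or unlabeled nodes
edge_support <- function(tree) {
  ntip <- length(tree$tip.label)
  supp <- rep(NA_real_, nrow(tree$edge))
  if (!is.null(tree$node.label)) {
    internal <- tree$edge[, 2] > ntip
    lab <- tree$node.label[tree$edge[internal, 2] - ntip]
    supp[internal] <- suppressWarnings(as.numeric(lab))
  }
  supp
}

#' Enumerate constrained alternative placements of a focal clade
#'
#' Removes the focal clade and regrafts it, one tree per legal candidate
#' edge of the backbone.  A candidate edge must (a) lie within `scope`
#' when given (the scope clade's stem edge included), (b) not be strictly
#' internal to any protected clade, and (c) carry no support label at or
#' above the support threshold.  The placement that regenerates the base
#' topology is excluded, and duplicate topologies are removed.  Ordering
#' follows the backbone's postorder edge indices, so the enumeration is
#' deterministic.
#'
#' @param tree base `phylo`.
#' @param focal leaf labels of the (monophyletic) focal clade.
#' @param constraints a [placement_constraints()] object.
#' @return an object of class `topology_set`: list with `base_tree`,
#'   `focal`, and `alternatives`, each alternative holding `tree`, `edge`
#'   (backbone edge index) and `split` (leaf labels below that edge).
#' @export
enumerate_placements <- function(tree, focal,
                                 constraints = placement_constraints()) {
  ext <- extract_clade(tree, focal)
  pruned <- ape::reorder.phylo(ext$pruned, "postorder")
  els <- edge_leaf_sets(pruned)
  pruned <- els$tree
  sets <- els$child_sets
  all_leaves <- sort(pruned$tip.label)
  supp <- edge_support(pruned)
  cons <- constraints
  for (p in cons$protected) {
    if (length(setdiff(p, tree$tip.label)))
      stop("protected clade names unknown taxa")
    p2 <- setdiff(p, focal)
    if (length(p2) > 1L && !check_monophyly(pruned, p2))
      stop("protected clade is not monophyletic in the pruned tree")
  }
  ok <- rep(TRUE, nrow(pruned$edge))
  if (!is.null(cons$scope)) {
    sc <- setdiff(cons$scope, focal)
    ok <- ok & vapply(sets, function(s) {
      other <- setdiff(all_leaves, s)
      all(s %in% sc) || all(other %in% sc)
    }, TRUE)
  }
  for (p in cons$protected) {
    p2 <- setdiff(p, focal)
    if (length(p2) <= 1L) next
    ok <- ok & !vapply(sets, function(s) {
      other <- setdiff(all_leaves, s)
      (all(s %in% p2) && length(s) < length(p2)) ||
        (all(other %in% p2) && length(other) < length(p2))
    }, TRUE)
  }
  ok <- ok & (is.na(supp) | supp < cons$support_threshold)
  base_keys <- tree_split_keys(tree)
  seen <- character()
  alternatives <- list()
  for (e in which(ok)) {
    cand <- graft_clade(pruned, ext$focal_tree, e)
    keys <- tree_split_keys(cand)
    sig <- paste(sort(keys), collapse = ";")
    if (setequal(keys, base_keys)) next
    if (sig %in% seen) next
    seen <- c(seen, sig)
    alternatives[[length(alternatives) + 1L]] <-
      list(tree = cand, edge = e, split = sets[[e]])
  }
  if (!length(alternatives))
    warning("no legal alternative placements under these constraints")
  structure(list(base_tree = tree, focal = sort(unique(focal)),
                 pruned = pruned, alternatives = alternatives),
            class = "topology_set")
}

#' @export
print.topology_set <- function(x, ...) {
  cat(sprintf("topology_set: base tree (%d leaves) + %d alternative placement(s) of {%s}\n",
              length(x$base_tree$tip.label), length(x$alternatives),
              paste(utils::head(x$focal, 3), collapse = ",")))
  invisible(x)
}

#' Write a topology set as multi-tree Newick
#'
#' Base tree first, then each alternative, one Newick string per line.
#'
#' @param ts a `topology_set`.
#' @param path output file.
#' @param header optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_topology_set <- function(ts, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(ape::write.tree(ts$base_tree), con)
  for (a in ts$alternatives) writeLines(ape::write.tree(a$tree), con)
  invisible(path)
}
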