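# Synthetic gene families with a known lateral-gene-transfer history.
#
# The generator emulates the structure of a glycosyl-hydrolase-family-5
# style data set: two "bacterial" sub-family clades and one "symbiont"
# focal clade, ~40-100 taxa, a few hundred aligned amino-acid sites
# evolved under an empirical model with discrete-gamma rates and invariant
# sites.  An optional LGT event prunes the symbiont clade from its
# species-tree position and regrafts it inside bacterial sub-family 1.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Sample a random unrooted tree
#'
#' Coalescent-style random topology (every labeled shape from sequential
#' random joins) with independent exponential branch lengths.
#'
#' @param ntaxa number of leaves (>= 4); labels are `T0001`, `T0002`, ...
#' @param branch_scale mean branch length, in expected substitutions per
#'   site (default 0.1).
#' @param seed integer seed; identical seeds give identical trees.
#' @return an unrooted binary `phylo`.
#' @export
sample_tree <- function(ntaxa, branch_scale = 0.1, seed = NULL) {
  if (ntaxa < 4) stop("invalid input: ntaxa must be >= 4")
  if (!is.finite(branch_scale) || branch_scale <= 0)
    stop("invalid input: branch_scale must be positive")
  with_seed(seed, {
    tr <- ape::unroot(ape::rcoal(ntaxa,
                                 tip.label = sprintf("T%04d", seq_len(ntaxa))))
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / branch_scale)
    tr
  })
}

#' LGT scenario
#'
#' Bundles a species tree, a focal ("symbiont") clade, the donor edge the
#' clade is transferred onto, and the protected constraint clades.
#'
#' @param species_tree a `phylo`; `focal_taxa` must be monophyletic in it.
#' @param focal_taxa leaf labels of the focal clade.
#' @param donor_edge leaf labels below the donor edge of the backbone
#'   (species tree minus focal clade); must lie strictly inside one
#'   constraint clade.
#' @param constraint_clades list of leaf-label sets (pairwise disjoint or
#'   properly nested) that must stay monophyletic.
#' @return an object of class `lgt_scenario`.
#' @export
lgt_scenario <- function(species_tree, focal_taxa, donor_edge,
                         constraint_clades = list()) {
  if (!check_monophyly(species_tree, focal_taxa))
    stop("focal taxa are not monophyletic in the species tree")
  for (i in seq_along(constraint_clades))
    for (j in seq_len(i - 1L)) {
      a <- constraint_clades[[i]]; b <- constraint_clades[[j]]
      inter <- length(intersect(a, b))
      if (inter > 0 && inter < min(length(a), length(b)))
        stop("constraint clades must be pairwise disjoint or nested")
    }
  scope <- Filter(function(cl) all(donor_edge %in% setdiff(cl, focal_taxa)) &&
                    length(setdiff(cl, focal_taxa)) > length(donor_edge),
                  constraint_clades)
  if (!length(scope))
    stop("donor edge must lie strictly inside one constraint clade")
  structure(list(species_tree = species_tree,
                 focal_taxa = sort(unique(focal_taxa)),
                 donor_edge = sort(unique(donor_edge)),
                 constraint_clades = constraint_clades),
            class = "lgt_scenario")
}

#' Build the gene tree implied by an LGT scenario
#'
#' Prunes the focal clade from the species tree and regrafts it onto the
#' donor edge, splitting that edge at its midpoint with a graft stem of
#' half the donor edge length.  All other relationships are unchanged.
#'
#' @param scenario an [lgt_scenario()].
#' @return a `phylo` gene tree.
#' @export
build_lgt_gene_tree <- function(scenario) {
  stopifnot(inherits(scenario, "lgt_scenario"))
  ext <- extract_clade(scenario$species_tree, scenario$focal_taxa)
  pruned <- ape::reorder.phylo(ext$pruned, "postorder")
  sets <- edge_leaf_sets(pruned)
  pruned <- sets$tree
  all_leaves <- pruned$tip.label
  hit <- which(vapply(sets$child_sets, function(s)
    setequal(s, scenario$donor_edge) ||
      setequal(setdiff(all_leaves, s), scenario$donor_edge), TRUE))
  if (!length(hit))
    stop("donor edge not found in the pruned species tree")
  s <- sets$child_sets[[hit[1]]]
  if (setequal(s, ext$attachment_split) ||
      setequal(setdiff(all_leaves, s), ext$attachment_split))
    stop("degenerate move: donor edge regenerates the species tree")
  graft_clade(pruned, ext$focal_tree, hit[1])
}

#' Simulate an amino-acid alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies; each
#' site is invariant with probability `p_inv` or assigned one of the
#' discrete-gamma rate categories; states then evolve down each branch by
#' the model's transition probabilities.  Columns are independent.
#'
#' @param tree a `phylo` with branch lengths.
#' @param model an `aa_model`.
#' @param nsites number of alignment columns.
#' @param seed integer seed.
#' @param missing_frac optional i.i.d. per-cell probability of masking a
#'   state as missing (default 0).
#' @return an `aa_alignment` over the tree's leaves.
#' @export
simulate_alignment <- function(tree, model, nsites, seed = NULL,
                               missing_frac = 0) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "aa_model"))
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("tree must have at least 2 leaves")
  nsites <- as.integer(nsites)
  if (nsites < 1) stop("nsites must be positive")
  with_seed(seed, {
    tr <- ape::reorder.phylo(tree, "postorder")
    eig <- model_eigen(model)
    gam <- model_rates(model)
    # per-site rate: 0 with prob p_inv, else a gamma category
    rate_id <- ifelse(stats::runif(nsites) < model$p_inv, 0L,
                      sample.int(length(gam), nsites, replace = TRUE))
    site_rate <- c(0, gam)[rate_id + 1L]
    nnode <- ntip + tr$Nnode
    states <- matrix(0L, nnode, nsites)
    root <- tr$edge[nrow(tr$edge), 1]
    states[root, ] <- sample.int(20L, nsites, replace = TRUE,
                                 prob = model$pi)
    rate_levels <- sort(unique(site_rate))
    for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder: parents first
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; len <- tr$edge.length[e]
      for (r in rate_levels) {
        idx <- which(site_rate == r)
        if (!length(idx)) next
        if (r == 0 || len == 0) {
          states[ch, idx] <- states[p, idx]
        } else {
          P <- transition_matrix(model, r * len, eig)
          ps <- states[p, idx]
          for (s in unique(ps)) {
            ii <- idx[ps == s]
            states[ch, ii] <- sample.int(20L, length(ii), replace = TRUE,
                                         prob = P[s, ])
          }
        }
      }
    }
    tips <- states[seq_len(ntip), , drop = FALSE]
    rownames(tips) <- tr$tip.label
    if (missing_frac > 0)
      tips[stats::runif(length(tips)) < missing_frac] <- NA_integer_
    aa_alignment(tips)
  })
}

#' GHF5-like synthetic bundle
#'
#' Generates everything one pipeline run needs: a gene family with two
#' bacterial sub-family clades (`SF1_*`, `SF2_*`), a symbiont focal clade
#' (`SYM_*`) and a small outgroup (`OUT_*`), plus an alignment simulated
#' on the true tree.  With `lgt = TRUE` the symbiont clade is nested
#' inside sub-family 1 (via [build_lgt_gene_tree()]); otherwise it
#' attaches outside both sub-families ("vertical" history).  Defaults
#' give 60 taxa by 300 sites under WAG+G+I.
#'
#' @param lgt logical: simulate a transfer event?
#' @param n_sf1,n_sf2 bacterial sub-family sizes (default 22 each).
#' @param n_focal symbiont clade size (default 12).
#' @param n_out outgroup size (default 4).
#' @param nsites alignment length (default 300).
#' @param model an `aa_model` (default `WAG+G+I` with alpha 0.8,
#'   p_inv 0.1).
#' @param branch_scale mean within-clade branch length (default 0.08).
#' @param stem_scale backbone branch length separating the major clades
#'   (default 0.4): deep enough that nested versus vertical placements
#'   are distinguishable at a few hundred sites.
#' @param seed integer seed.
#' @return list with `alignment`, `true_tree`, `vertical_tree`,
#'   `lgt_tree`, `focal_taxa`, `constraint_clades` (the sub-sub-family
#'   analogs, the clades a real analysis would protect), `subfamilies`
#'   (the full `sf1`/`sf2` leaf sets), `scenario`, `lgt`, `model`.
#' @export
ghf5_like_bundle <- function(lgt = TRUE, n_sf1 = 22L, n_sf2 = 22L,
                             n_focal = 12L, n_out = 4L, nsites = 300L,
                             model = aa_model("WAG+G+I", alpha = 0.8,
                                              p_inv = 0.1),
                             branch_scale = 0.08, stem_scale = 0.4,
                             seed = NULL) {
  if (n_sf1 < 3L || n_sf2 < 3L || n_focal < 2L || n_out < 1L)
    stop("clade sizes too small for a GHF5-like scenario")
  with_seed(seed, {
    # each clade is a coalescent shape; its two root subclades play the
    # role of "sub-sub-families" (the strongly supported groups a real
    # analysis would protect)
    make_clade <- function(n, prefix) {
      if (n == 1L) {
        lab <- sprintf("%s_01", prefix)
        return(list(nwk = lab, ssf = list(lab)))
      }
      tr <- ape::rcoal(n, tip.label = sprintf("%s_%02d", prefix, seq_len(n)))
      tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / branch_scale)
      kids <- tr$edge[tr$edge[, 1] == n + 1L, 2]
      ssf <- lapply(kids, function(k) {
        if (k <= n) tr$tip.label[k] else ape::extract.clade(tr, k)$tip.label
      })
      list(nwk = sub(";$", "", ape::write.tree(tr)), ssf = ssf)
    }
    cl_sf1 <- make_clade(n_sf1, "SF1")
    cl_sf2 <- make_clade(n_sf2, "SF2")
    cl_sym <- make_clade(n_focal, "SYM")
    cl_out <- make_clade(n_out, "OUT")
    stem <- function() stats::rexp(1, rate = 1 / stem_scale)
    nwk <- sprintf("((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g);",
                   cl_sf1$nwk, stem(), cl_sf2$nwk, stem(), stem(),
                   cl_sym$nwk, stem(), cl_out$nwk, stem(), stem())
    species_tree <- ape::unroot(ape::read.tree(text = nwk))
    sf1 <- sprintf("SF1_%02d", seq_len(n_sf1))
    sf2 <- sprintf("SF2_%02d", seq_len(n_sf2))
    sym <- sprintf("SYM_%02d", seq_len(n_focal))
    ssfs <- c(cl_sf1$ssf, cl_sf2$ssf)
    constraint_clades <- Filter(function(s) length(s) >= 2L, ssfs)
    names(constraint_clades) <- sprintf("ssf_%d",
                                        seq_along(constraint_clades))
    # donor edge: a clade of about half the largest sub-sub-family of SF1
    host <- cl_sf1$ssf[[which.max(lengths(cl_sf1$ssf))]]
    sets <- edge_leaf_sets(species_tree)
    inside <- Filter(function(s) all(s %in% host) &&
                       length(s) < length(host), sets$child_sets)
    sizes <- vapply(inside, length, 1L)
    donor <- inside[[which.min(abs(sizes - length(host) / 2))]]
    scenario <- lgt_scenario(species_tree, focal_taxa = sym,
                             donor_edge = donor,
                             constraint_clades = constraint_clades)
    lgt_tree <- build_lgt_gene_tree(scenario)
    true_tree <- if (lgt) lgt_tree else species_tree
    alignment <- simulate_alignment(true_tree, model, nsites)
    list(alignment = alignment, true_tree = true_tree,
         vertical_tree = species_tree, lgt_tree = lgt_tree,
         focal_taxa = sym, constraint_clades = constraint_clades,
         subfamilies = list(sf1 = sf1, sf2 = sf2),
         scenario = scenario, lgt = lgt, model = model)
  })
}
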