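quartet <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("monophyly check follows unrooted bipartition semantics", {
  expect_true(check_monophyly(quartet, c("A", "B")))
  expect_false(check_monophyly(quartet, c("A", "C")))
  expect_true(check_monophyly(quartet, c("A", "B", "C", "D")))
  expect_true(check_monophyly(quartet, "C"))
  expect_true(check_monophyly(quartet, c("A", "B", "C")))  # complement of D
  expect_error(check_monophyly(quartet, "Z"), "missing taxon")

  set.seed(61)
  tr <- rand_tree(sprintf("t%d", 1:12))
  els <- lgtplace:::edge_leaf_sets(tr)
  for (s in els$child_sets) expect_true(check_monophyly(tr, s))
})

test_that("clade extraction conserves leaves, lengths and structure", {
  ext <- extract_clade(quartet, "A")
  expect_identical(sort(ext$pruned$tip.label), c("B", "C", "D"))
  expect_identical(ext$pruned$Nnode, 1L)          # 3-taxon star
  expect_identical(nrow(ext$pruned$edge), 3L)
  # B's pendant edge absorbs the suppressed internal edge: 1 + 1
  # B absorbs its pendant edge (1) plus the whole internal path (1 + 1)
  eb <- ext$pruned$edge.length[ext$pruned$edge[, 2] ==
                                 which(ext$pruned$tip.label == "B")]
  expect_equal(eb, 3)

  set.seed(71)
  tr <- rand_tree(sprintf("t%d", 1:10))
  cl <- Filter(function(s) length(s) %in% 2:4, all_clades(tr))[[1]]
  ext2 <- extract_clade(tr, cl)
  expect_identical(length(ext2$pruned$tip.label) +
                     length(ext2$focal_tree$tip.label), 10L)
  expect_identical(sort(ext2$focal_tree$tip.label), sort(cl))
  expect_error(extract_clade(quartet, c("A", "C")), "invalid clade")
})

test_that("Robinson-Foulds distance agrees with an independent oracle", {
  expect_identical(rf_distance(quartet, quartet), 0L)
  q2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_identical(rf_distance(quartet, q2), 2L)
  expect_error(rf_distance(quartet,
                           ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")),
               "leaf sets")
  set.seed(81)
  for (i in 1:8) {
    t1 <- rand_tree(sprintf("t%d", 1:20))
    t2 <- rand_tree(sprintf("t%d", 1:20))
    expect_identical(rf_distance(t1, t2),
                     as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("placement enumeration matches the exhaustive regraft oracle", {
  ts <- enumerate_placements(quartet, "A")
  expect_length(ts$alternatives, 2L)
  # the two alternatives are the two other quartet topologies
  rfs <- vapply(ts$alternatives, function(a) rf_distance(a$tree, quartet), 0L)
  expect_true(all(rfs > 0))

  set.seed(91)
  for (i in 1:6) {
    tr <- sample_tree(10, 0.2, seed = 90 + i)
    els <- lgtplace:::edge_leaf_sets(tr)
    cherry <- els$child_sets[[which(lengths(els$child_sets) == 2)[1]]]
    ts <- enumerate_placements(tr, cherry,
                               placement_constraints())
    expect_identical(length(ts$alternatives),
                     oracle_regraft_count(tr, cherry))
    # focal clade intact and topologies pairwise distinct
    for (a in ts$alternatives)
      expect_true(check_monophyly(a$tree, cherry))
    n <- length(ts$alternatives)
    if (n > 1) {
      for (j in 2:n)
        expect_gt(rf_distance(ts$alternatives[[1]]$tree,
                              ts$alternatives[[j]]$tree), 0)
    }
  }
})

test_that("constraints: protected clades, scope and support thresholds", {
  set.seed(101)
  tr <- sample_tree(12, 0.2, seed = 77)
  clades <- all_clades(tr)
  focal <- clades[[which(lengths(clades) == 2)[1]]]
  prot <- Filter(function(s) length(s) == 3 && !any(focal %in% s),
                 clades)[[1]]

  free <- enumerate_placements(tr, focal,
                               placement_constraints())
  cons <- enumerate_placements(tr, focal, placement_constraints(
    protected = list(prot)))
  # protecting a 3-leaf clade forbids its 3 pendant + 2 internal edges,
  # but its stem stays legal
  expect_lt(length(cons$alternatives), length(free$alternatives))
  for (a in cons$alternatives) {
    expect_true(check_monophyly(a$tree, prot))
    expect_false(all(a$split %in% prot) && length(a$split) < length(prot))
  }

  # scope restricts attachments to one clade (stem included)
  scope <- Filter(function(s) length(s) >= 4 && length(s) <= 6 &&
                    !any(focal %in% s), clades)[[1]]
  sc <- enumerate_placements(tr, focal, placement_constraints(
    scope = scope))
  for (a in sc$alternatives)
    expect_true(all(a$split %in% scope) ||
                  all(setdiff(sc$pruned$tip.label, a$split) %in% scope))

  # a high support label forbids using that edge as attachment point
  trs <- tr
  trs$node.label <- rep("", trs$Nnode)
  ext <- extract_clade(trs, focal)
  hi <- enumerate_placements(trs, focal, placement_constraints())
  # label every internal node of the base tree with strong support
  trs$node.label <- rep("98", trs$Nnode)
  lo <- enumerate_placements(trs, focal, placement_constraints())
  expect_lt(length(lo$alternatives), length(hi$alternatives))
  expect_warning(enumerate_placements(trs, focal,
                                      placement_constraints(scope = focal)),
                 "no legal")
})

test_that("regraft/extract round-trip preserves backbone bipartitions", {
  set.seed(111)
  tr <- sample_tree(10, 0.2, seed = 55)
  els <- lgtplace:::edge_leaf_sets(tr)
  focal <- els$child_sets[[which(lengths(els$child_sets) == 3)[1]]]
  ext <- extract_clade(tr, focal)
  ts <- enumerate_placements(tr, focal,
                             placement_constraints())
  for (a in ts$alternatives) {
    back <- extract_clade(a$tree, focal)
    expect_identical(rf_distance(back$pruned, ext$pruned), 0L)
  }
})
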