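test_that("random trees: shape, determinism, branch-length distribution", {
  t4 <- sample_tree(4, seed = 1)
  expect_identical(nrow(t4$edge), 5L)   # unrooted binary: 2n - 3 edges
  expect_identical(t4$Nnode, 2L)
  expect_error(sample_tree(3), "ntaxa")
  expect_error(sample_tree(10, branch_scale = 0), "branch_scale")

  a <- ape::write.tree(sample_tree(64, 0.1, seed = 1))
  b <- ape::write.tree(sample_tree(64, 0.1, seed = 1))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(sample_tree(64, 0.1, seed = 2))))

  # Monte-Carlo check of the exponential branch-length law
  lens <- unlist(lapply(1:10000, function(i)
    sample_tree(64, 0.1, seed = i)$edge.length))
  expect_equal(mean(lens), 0.1, tolerance = 0.02)
})

test_that("alignment simulation matches its stated generating process", {
  # zero branch lengths: every sequence equals the root draw
  tr <- sample_tree(6, seed = 3)
  tr$edge.length[] <- 0
  aln0 <- simulate_alignment(tr, aa_model("WAG"), 30, seed = 4)
  for (i in 2:6)
    expect_identical(unname(aln0$states[i, ]), unname(aln0$states[1, ]))

  # stationary root frequencies, uniform case: binomial 99% CI at 20k sites
  aln1 <- simulate_alignment(tr, aa_model("Poisson"), 20000, seed = 5)
  freqs <- tabulate(aln1$states[1, ], 20) / 20000
  ci <- 2.576 * sqrt(0.05 * 0.95 / 20000)
  expect_true(all(abs(freqs - 0.05) < ci))

  # two-taxon Poisson closed form for the expected difference fraction
  tr2 <- ape::read.tree(text = "(a:0.25,b:0.25);")
  aln2 <- simulate_alignment(tr2, aa_model("Poisson"), 20000, seed = 6)
  pdiff <- mean(aln2$states[1, ] != aln2$states[2, ])
  pexp <- 1 - (1 / 20 + (19 / 20) * exp(-(20 / 19) * 0.5))
  expect_lt(abs(pdiff - pexp), 2.576 * sqrt(pexp * (1 - pexp) / 20000))

  # byte-identical FASTA under a fixed seed
  t8 <- sample_tree(8, seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta_aa(simulate_alignment(t8, aa_model("WAG+G", alpha = 1), 50,
                                    seed = 8), f1)
  write_fasta_aa(simulate_alignment(t8, aa_model("WAG+G", alpha = 1), 50,
                                    seed = 8), f2)
  expect_identical(readLines(f1), readLines(f2))

  # only canonical residues unless masking is requested
  expect_false(anyNA(simulate_alignment(t8, aa_model("LG"), 40,
                                        seed = 9)$states))
  masked <- simulate_alignment(t8, aa_model("LG"), 400, seed = 10,
                               missing_frac = 0.1)
  expect_gt(mean(is.na(masked$states)), 0.05)

  # pairwise identity decays with path length on the tree
  t20 <- sample_tree(20, 0.12, seed = 11)
  aln20 <- simulate_alignment(t20, aa_model("WAG+G", alpha = 1), 500,
                              seed = 12)
  D <- ape::cophenetic.phylo(t20)
  set.seed(13)
  pairs <- t(replicate(100, sample(t20$tip.label, 2)))
  ident <- apply(pairs, 1, function(p)
    mean(aln20$states[p[1], ] == aln20$states[p[2], ]))
  plen <- D[pairs]
  expect_lt(cor(ident, plen, method = "spearman"), 0)
})

test_that("LGT grafting: scenario validation and gene-tree construction", {
  set.seed(21)
  tr <- sample_tree(10, 0.2, seed = 21)
  clades <- all_clades(tr)
  focal <- clades[[which(lengths(clades) == 2)[1]]]
  host <- Filter(function(s) length(s) >= 4 && length(s) <= 6 &&
                   !any(focal %in% s), clades)[[1]]
  # donor: a proper sub-clade of the host clade
  donor <- Filter(function(s) length(s) >= 2 && length(s) < length(host) &&
                    all(s %in% host), clades)[[1]]
  sc <- lgt_scenario(tr, focal, donor, constraint_clades = list(host))
  gt <- build_lgt_gene_tree(sc)
  expect_true(check_monophyly(gt, c(focal, donor)))
  expect_gt(rf_distance(tr, gt), 0)
  expect_setequal(gt$tip.label, tr$tip.label)

  # the graft splits the donor edge at its midpoint with a half-length stem
  ext <- extract_clade(tr, focal)
  pr <- ape::reorder.phylo(ext$pruned, "postorder")
  pels <- lgtplace:::edge_leaf_sets(pr)
  backbone <- pr$tip.label
  de <- which(vapply(pels$child_sets, function(s)
    setequal(s, donor) || setequal(setdiff(backbone, s), donor), TRUE))
  manual <- graft_clade(pr, ext$focal_tree, de[1])
  expect_identical(rf_distance(gt, manual), 0L)

  expect_error(lgt_scenario(tr, c(focal, donor), donor, list(host)),
               "not monophyletic")
  expect_error(lgt_scenario(tr, focal, donor, list()), "constraint clade")
  # degenerate move: donor edge adjacent to the original attachment
  degen <- ext$attachment_split
  expect_error({
    sc2 <- lgt_scenario(tr, focal, degen,
                        constraint_clades = list(setdiff(tr$tip.label,
                                                         focal)))
    build_lgt_gene_tree(sc2)
  }, "degenerate|not found")
})

test_that("GHF5-like bundles encode the requested transfer history", {
  b <- ghf5_like_bundle(lgt = TRUE, seed = 31)
  expect_identical(dim(b$alignment$states), c(60L, 300L))
  expect_true(check_monophyly(b$true_tree,
                              c(b$subfamilies$sf1, b$focal_taxa)))
  # nested strictly inside: symbionts not attached at the sub-family stem
  expect_gt(rf_distance(b$lgt_tree, b$vertical_tree), 0)

  b0 <- ghf5_like_bundle(lgt = FALSE, seed = 31)
  expect_false(check_monophyly(b0$true_tree,
                               c(b0$subfamilies$sf1, b0$focal_taxa)))
  expect_false(check_monophyly(b0$true_tree,
                               c(b0$subfamilies$sf2, b0$focal_taxa)))
  expect_true(check_monophyly(b0$true_tree, b0$focal_taxa))

  # determinism of the whole bundle
  b2 <- ghf5_like_bundle(lgt = TRUE, seed = 31)
  expect_identical(b$alignment$states, b2$alignment$states)
  expect_identical(ape::write.tree(b$true_tree), ape::write.tree(b2$true_tree))
})
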