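test_that("pruning equals exhaustive-state enumeration on small trees", {
  set.seed(11)
  specs <- c("Poisson", "WAG+G", "LG+G+I")
  for (rep in 1:4) {
    n <- sample(4:5, 1)
    labs <- sprintf("t%d", seq_len(n))
    tr <- rand_tree(labs)
    aln <- rand_aln(labs, 6)
    for (spec in specs) {
      m <- aa_model(spec, alpha = runif(1, 0.3, 2), p_inv = runif(1, 0, 0.3))
      o <- oracle_site_ll(tr, aln, m)
      p <- site_loglikelihoods(tr, aln, m)
      expect_lt(max(abs((p - o) / o)), 1e-11)
      expect_equal(attr(p, "loglik"), sum(p))
    }
  }
})

test_that("degenerate and invariance properties of the likelihood", {
  # zero-time limit: two identical taxa collapse to a stationary draw
  aln2 <- aa_alignment(c(a = "A", b = "A"))
  tr2 <- ape::read.tree(text = "(a:1e-10,b:1e-10);")
  ll <- site_loglikelihoods(tr2, aln2, aa_model("Poisson"))
  expect_equal(as.numeric(ll), log(1 / 20), tolerance = 1e-4)

  set.seed(23)
  labs <- sprintf("t%d", 1:8)
  tr <- rand_tree(labs)
  m <- aa_model("WAG+G+I", alpha = 0.9, p_inv = 0.1)
  aln <- simulate_alignment(tr, m, 40, seed = 5)
  base <- site_loglikelihoods(tr, aln, m)

  # rerooting invariance (pulley principle for reversible models)
  for (og in labs[c(2, 5, 7)]) {
    rr <- ape::unroot(ape::root(tr, outgroup = og, resolve.root = TRUE))
    expect_equal(as.numeric(site_loglikelihoods(rr, aln, m)),
                 as.numeric(base), tolerance = 1e-10)
  }

  # leaf-order permutation of the alignment must not matter
  perm <- aa_alignment(aln$states[sample(nrow(aln$states)), , drop = FALSE])
  expect_equal(as.numeric(site_loglikelihoods(tr, perm, m)),
               as.numeric(base), tolerance = 1e-12)

  # an all-missing taxon attached anywhere changes nothing
  st <- rbind(aln$states, t9 = rep(NA_integer_, ncol(aln$states)))
  aln9 <- aa_alignment(st)
  tr9 <- graft_clade(tr, ape::read.tree(text = "(t9:0.31);"), 4,
                     stem_length = 0.17)
  ll9 <- site_loglikelihoods(tr9, aln9, m)
  expect_equal(attr(ll9, "loglik"), attr(base, "loglik"), tolerance = 1e-9)

  # tree leaf missing from the alignment is an error
  expect_error(site_loglikelihoods(rand_tree(c(labs, "zz")), aln, m),
               "missing taxon")
})

test_that("branch-length optimization: closed form, bounds, monotonicity", {
  # two-taxon Poisson MLE has a closed form in the difference fraction
  mk2 <- function(ndiff, n = 500) {
    a <- rep("A", n)
    b <- c(rep("R", ndiff), rep("A", n - ndiff))
    aa_alignment(c(a = paste(a, collapse = ""), b = paste(b, collapse = "")))
  }
  tr2 <- ape::read.tree(text = "(a:0.2,b:0.2);")
  for (phat in c(0.1, 0.4)) {
    aln <- mk2(phat * 500)
    fit <- optimize_branch_lengths(tr2, aln, aa_model("Poisson"), tol = 1e-9)
    expect_equal(sum(fit$tree$edge.length),
                 -(19 / 20) * log(1 - (20 / 19) * phat), tolerance = 1e-4)
  }

  # identical sequences drive every branch to the lower bound
  same <- aa_alignment(c(a = "ARNDAR", b = "ARNDAR", c = "ARNDAR",
                         d = "ARNDAR"))
  tr4 <- rand_tree(c("a", "b", "c", "d"))
  fit0 <- optimize_branch_lengths(tr4, same, aa_model("Poisson"))
  expect_true(all(fit0$tree$edge.length <= 1e-6))

  # optimization never decreases the log-likelihood
  set.seed(31)
  labs <- sprintf("t%d", 1:10)
  tr <- rand_tree(labs)
  m <- aa_model("WAG+G", alpha = 0.8)
  aln <- simulate_alignment(tr, m, 60, seed = 8)
  start <- attr(site_loglikelihoods(tr, aln, m), "loglik")
  fit <- optimize_branch_lengths(tr, aln, m)
  expect_gte(fit$loglik, start)
  expect_true(all(fit$tree$edge.length >= 1e-8 - 1e-15))
  expect_error(optimize_branch_lengths(tr, aln, m, tol = -1), "tol")
})

test_that("rate-parameter fitting improves or preserves the likelihood", {
  set.seed(41)
  labs <- sprintf("t%d", 1:10)
  tr <- rand_tree(labs)
  truth <- aa_model("WAG+G", alpha = 0.5)
  aln <- simulate_alignment(tr, truth, 150, seed = 9)
  m0 <- aa_model("WAG+G+I", alpha = 2, p_inv = 0.3)
  ll0 <- attr(site_loglikelihoods(tr, aln, m0), "loglik")
  fit <- optimize_rate_params(tr, aln, m0)
  expect_gte(fit$loglik, ll0)
  expect_true(fit$model$alpha >= 0.02 && fit$model$alpha <= 100)
  # p_inv fitted on data generated without invariant sites stays small
  expect_lt(fit$model$p_inv, 0.08)
})

test_that("model selection ranks by AIC, independent of candidate order", {
  set.seed(51)
  labs <- sprintf("t%d", 1:8)
  tr <- rand_tree(labs)
  aln <- simulate_alignment(tr, aa_model("WAG+G", alpha = 0.7), 400,
                            seed = 10)
  cands <- c("Poisson+G", "WAG+G")
  tab <- select_model(aln, tr, cands)
  expect_identical(tab$model[1], "WAG+G")
  expect_equal(tab$AIC, 2 * tab$params - 2 * tab$loglik)
  tab2 <- select_model(aln, tr, rev(cands))
  expect_identical(tab$model, tab2$model)
  expect_equal(tab$AIC, tab2$AIC, tolerance = 1e-6)
  expect_error(select_model(aln, tr, character()), "empty candidate")
})
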