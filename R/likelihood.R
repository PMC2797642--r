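# R-level interface to the pruning kernel: per-site log-likelihoods,
# branch-length optimization, rate-parameter fitting and AIC-based model
# selection.

BL_MIN <- 1e-8
BL_MAX <- 10

# Validate tree/alignment/model, reorder the tree in postorder and
# assemble everything the C++ kernel needs.
peel_args <- function(tree, aln, model) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "aa_alignment"),
            inherits(model, "aa_model"))
  missing <- setdiff(tree$tip.label, aln$labels)
  if (length(missing))
    stop("missing taxon in alignment: ", paste(missing, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tree <- ape::reorder.phylo(tree, "postorder")
  states <- aln$states[tree$tip.label, , drop = FALSE]
  tipstate <- states - 1L
  tipstate[is.na(tipstate)] <- -1L
  eig <- model_eigen(model)
  # invariant-class site term: pi of the single observed residue, zero if
  # two observed residues differ, one if the column is all-missing
  invterm <- apply(states, 2L, function(col) {
    obs <- unique(col[!is.na(col)])
    if (length(obs) == 0L) 1 else if (length(obs) == 1L) model$pi[obs] else 0
  })
  list(tree = tree, edge = tree$edge, ntip = length(tree$tip.label),
       el = tree$edge.length, tipstate = tipstate, eig = eig,
       rates = model_rates(model), pinv = model$p_inv, invterm = invterm)
}

#' Per-site log-likelihoods of a tree
#'
#' Felsenstein pruning under the model's discrete-gamma (+ optional
#' invariant-sites) mixture.  Missing states contribute all-ones partial
#' likelihoods; per-node rescaling keeps large trees inside double range.
#'
#' @param tree an unrooted `phylo` with branch lengths.
#' @param aln an `aa_alignment` covering all tree leaves.
#' @param model an `aa_model` (use [set_empirical_frequencies()] first for
#'   `+F` models).
#' @return numeric vector of natural-log per-site likelihoods, with the
#'   total in `attr(,"loglik")`.
#' @export
site_loglikelihoods <- function(tree, aln, model) {
  pa <- peel_args(tree, aln, model)
  res <- cpp_peel(pa$edge, pa$ntip, pa$el, pa$tipstate, pa$eig$U,
                  pa$eig$Uinv, pa$eig$lambda, model$pi, pa$rates, pa$pinv,
                  pa$invterm, FALSE, 0, 0L, BL_MIN, BL_MAX)
  ll <- as.numeric(res$sitell)
  attr(ll, "loglik") <- res$loglik
  ll
}

#' Optimize branch lengths by coordinate ascent
#'
#' Sweeps over all branches, optimizing each with a bounded Brent search
#' (bounds `[1e-8, 10]`) against the current state of all other branches,
#' until the total log-likelihood gain of a sweep falls below `tol`.  The
#' log-likelihood is non-decreasing across sweeps.
#'
#' @inheritParams site_loglikelihoods
#' @param tol stop when a full sweep improves the log-likelihood by less
#'   than this (log units), default 1e-4.
#' @param max_sweeps sweep cap, default 20.
#' @return list with elements `tree` (optimized lengths), `loglik`,
#'   `site_loglik` and `sweeps`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-4,
                                    max_sweeps = 20L) {
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  pa <- peel_args(tree, aln, model)
  res <- cpp_peel(pa$edge, pa$ntip, pa$el, pa$tipstate, pa$eig$U,
                  pa$eig$Uinv, pa$eig$lambda, model$pi, pa$rates, pa$pinv,
                  pa$invterm, TRUE, tol, as.integer(max_sweeps), BL_MIN,
                  BL_MAX)
  out <- pa$tree
  out$edge.length <- as.numeric(res$el)
  ll <- as.numeric(res$sitell)
  attr(ll, "loglik") <- res$loglik
  list(tree = out, loglik = res$loglik, site_loglik = ll,
       sweeps = res$sweeps)
}

#' Fit gamma shape and invariant proportion
#'
#' Bounded optimization of the model's free rate-heterogeneity parameters
#' (`alpha` in `[0.02, 100]` when `+G`, `p_inv` in `[0, 0.99]` when `+I`)
#' with branch lengths held fixed.  Never returns a model with lower
#' likelihood than the input.
#'
#' @inheritParams site_loglikelihoods
#' @return list with elements `model` (updated) and `loglik`.
#' @export
optimize_rate_params <- function(tree, aln, model) {
  eval_ll <- function(alpha, p_inv) {
    m <- model
    m$alpha <- alpha
    m$p_inv <- p_inv
    attr(site_loglikelihoods(tree, aln, m), "loglik")
  }
  a0 <- if (model$gamma) min(max(model$alpha, 0.02), 100) else Inf
  p0 <- if (model$invariant) min(max(model$p_inv, 0), 0.99) else 0
  ll0 <- eval_ll(a0, p0)
  best <- list(alpha = a0, p_inv = p0, loglik = ll0)
  if (model$gamma && model$invariant) {
    fn <- function(par) -eval_ll(exp(par[1]), par[2])
    opt <- stats::optim(c(log(a0), p0), fn, method = "L-BFGS-B",
                        lower = c(log(0.02), 0), upper = c(log(100), 0.99),
                        control = list(factr = 1e9))
    if (-opt$value > best$loglik)
      best <- list(alpha = exp(opt$par[1]), p_inv = opt$par[2],
                   loglik = -opt$value)
  } else if (model$gamma) {
    opt <- stats::optimize(function(la) -eval_ll(exp(la), p0),
                           c(log(0.02), log(100)), tol = 1e-4)
    if (-opt$objective > best$loglik)
      best <- list(alpha = exp(opt$minimum), p_inv = p0,
                   loglik = -opt$objective)
  } else if (model$invariant) {
    opt <- stats::optimize(function(p) -eval_ll(a0, p), c(0, 0.99),
                           tol = 1e-6)
    if (-opt$objective > best$loglik)
      best <- list(alpha = a0, p_inv = opt$minimum, loglik = -opt$objective)
  }
  model$alpha <- best$alpha
  model$p_inv <- best$p_inv
  list(model = model, loglik = best$loglik)
}

#' Jointly fit branch lengths and rate parameters
#'
#' Alternates one branch-length sweep with one rate-parameter fit until
#' the cycle gain drops below `tol` (default 1e-4 log units) or
#' `max_cycles` is reached.
#'
#' @inheritParams site_loglikelihoods
#' @param tol convergence threshold on the per-cycle log-likelihood gain.
#' @param max_cycles cycle cap, default 20.
#' @return list with `tree`, `model`, `loglik`, `site_loglik`, `cycles`.
#' @export
fit_model <- function(tree, aln, model, tol = 1e-4, max_cycles = 20L) {
  model <- set_empirical_frequencies(model, aln)
  ll <- attr(site_loglikelihoods(tree, aln, model), "loglik")
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    ob <- optimize_branch_lengths(tree, aln, model, tol = tol,
                                  max_sweeps = 1L)
    tree <- ob$tree
    if (model$gamma || model$invariant) {
      orp <- optimize_rate_params(tree, aln, model)
      model <- orp$model
      ll_new <- orp$loglik
    } else ll_new <- ob$loglik
    if (ll_new - ll < tol || cycles >= max_cycles) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  sl <- site_loglikelihoods(tree, aln, model)
  list(tree = tree, model = model, loglik = attr(sl, "loglik"),
       site_loglik = sl, cycles = cycles)
}

#' Rank substitution models by AIC
#'
#' For each candidate specification, fits its free parameters on the given
#' tree and reports `AIC = 2 k - 2 lnL`, where `k` counts gamma shape,
#' invariant proportion and (for `+F`) 19 free frequencies; branch lengths
#' are re-optimized per candidate but, being common to all candidates, are
#' not counted.  The best model minimizes AIC.  Ranking does not depend on
#' candidate order (ties broken by specification string).
#'
#' @param aln an `aa_alignment`.
#' @param tree an unrooted `phylo` with starting branch lengths.
#' @param candidates character vector of model specs, e.g.
#'   `c("WAG+G+I+F", "LG+G+F", "Poisson+G")`.
#' @param k gamma category count, default 4.
#' @param max_cycles per-candidate fit cycles, default 5.
#' @return data frame with columns `model`, `loglik`, `params`, `AIC`,
#'   `delta_AIC`, sorted best first.
#' @export
select_model <- function(aln, tree, candidates, k = 4L, max_cycles = 5L) {
  if (!length(candidates)) stop("empty candidate list")
  rows <- lapply(candidates, function(spec) {
    m <- aa_model(spec, alpha = 1, p_inv = if (grepl("\\+I", spec)) 0.1 else 0,
                  k = k)
    fit <- fit_model(tree, aln, m, max_cycles = max_cycles)
    data.frame(model = spec, loglik = fit$loglik,
               params = n_free_params(m),
               AIC = 2 * n_free_params(m) - 2 * fit$loglik,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC, tab$model), , drop = FALSE]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  tab
}
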