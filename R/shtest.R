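# Per-topology site log-likelihoods, RELL bootstrap and the
# Shimodaira-Hasegawa test.  The SH procedure compares every candidate
# topology against the maximum-likelihood one using centered resampled
# log-likelihoods, which makes it conservative: a topology is only
# rejected when its likelihood deficit exceeds what resampling noise
# produces under the least-favourable null.

#' Per-topology site log-likelihood matrix
#'
#' Evaluates every tree of a topology set on the same alignment.  By
#' default branch lengths are re-optimized for each topology
#' (`reopt = "branches"`); `"full"` also refits gamma shape/invariant
#' proportion per topology; `"fixed"` evaluates trees as given.
#'
#' @param topologies a `topology_set` (from [enumerate_placements()]) or a
#'   plain list of `phylo` trees sharing one leaf set (first tree = base).
#' @param aln an `aa_alignment`.
#' @param model an `aa_model`; `+F` frequencies are filled from `aln`.
#' @param reopt one of `"branches"`, `"full"`, `"fixed"`.
#' @param tol branch-optimization convergence tolerance in log units
#'   (default 0.05: topology comparisons ride on log-likelihood
#'   differences orders of magnitude larger).
#' @return matrix (topologies x sites) of site log-likelihoods, base tree
#'   in row 1; per-topology totals in `attr(,"loglik")`, the evaluated
#'   trees in `attr(,"trees")`.
#' @export
per_topology_site_ll <- function(topologies, aln, model,
                                 reopt = c("branches", "full", "fixed"),
                                 tol = 0.05) {
  reopt <- match.arg(reopt)
  trees <- as_tree_list(topologies)
  model <- set_empirical_frequencies(model, aln)
  leafset <- sort(trees[[1]]$tip.label)
  rows <- vector("list", length(trees))
  fitted <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), leafset))
      stop("topology ", names(trees)[i], ": leaf set differs from base")
    res <- tryCatch(switch(reopt,
      fixed = {
        sl <- site_loglikelihoods(trees[[i]], aln, model)
        list(tree = trees[[i]], site_loglik = sl,
             loglik = attr(sl, "loglik"))
      },
      branches = optimize_branch_lengths(trees[[i]], aln, model,
                                         tol = tol),
      full = fit_model(trees[[i]], aln, model, tol = tol)
    ), error = function(e)
      stop("topology ", names(trees)[i], ": ", conditionMessage(e)))
    rows[[i]] <- as.numeric(res$site_loglik)
    fitted[[i]] <- res$tree
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(trees)
  attr(m, "loglik") <- rowSums(m)
  attr(m, "trees") <- fitted
  m
}

as_tree_list <- function(topologies) {
  if (inherits(topologies, "topology_set")) {
    trees <- c(list(topologies$base_tree),
               lapply(topologies$alternatives, `[[`, "tree"))
    names(trees) <- c("base",
                      vapply(topologies$alternatives,
                             function(a) paste0("alt_edge", a$edge), ""))
  } else if (inherits(topologies, "phylo")) {
    trees <- list(base = topologies)
  } else {
    trees <- topologies
    if (is.null(names(trees)))
      names(trees) <- c("base", sprintf("alt%d",
                                        seq_len(max(length(trees) - 1, 0))))
  }
  trees
}

#' RELL bootstrap of total log-likelihoods
#'
#' Resampling estimated log-likelihood: each replicate draws multinomial
#' site weights summing to the site count and returns the weighted total
#' log-likelihood of every topology, avoiding any re-optimization.
#'
#' @param matrix topologies x sites matrix of site log-likelihoods.
#' @param B number of replicates (>= 1).
#' @param seed integer seed.
#' @return B x topologies matrix of resampled total log-likelihoods.
#' @export
rell_bootstrap <- function(matrix, B = 1000L, seed = NULL) {
  B <- as.integer(B)
  if (B < 1L) stop("invalid parameter: B must be >= 1")
  nsites <- ncol(matrix)
  with_seed(seed, {
    w <- stats::rmultinom(B, size = nsites, prob = rep(1 / nsites, nsites))
    res <- t(matrix %*% w)
    colnames(res) <- rownames(matrix)
    res
  })
}

#' Shimodaira-Hasegawa topology test
#'
#' One-sided SH test from a site log-likelihood matrix:
#' observed deficits `D_a = max_a' lnL_a' - lnL_a`; RELL replicates are
#' centered per topology, null deficits are taken against the per-replicate
#' maximum of the centered values, and
#' `p_a = (#\{b: D~_ab >= D_a\} + 1) / (B + 1)` (the +1 correction avoids
#' Monte-Carlo zeros).  `SD_a` is the RELL standard deviation of the
#' likelihood difference between the best tree and topology `a`.
#'
#' @param matrix topologies x sites site log-likelihood matrix
#'   (from [per_topology_site_ll()]).
#' @param B RELL replicates, default 1000.
#' @param alpha rejection level, default 0.05.
#' @param seed integer seed.
#' @return an `sh_report` data frame with columns `tree`, `loglik`,
#'   `D_LH` (signed, 0 for the best tree), `SD`, `p_value`,
#'   `significantly_worse`.
#' @export
sh_test <- function(matrix, B = 1000L, alpha = 0.05, seed = NULL) {
  if (nrow(matrix) < 2L) stop("need at least 2 topologies")
  B <- as.integer(B)
  if (B < 1L) stop("invalid parameter: B must be >= 1")
  lnL <- rowSums(matrix)
  best <- unname(which.max(lnL)[1])  # ties: first index
  D <- lnL[best] - lnL               # >= 0
  rep_ll <- rell_bootstrap(matrix, B = B, seed = seed)   # B x ntopo
  centered <- sweep(rep_ll, 2L, colMeans(rep_ll))
  null_max <- do.call(pmax, as.data.frame(centered))
  pvals <- vapply(seq_len(nrow(matrix)), function(a) {
    (sum(null_max - centered[, a] >= D[a]) + 1) / (B + 1)
  }, 0)
  SD <- vapply(seq_len(nrow(matrix)), function(a)
    stats::sd(rep_ll[, best] - rep_ll[, a]), 0)
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- sprintf("tree%d", seq_len(nrow(matrix)))
  out <- data.frame(tree = ids, loglik = unname(lnL),
                    D_LH = unname(lnL - lnL[best]), SD = unname(SD),
                    p_value = unname(pvals),
                    significantly_worse = unname(pvals < alpha),
                    stringsAsFactors = FALSE)
  attr(out, "best") <- best
  attr(out, "alpha") <- alpha
  attr(out, "B") <- B
  class(out) <- c("sh_report", "data.frame")
  out
}

#' @export
print.sh_report <- function(x, ...) {
  cat(sprintf("SH test (B = %d, alpha = %g); best tree: %s\n",
              attr(x, "B"), attr(x, "alpha"), x$tree[attr(x, "best")]))
  print.data.frame(x, digits = 8, row.names = FALSE)
  invisible(x)
}

#' Write an SH report as TSV
#'
#' Columns `Tree`, `Likelihood`, `D_LH`, `SD`, `p_value`,
#' `SignificantlyWorse` (Yes/No), floats to 6 decimals; the best tree is
#' printed first, remaining rows in input order.
#'
#' @param report an `sh_report`.
#' @param path output file.
#' @param header optional `#`-prefixed comment line(s).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, header = NULL) {
  best <- attr(report, "best")
  ord <- c(best, setdiff(seq_len(nrow(report)), best))
  r <- report[ord, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("Tree\tLikelihood\tD_LH\tSD\tp_value\tSignificantlyWorse", con)
  writeLines(sprintf("%s\t%.6f\t%.6f\t%.6f\t%.6f\t%s", r$tree, r$loglik,
                     r$D_LH, r$SD, r$p_value,
                     ifelse(r$significantly_worse, "Yes", "No")), con)
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path file path.
#' @return data frame with the report columns.
#' @export
read_report <- function(path) {
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  names(d) <- c("tree", "loglik", "D_LH", "SD", "p_value",
                "significantly_worse")
  d$significantly_worse <- d$significantly_worse == "Yes"
  d
}
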