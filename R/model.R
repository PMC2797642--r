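# Empirical amino-acid substitution models in GTR form: a symmetric
# exchangeability matrix S combined with stationary frequencies pi gives
# Q_ij = S_ij * pi_j, diagonal set so rows sum to zero, globally scaled so
# the mean substitution rate -sum_i pi_i Q_ii equals 1 (branch lengths are
# then expected substitutions per site).  Rate heterogeneity follows the
# standard discrete-gamma (k equal-weight categories) plus an optional
# proportion of invariant sites.

.exch_from_lower <- function(lower) {
  S <- matrix(0, 20, 20, dimnames = list(AA_RESIDUES, AA_RESIDUES))
  S[lower.tri(S)] <- lower
  S + t(S)
}

model_tables <- function(name) {
  tab <- switch(toupper(name),
    WAG = list(S = .exch_from_lower(.wag_exch_lower),
               pi = stats::setNames(.wag_freqs, AA_RESIDUES)),
    LG = list(S = .exch_from_lower(.lg_exch_lower),
              pi = stats::setNames(.lg_freqs, AA_RESIDUES)),
    POISSON = list(S = .exch_from_lower(rep(1, 190)),
                   pi = stats::setNames(rep(1 / 20, 20), AA_RESIDUES)),
    stop("unknown substitution model: ", name)
  )
  tab$pi <- tab$pi / sum(tab$pi)  # published tables are rounded
  tab
}

#' Build a normalized amino-acid rate matrix
#'
#' Constructs `Q[i,j] = S[i,j] * pi[j]` for `i != j`, sets the diagonal so
#' each row sums to zero, and rescales so the mean rate
#' `-sum(pi * diag(Q))` is exactly 1.
#'
#' @param S symmetric non-negative 20x20 exchangeability matrix with zero
#'   diagonal (off-diagonal values only are used).
#' @param pi stationary frequencies, positive, summing to 1 within 1e-9.
#' @return normalized 20x20 rate matrix.
#' @export
build_rate_matrix <- function(S, pi) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-12)))
    stop("invalid model: exchangeability matrix is not symmetric")
  if (any(S < 0)) stop("invalid model: negative exchangeability")
  if (abs(sum(pi) - 1) > 1e-9)
    stop("invalid model: frequencies do not sum to 1")
  if (any(pi <= 0)) stop("invalid model: non-positive frequency")
  Q <- S * rep(pi, each = nrow(S))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

#' Discrete-gamma rate categories
#'
#' Mean-of-quantile-bin discretization of a Gamma(shape = alpha,
#' rate = alpha) distribution into `k` equal-probability categories
#' (Yang's method), renormalized so the category mean is exactly 1.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param k number of categories (>= 1), default 4.
#' @return numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("invalid parameter: alpha <= 0")
  k <- as.integer(k)
  if (k < 1L) stop("invalid parameter: k < 1")
  if (k == 1L) return(1)
  # E[X | a < X <= b] * P(a < X <= b) = F_{alpha+1}(b) - F_{alpha+1}(a)
  # for X ~ Gamma(alpha, alpha); each bin has probability 1/k.
  bounds <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                          rate = alpha)
  mass <- diff(stats::pgamma(bounds, shape = alpha + 1, rate = alpha))
  rates <- mass * k
  rates / mean(rates)
}

#' Specify an amino-acid substitution model
#'
#' Parses a model string in the usual `NAME[+G][+I][+F]` notation, e.g.
#' `"WAG+G+I+F"` or `"LG+G+F"`.  `+G` enables discrete-gamma rate
#' variation (`k` categories, default 4), `+I` an invariant-site
#' proportion, `+F` empirical frequencies estimated from the alignment
#' (model-default frequencies otherwise).
#'
#' @param spec model string; base name one of `WAG`, `LG`, `Poisson`.
#' @param alpha gamma shape (used when `+G`; default 1).
#' @param p_inv invariant proportion in `[0, 1)` (used when `+I`; default 0).
#' @param k gamma category count, default 4.
#' @param frequencies optional explicit frequency vector overriding the
#'   model defaults (used for `+F` once data are seen).
#' @return an object of class `aa_model`.
#' @examples
#' m <- aa_model("WAG+G+I+F", alpha = 0.8, p_inv = 0.1)
#' m$gamma
#' @export
aa_model <- function(spec, alpha = 1, p_inv = 0, k = 4L,
                     frequencies = NULL) {
  parts <- strsplit(spec, "+", fixed = TRUE)[[1]]
  if (!length(parts)) stop("empty model spec")
  base <- parts[1]
  flags <- toupper(parts[-1])
  bad <- setdiff(flags, c("G", "I", "F"))
  if (length(bad)) stop("unknown model flags: ", paste(bad, collapse = ","))
  tab <- model_tables(base)
  has_g <- "G" %in% flags
  has_i <- "I" %in% flags
  has_f <- "F" %in% flags
  if (!has_g) alpha <- Inf
  if (!has_i) p_inv <- 0
  if (!is.null(frequencies)) {
    if (length(frequencies) != 20 || abs(sum(frequencies) - 1) > 1e-9)
      stop("frequencies must be 20 values summing to 1")
    tab$pi <- stats::setNames(as.numeric(frequencies), AA_RESIDUES)
  }
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)")
  m <- structure(list(
    name = toupper(base), spec = spec, S = tab$S, pi = tab$pi,
    gamma = has_g, invariant = has_i, empirical_freqs = has_f,
    alpha = alpha, p_inv = p_inv, k = if (has_g) as.integer(k) else 1L
  ), class = "aa_model")
  m
}

#' @export
print.aa_model <- function(x, ...) {
  cat(sprintf("aa_model %s  (alpha=%s, p_inv=%.4g, k=%d)\n", x$spec,
              if (x$gamma) format(x$alpha, digits = 4) else "-",
              x$p_inv, x$k))
  invisible(x)
}

#' Fill a +F model's frequencies from an alignment
#'
#' For models with the `+F` flag, replaces the frequency vector by the
#' alignment's empirical residue proportions (with pseudocount); a no-op
#' otherwise.
#'
#' @param model an `aa_model`.
#' @param aln an `aa_alignment`.
#' @return the updated model.
#' @export
set_empirical_frequencies <- function(model, aln) {
  if (!model$empirical_freqs) return(model)
  model$pi <- empirical_frequencies(aln)
  model
}

# Rates and weights of the full among-site rate mixture, excluding the
# invariant class (handled separately in the likelihood).
model_rates <- function(model) {
  if (model$gamma) discrete_gamma_rates(model$alpha, model$k) else 1
}

# Symmetric eigendecomposition of Q: with D = diag(sqrt(pi)),
# B = D Q D^-1 is symmetric for reversible Q, so Q = U L U^-1 with real L,
# U = D^-1 V, U^-1 = V' D.  P(t) = U diag(exp(L t)) U^-1.
model_eigen <- function(model) {
  Q <- build_rate_matrix(model$S, model$pi)
  sp <- sqrt(model$pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sp, Uinv = t(e$vectors) * rep(sp, each = 20),
       lambda = e$values, Q = Q)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` for the model's normalized rate matrix, computed via
#' the reversible model's symmetric eigendecomposition.
#'
#' @param model an `aa_model`.
#' @param t branch length (expected substitutions per site at rate 1).
#' @param eig optional precomputed decomposition (internal reuse).
#' @return 20x20 stochastic matrix.
#' @export
transition_matrix <- function(model, t, eig = model_eigen(model)) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P
}

#' Number of free parameters of a model specification
#'
#' Counts rate-heterogeneity and frequency parameters: 1 for `+G`
#' (gamma shape), 1 for `+I` (invariant proportion), 19 for `+F`
#' (empirical frequencies).  Branch lengths are shared by all candidates
#' in a model-selection comparison and are not counted.
#'
#' @param model an `aa_model`.
#' @return integer parameter count.
#' @export
n_free_params <- function(model) {
  sum(model$gamma, model$invariant) + if (model$empirical_freqs) 19L else 0L
}
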