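---
title: "Testing lateral gene transfer by constrained clade placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing lateral gene transfer by constrained clade placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtplace)
```

## The question this package answers

In gene families sampled from host-associated microbial communities —
the motivating case is cellulase (glycosyl hydrolase) genes expressed by
the protist symbionts of lower termites — a eukaryotic clade sometimes
appears *nested inside* a bacterial clade of the gene tree. Nesting is
the classic signature of lateral gene transfer (LGT) from bacteria to
the eukaryotes. But an observed nesting with weak bootstrap support is
not evidence by itself: the question is whether the nested placement is
*statistically distinguishable* from plausible alternatives, such as the
focal clade attaching outside the bacterial group altogether ("vertical"
history).

`lgtplace` turns that question into a reproducible procedure:

1. remove the focal clade from the base maximum-likelihood tree;
2. enumerate **all** legal re-attachment points, under constraints
   (protected clades stay intact, strongly supported edges are not used,
   an optional scope restricts attachments to one sub-family);
3. re-optimize branch lengths for every resulting topology and record
   per-site log-likelihoods;
4. compare topologies with the Shimodaira–Hasegawa (SH) test using RELL
   bootstrapping;
5. report which placements can and cannot be rejected.

If the nested placement survives while the vertical one is rejected, the
data actively support transfer; if both survive, the data cannot decide.
In the termite-symbiont cellulase setting this is precisely the argument
by which a symbiont clade nested inside a bacterial sub-family is read
as evidence of transfer.

Step 2 deliberately replaces the traditional manual step — moving the
clade by hand to a few positions chosen by eye — with an exhaustive,
constraint-driven enumeration, so runs are reproducible and complete.

## Model

Amino-acid substitution follows the general time-reversible form: a
symmetric exchangeability matrix $S$ (WAG, LG, or Poisson) and
stationary frequencies $\pi$ give rates $Q_{ij} = S_{ij}\pi_j$, scaled
so the mean rate $-\sum_i \pi_i Q_{ii} = 1$; branch lengths are then
expected substitutions per site. Frequencies are the model's published
vector, or the alignment's empirical proportions under `+F` (with a
$10^{-6}$ pseudocount per residue so none is zero).

Among-site rate variation uses the standard discrete-gamma
approximation: $k$ equal-weight categories (default $k = 4$, the
conventional choice for protein data) whose rates are the conditional means of
$\Gamma(\alpha, \alpha)$ over its probability quantiles, renormalized to
mean exactly 1. `+I` adds an invariant class with proportion
$p_{\mathrm{inv}}$: a site's likelihood is

$$\ell_s = p_{\mathrm{inv}}\,\ell_s^{(0)} +
 (1 - p_{\mathrm{inv}})\,\frac{1}{k}\sum_{c=1}^{k} \ell_s^{(r_c)},$$

where $\ell_s^{(0)}$ is $\pi$ of the observed residue for a constant
(or all-missing) column and zero otherwise — the standard `+I`
definition.

Likelihoods are computed by Felsenstein pruning with per-node rescaling
(accumulated log scalers), so 60+ taxon alignments stay inside double
range. Transition matrices come from the symmetric eigendecomposition of
$\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$, valid because
the models are reversible; the decomposition is done once per model and
reused for every branch and rate category. Gaps and the ambiguity codes
X, B, Z, J, U, O are all treated as missing data and contribute all-ones
partial likelihoods.

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `alpha` | gamma shape (unitless) | fitted; init 1 | typical protein values 0.5–1.5 |
| `p_inv` | invariant proportion | fitted; init 0.1 | bounded in [0, 0.99] |
| `k` | gamma categories | 4 | conventional for protein data |
| branch bounds | substitutions/site | [1e-8, 10] | avoids degenerate optima |
| `support_threshold` | bootstrap % above which an edge may not receive an attachment | 70 | common "strong support" convention |
| `B` | RELL replicates | 1000 | standard; p-values use the $(\#+1)/(B+1)$ correction so Monte-Carlo zeros cannot occur |
| `alpha` (test) | SH rejection level | 0.05 | one-sided, matching the Yes/No reporting convention |
| `reopt` | per-topology re-optimization | `"branches"` | branch lengths are refit per topology; `"full"` also refits rate parameters; published pipelines differ, so both are exposed |

Branch-length optimization is coordinate ascent: one sweep visits every
edge in pre-order and solves each one-dimensional problem by bounded
Brent search against the *current* state of all other edges (partials
above the edge are updated incrementally on the way down, partials below
are unaffected by edges above), so a sweep can never decrease the
likelihood. Sweeps repeat until the gain drops below `tol` (default
1e-4 log units; per-topology evaluation inside the SH pipeline uses
0.01, since topology decisions ride on log-likelihood differences
orders of magnitude larger). After the first sweep each edge is only
refined within a local bracket around its current value — the incumbent
is evaluated first, so this cannot break monotonicity, and it roughly
halves the optimization cost on 60-taxon problems. Model fitting
alternates one branch sweep with one bounded fit of
$(\alpha, p_{\mathrm{inv}})$, at most 20 cycles. Model
selection ranks candidates by $\mathrm{AIC} = 2k - 2\ln L$, counting
gamma shape, invariant proportion and 19 free frequencies for `+F`;
branch lengths are common to all candidates and not counted.

## The SH test as implemented

With per-site log-likelihood rows $\ell_{a,s}$ for topologies $a$:
observed deficits $D_a = \max_{a'} \ln L_{a'} - \ln L_a$; each RELL
replicate $b$ draws multinomial site weights $w$ (summing to the site
count) and sets $\tilde L_{a,b} = \sum_s w_s \ell_{a,s}$; centering
$R_{a,b} = \tilde L_{a,b} - \overline{\tilde L_{a,\cdot}}$ yields null
deficits $\tilde D_{a,b} = \max_{a'} R_{a',b} - R_{a,b}$ and

$$p_a = \frac{\#\{b : \tilde D_{a,b} \ge D_a\} + 1}{B + 1}.$$

The reported `SD` is the RELL standard deviation of
$\tilde L_{\mathrm{best},b} - \tilde L_{a,b}$, the per-tree dispersion
classic RELL reports print alongside the likelihood deficit. Ties for the best tree are broken by first
index, and the best row shows $D = 0$ exactly.

## What the synthetic generator emulates — and what it does not

`ghf5_like_bundle()` builds two "bacterial sub-family" clades (22 + 22
taxa by default), a 12-taxon "symbiont" focal clade and a 4-taxon
outgroup — 60 taxa total, a realistic size for a mixed
bacterial-plus-symbiont enzyme family — with coalescent-shaped clades, exponential branch lengths
(mean 0.08 within clades; deeper 0.4-scale stems separating the major
groups so that nested and vertical placements are distinguishable at a
few hundred sites), and 300 aligned sites under WAG+G+I
($\alpha = 0.8$, $p_{\mathrm{inv}} = 0.1$) — a typical protein-family
regime, fixed once as the generator's stated world. Each sub-family's two root
subclades play the role of the "sub-sub-families": the strongly
supported groups a real analysis protects during enumeration. With
`lgt = TRUE` the focal clade is pruned and regrafted onto a donor edge
about half-way inside the largest sub-sub-family of sub-family 1,
splitting the donor edge at its midpoint with a stem of half its length
(a symmetric, reproducible rule; lengths are re-optimized downstream
regardless).

Deliberately **not** emulated: insertions/deletions (gaps appear only
via optional i.i.d. masking), sequencing error, codon-level effects,
among-lineage compositional heterogeneity, and data-driven tree shapes.
A green simulation test therefore establishes that the *inference
machinery* behaves as claimed under the model's own assumptions — not
that the model is adequate for any particular real alignment.

## Numerical choices and degenerate inputs

* Per-node partial rescaling with log-scaler accumulation; columns of
  all-zero partials cannot occur for strictly positive transition
  probabilities, and tiny negative eigen-decomposition round-off is
  clamped to zero.
* A focal set that is not exactly monophyletic is an error — the package
  never silently substitutes the MRCA superset.
* The placement that regenerates the base topology is excluded from the
  alternatives; duplicate topologies are removed by bipartition-set
  equality; enumeration order follows postorder edge indices of the
  backbone, so output order is deterministic.
* An empty candidate set (over-constrained enumeration) is a warning,
  not an error.
* All-identical sequences: branch lengths go to the lower bound 1e-8;
  neighbor joining warns and returns a star-like tree.
* Every user-facing source of randomness takes a `seed`; the pipeline
  derives per-stage child seeds from the global seed by fixed offsets,
  so stages rerun standalone reproduce their in-pipeline behavior.

## Known limitations

* No tree search: the base topology is an input (or the synthetic
  truth, or a neighbor-joining starter); only the focal clade moves.
* Only WAG, LG and Poisson exchangeabilities; no CAT-style mixtures, no
  codon or nucleotide models.
* The SH test is conservative by construction; with many candidate
  topologies its power drops, which is the expected behavior, not a bug
  — the type-I acceptance criterion checks rejection of the true
  topology stays *below* nominal level.
* Branch-length re-optimization per topology is the default
  (`reopt = "branches"`); full per-topology refits of rate parameters
  cost roughly one model fit per topology and rarely change decisions
  in the regimes tested.
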