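---
title: "Position-specific stationary vectors: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific stationary vectors: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssver)
```

## The problem

A transcription factor binding site (TFBS) is usually summarised by a
position weight matrix (PWM): the distribution of nucleotides at each motif
position across binding instances in one species, today.  A PWM says nothing
about *dynamics* — which nucleotides a position tolerates over evolutionary
time.  `pssver` infers, for each motif position, the **stationary vector** of
a nucleotide substitution model fitted to gapless orthologous instances of
the site across species: the long-term equilibrium distribution that
position would reach under continued evolution.  The collection of these
per-position vectors is the **position-specific stationary vector** (PSSV),
the evolutionary analogue of the PWM.  A position under strong purifying
selection has a sharply peaked stationary vector; a neutrally evolving flank
has a stationary vector close to the genomic background.

## Substitution models

Both models are parameterised by a stationary vector
$\pi = (\pi_A, \pi_C, \pi_G, \pi_T)$ and, per branch, an evolutionary time
$t \ge 0$ in units where the mutation event rate is $\mu = 1$.  It is
convenient to work with the *proximity* $q = e^{-t} \in (0, 1]$: $q = 1$
means no evolution, $q \to 0$ means the branch has reached equilibrium.

**F81.**  The Felsenstein 1981 model has the transition probability
$$T_{\alpha\beta}(q) = q\,\delta_{\alpha\beta} + (1 - q)\,\pi_\alpha,$$
with columns indexing the ancestor $\beta$: with probability $q$ the
nucleotide survives the branch unchanged, otherwise it is redrawn from
$\pi$.  This "copy-or-redraw" structure is what every fast path in the
package exploits.  It also gives Chapman–Kolmogorov multiplicativity
directly: $T(q_1)T(q_2) = T(q_1 q_2)$.

**HKY85.**  Adds a transition/transversion rate ratio $\kappa$.  We use the
standard closed form (TN93 specialisation) but deliberately leave the
generator *unnormalised*, with transversion rate 1 and transition rate
$\kappa$, so that at $\kappa = 1$ HKY85 coincides *exactly* with F81 at
$q = e^{-t}$.  This keeps a single time unit across both families; it is a
package convention (the usual alternative normalises to one expected
substitution per time unit, which would rescale all fitted $t$ by
$1 - \sum_\alpha \pi_\alpha^2$ at $\kappa = 1$).  The equivalence, column
stochasticity, stationarity, and detailed balance are all enforced by tests,
and the closed form is checked against an eigendecomposition-based matrix
exponential.

Matrices are column-stochastic with `T[alpha, beta] = P(alpha | beta)`, and
the alphabet order is A, C, G, T everywhere — files, matrices, and reports.

## Likelihood engines

`prune_likelihood()` is Felsenstein's pruning algorithm: a post-order pass
propagating conditional likelihood vectors to the root, contracted with the
root prior $\pi$.  It works for any model and any rooted, possibly
multifurcating tree, and is the package's reference engine.  Batch
evaluation loops over site patterns; the per-locus tree traversal is exactly
the cost the star decomposition removes, so we do not vectorise it away
(representing the pruning recursion as reusable matrices is a known further
optimisation, deliberately left out so that the two engines differ by the
algorithmic idea and not by implementation tricks).

`decompose_sum_of_stars()` implements the F81-specific rewriting.  Under
F81, any rooted tree's site likelihood equals a weighted sum of products of
*star-tree* likelihoods, where a star tree's factor is
$\sum_\alpha \pi_\alpha \prod_k [q_k \delta_{S_k\alpha} + (1-q_k)\pi_{S_k}]$
— one scalar per leaf, $O(\Sigma)$ in alphabet size rather than the
$O(\Sigma^2)$ of a matrix product.  The rewriting picks a *star node* (all
children leaves) with proximity $q_j$ to its parent, and splits the
likelihood into: unmutated (weight $q_j$; the star's leaves merge into the
parent keeping their own proximities) and mutated-and-independent (weight
$1 - q_j$; the star becomes a standalone factor with its own root prior).
Iterating yields a list of terms whose weights are symbolic products of
$q_j$ / $(1-q_j)$ factors tied to branch identities; the decomposition is
done once per topology and re-evaluated for free under new $q$ or $\pi$ —
which matters because ML fitting calls the likelihood thousands of times,
including for numerical derivatives.

Three degenerate rules the rewriting needs: a childless root evaluates to
$\sum_\alpha \pi_\alpha = 1$ and is dropped; removing a star subtree can
leave its former parent childless, in which case that node contributes
$\sum_\beta T_{\beta\alpha} = 1$ and is pruned recursively; and star-node
search is depth-first leftmost-first, so decompositions are byte-for-byte
reproducible.  Term count roughly doubles per processed star node, so the
engine warns beyond 12 leaves and `site_likelihood()` falls back to pruning
there; both study topologies (5 and 7 leaves) are comfortably inside the
useful range.

Equivalence of the two engines is tested over hundreds of random topologies
(including multifurcations) at relative tolerance $10^{-12}$, and both
engines are checked to normalise: summed over all $4^n$ patterns the site
likelihood is 1.

## The inference pipeline

1. **Branch proximities** (`fit_branch_proximities()`).  One shared $q$ per
   branch (plus $\kappa$ for HKY85) is fitted by ML on presumed neutral
   columns with $\pi$ fixed to the mammalian background
   $\pi_A = \pi_T = 0.3$, $\pi_C = \pi_G = 0.2$.  By default the neutral
   columns are the outermost flank column on each side of the motif; any
   explicit column list overrides this.  Under a reversible model the two
   branches meeting at the root are identified only through their product,
   so recovery is judged on that product.
2. **PSSVs** (`fit_pssv()`).  With the tree fixed, each column's $\pi$ is
   fitted independently on the 3-simplex by ML over all site groups.
3. **Ancestral posteriors** (`ancestral_posterior()`).  For each site group,
   $p(\alpha \mid \text{leaves}) \propto P(\text{leaves} \mid \text{root} =
   \alpha)\, b_\alpha$ with the background $b$ as prior; the conditional
   likelihoods are the pruning root partials.
4. **Conditional PSSVs** (`conditional_pssv()`).  The PSSV refitted on the
   subset of groups whose posterior for a chosen ancestral nucleotide at a
   chosen position strictly exceeds 0.5.  Divergence between PSSVs
   conditioned on different ancestral nucleotides at the same position —
   measured per position by the base-2 Jensen–Shannon divergence — is the
   package's probe for compensatory/positional coupling.

### Numerical choices

* $q$ is optimised through a logit transform and $\pi$ through a softmax
  over three free coordinates, so the optimiser (BFGS with numerical
  gradients, relative tolerance $10^{-10}$ on the log-likelihood) is
  unconstrained.  Fits are deterministic: the same data and options give
  bit-identical results.
* Fitted $\pi$ components are floored at $10^{-6}$ (configurable) and
  renormalised, with a warning, when a nucleotide is absent from every leaf
  at a column — the ML optimum is then on the simplex boundary and the raw
  log-likelihood diverges.
* $\hat q$ estimates within $10^{-6}$ of 1 (no observed substitutions) are
  clamped just inside the boundary and flagged.
* Likelihoods are accumulated over loci in log space, after collapsing
  duplicate site patterns with counts ($\le 4^{\text{leaves}}$ unique
  patterns, which bounds the per-iteration cost independently of the number
  of loci).
* Posterior ties at exactly the conditioning threshold are excluded
  (selection is a strict inequality); an empty conditional subset is an
  error, never a silent zero matrix.

### Open choices made here

The transition probabilities inside the ancestral posterior use the
*background* stationary vector, not the fitted PSSV: the conditioning subset
should be selectable before position-specific selection is assumed.  A
`transition_pi` argument exposes the alternative.  Similarly, HKY85 PSSV
fits refit the branch proximities (and $\kappa$) under HKY85 rather than
reusing F81 values; passing any fitted tree switches this.

## The simulator, and what passing tests mean

`simulate_groups()` draws, per site and position, a root nucleotide from the
position's stationary vector and propagates it down the tree with the exact
model transition matrices; optional coupling rules redirect the root draw at
one position conditional on the root draw at another, emulating
ancestral-state coupling while keeping descendant evolution per-column
independent — precisely the structure conditional PSSVs are designed to
detect.  One master seed expands into per-site substreams, so site $i$'s
draw does not depend on how many sites follow.  `inject_turnover()`
resamples whole non-reference lineages from the background, emulating
lineage-specific site loss.

The simulator is the inference model.  Recovery tests therefore validate
correctness of the estimators *under the model*: branch proximities to
within $\pm 0.02$ at 5000 neutral sites on the primate topology, PSSVs to
within total-variation 0.05 per position at 2000 sites, and $>80\%$ correct
ancestral assignment in the conditional-mixture setting (the package's
acceptance checks recompute all of these).  What they do not show: real
TFBS data contain alignment error, indel-driven orthology mistakes,
context-dependent mutation (notably CpG deamination), heterogeneous
turnover, and motif instances that are false positives of the scanner.
PSSVs fitted to such data inherit those artefacts; the scrambled-motif
information-loss comparison is the package's built-in control for part of
this.

## Problem sizes and defaults

| Quantity | Default | Rationale |
|---|---|---|
| Background $\pi$ | (0.3, 0.2, 0.2, 0.3) | approximate mammalian genome composition |
| Neutral columns | outermost flanks | least motif-constrained positions available per locus |
| PWM pseudocount | 0.5 per cell | keeps log-odds finite for unseen nucleotides; information formulas also accept raw counts |
| Probability floor | $10^{-6}$ | boundary guard, below any biologically distinguishable frequency |
| Conditioning threshold | posterior $> 0.5$ | majority ancestral nucleotide, strict |
| Star-engine leaf guard | 12 | term count doubles per star node |
| Recovery test sizes | 5000 / 2000 / 1500 sites | sizes at which the estimators' sampling error sits well inside the stated tolerances |

## Known limitations

* Per-column independence is baked in: the PSSV model itself cannot express
  positional dependence — conditional PSSVs *detect* it but do not model it
  jointly.
* No rate heterogeneity (no $\Gamma$), no GTR, no indels, no
  context-dependent mutation.
* The star decomposition is F81-specific; HKY85 always uses pruning.
* Branch lengths are always fitted or user-supplied; the package ships only
  the two study topologies, with placeholder lengths.
* Joint optimisation of tree and PSSVs is out of scope; proximities are
  fitted once on neutral columns and reused.
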