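---
title: "Sampling RNA branching under the NNTM: model, chain and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling RNA branching under the NNTM: model, chain and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treegibbs)
```

## The model

An RNA secondary structure's branching pattern, stripped of all
sequence-level detail, is a plane tree: a rooted tree with ordered children.
Edges stand for helices, leaves for hairpin loops, non-root nodes of down
degree one for helices interrupted by an interior loop, nodes of down degree
two or more for multiloops, and the root for the exterior loop. There are
Catalan-many (C_n) trees with n edges.

Under the Nearest Neighbor Thermodynamic Model the free energy of such a
structure is additive over its loops. With the seven aggregate quantities
a, b, c (multiloop penalty, per-unpaired-nucleotide penalty, per-branching
helix penalty), h (helix), f (hairpin), i (interior loop) and g (dangles),
all in kcal/mol, the total is

$$d_0 f + d_1 i + \sum_{j \ge 2} d_j\,\bigl(a + 4b(j{+}1) + c(j{+}1) + g(j{+}1)\bigr) + n h + g r ,$$

where $d_j$ counts non-root nodes of down degree $j$ and $r$ is the root
degree. Using the identities $\sum_k d_k = n$ and $\sum_k k\,d_k = n - r$
this collapses to the linear form
$\alpha d_0 + \beta d_1 + \gamma r + \delta n$ with

$$\alpha = f - a - 4b - c - g,\qquad \beta = i - a - 8b - 2c - 2g,\qquad
\gamma = -4b - c,\qquad \delta = a + 8b + 2c + h + 2g .$$

`full_structure_energy()` evaluates the first form and
`derive_coefficients()` + `tree_energy()` the second; the package's test
suite checks that the two routes agree to 1e-9 on complete enumerations
under randomised parameter sets. At fixed size the $\delta n$ term is
constant, and the exterior-loop term $\gamma r$ is dropped from the sampled
energy — its contribution is small against the total, and excluding it makes
the bijection below carry the energy exactly. Both terms remain available in
`tree_energy()` behind explicit flags, and $\gamma$, $\delta$ are always
computed and reported.

The target distribution is the Gibbs measure $g(t) = e^{-E(t)}/Z$ with
$E(t) = \alpha d_0 + \beta d_1$. The energy enters the exponent as a bare
number, i.e. in whatever units the coefficients carry, with no RT divisor;
this matches the published form of the model, and a user who wants a thermal
scale can fold it into $\alpha, \beta$ directly.

Six published parameter sets are built in (`nntm_turner()`): the Turner
1989, 1999 and 2004 rules evaluated for the two combinatorial sequences with
(Y,Z) = (C,G) and (G,C). Their reduced coefficients span
$\alpha \in [-2.8, 2.3]$, $\beta \in [-3.0, 1.9]$. Coefficients are carried
at full floating precision; the one-decimal printed values are display
rounding only.

## The path representation

Sampling operates on 2-Motzkin paths: strings over $\{U, H, I, D\}$ of
length $m = n - 1$ in which no prefix holds more Ds than Us and the totals
balance. The bijection with plane trees labels each edge (leftmost edge off
a branching non-root node U, rightmost D, the single edge off a degree-one
non-root node I, everything else H), reads labels in preorder and drops the
leading H. It transports the two statistics that carry energy:
$|x|_I = d_1(t)$ and $|x|_U + |x|_H + 1 = d_0(t)$, so the path energy
$E(x) = \alpha(|x|_U + |x|_H + 1) + \beta |x|_I$ equals the tree energy
exactly. `tree_to_path()` / `path_to_tree()` implement the two directions;
the inverse is the stack algorithm that pre-seeds the root's first child, so
the empty path maps to the single-edge tree. Both are validated by full
round-trips over every tree with up to 8 edges.

## The chain

One step of the sampler (`chain_step()`, compiled inner loop in
`src/chain.cpp`):

1. draw a move type $l$ uniformly from $\{1,2,3,4\}$;
2. $l=1$: pick an adjacent pair uniformly from the $m-1$ positions; replace
   UD by HH with probability $e^{-\alpha} / (2(1+e^{-\alpha}))$ or HH by UD
   with probability $1/(2(1+e^{-\alpha}))$;
3. $l=2$: pick a position uniformly; recolour I to H with probability
   $e^{-\alpha}/(2(e^{-\alpha}+e^{-\beta}))$ or H to I with probability
   $e^{-\beta}/(2(e^{-\alpha}+e^{-\beta}))$;
4. $l=3$: pick two positions independently and uniformly; if both hold U or
   D symbols, swap them with probability 1/2, reverting if the result
   violates the prefix condition;
5. $l=4$: pick an adjacent pair; if exactly one symbol is U/D and the other
   H/I, reverse the pair with probability 1/2.

Every move is its own inverse as a proposal, and the Bernoulli probabilities
are chosen so that $\pi(x)P(x,y) = \pi(y)P(y,x)$ holds move by move — e.g.
for the UD/HH toggle the energy changes by exactly $-\alpha$ (one leaf
becomes two, one fewer U), and the ratio of the two Bernoulli probabilities
is $e^{-\alpha}$. The built-in factor 1/2 everywhere keeps the chain lazy,
hence aperiodic; irreducibility follows because any path can be walked to
the all-H string (move colours right with $l=4$, collapse UD pairs with
$l=1$, recolour with $l=2$) and every step is reversible. The all-H path is
therefore the default initial state.

Two conventions the pseudocode of the source model leaves open are fixed
here as follows. The fourth move's pair is the adjacent pair $(i, i+1)$, as
the prose describes (the pseudocode's stray index is read as a typo). The
third move draws its two indices independently, so $i = j$ is allowed and
ordered pairs are counted; a draw that swaps equal symbols (or $i=j$) is an
identity move and contributes to the self-loop probability. At $m = 1$ the
adjacent-pair moves have an empty index range and are automatic no-ops.
These choices are exactly mirrored in the exact transition matrix, which is
what makes the kernel-equivalence test meaningful.

### Randomness and reproducibility

All randomness comes from R's global RNG (`unif_rand` in the compiled code),
so `set.seed()` — or the `seed` argument of `run_chain()` — makes runs
bit-reproducible. The draw-order contract per step is: move type, then the
index (or two indices) of that move, then one uniform consumed as the
Bernoulli. Reproducibility is promised within one build of the package; it
is not a cross-version guarantee.

## Exact oracles and what "tested" means

For $m$ small enough to enumerate (default caps: 10 for distributions, 8
for matrices; C_9 = 4862 states is the practical matrix limit), the package
computes the Gibbs distribution by enumeration (`exact_distribution()`, log
space with a max shift so large $|\alpha|, |\beta|$ or $m$ cannot overflow),
the full one-step transition matrix (`transition_matrix()`, summing move
types, index choices and Bernoulli factors into each off-diagonal entry),
and diagnostics (`spectral_diagnostics()`): maximum detailed-balance
violation, total variation between the leading left eigenvector and the
Gibbs distribution, $|\lambda_1|$ and the spectral gap, and a
strong-connectivity verdict.

The shipped tests certify, among other things: detailed balance below
1e-12 and eigenvector agreement below TV 1e-10 for $m \le 6$ under all six
built-in coefficient pairs and the uniform case; empirical one-step
frequencies within 4-sigma binomial bands of the matrix entries at
$10^6$ trials per start state; and total variation below 0.02 between a
million-step thinned run at $m = 4$ and the enumerated distribution. Those
sizes are chosen so the full suite runs in about a minute and a half; the
properties they check (move-by-move balance, kernel equivalence) are
size-uniform by construction, but the numerical certificates themselves are
small-instance statements.

These samples *emulate* branching of the combinatorial model only. They say
nothing about sequence-dependent effects (stacking, loop-length rules,
pseudoknots) — real structures predicted from real sequences will deviate
from this null in ways the model deliberately ignores. Passing tests mean
the sampler draws from the stated Gibbs distribution on plane trees, not
that the distribution matches any structure database.

## Branching statistics and dispersion

`tree_statistics()` reports hairpins, interior loops, root degree, maximum
and count of multiloops (root excluded: it models the exterior loop), height
and diameter. "Maximum ladder distance" is a sequence-level notion; on the
tree abstraction, with each edge one helix, the closest analogue is the tree
diameter in edges, and it is labelled as such — an operationalisation of
this package, kept out of any external comparison. Dispersion summaries use
the unbiased variance and nearest-rank quantiles (no interpolation, which
would be artificial on integer statistics). `placement()` reports the
percentile (midpoint convention on ties) and z-score of an observed value
against the sampled null.

## Numerical choices

* Move probabilities are evaluated in logistic form,
  $1/(2(1+e^{\pm\alpha}))$ and $1/(2(1+e^{\pm(\alpha-\beta)}))$, which is
  exact and saturates gracefully for extreme user-supplied coefficients.
* Gibbs weights are normalised in log space with a max shift.
* `catalan_number()` / `motzkin_number()` use integer-exact recurrences
  (Catalan convolution; binomial sum over Catalans) and refuse n > 30, past
  which the values exceed the exact-integer range of a double. No
  arbitrary-precision dependency is used.
* Validity re-checks after the U/D swap are a full O(m) prefix scan; at the
  path lengths this package targets (m up to a few thousand) the scan is
  negligible against the per-step constant.
* Path positions are 1-based in all user-facing contracts; the compiled
  kernel indexes from 0 internally.
* Trees serialise as balanced-parenthesis strings (child subtrees
  concatenated inside the parent, root parentheses omitted), which are
  unambiguous, diffable and order-preserving; a Newick export is provided
  for viewers. Traversals are iterative, so chains thousands of edges deep
  neither recurse nor overflow.

## Defaults

`run_chain()` defaults: all-H initial state, no burn-in, thinning 1 — the
caller states the run length explicitly. The worked examples and tests use
$10^5$–$10^6$ steps with 5–10% burn-in and thinning 10–20, which at the
acceptance sizes ($m \le 8$) gives effective samples in the tens of
thousands; for larger m the spectral gap shrinks polynomially and runs
should be scaled accordingly (the theory behind the chain bounds the
relaxation time by a polynomial in m, but the constants are impractically
large; diagnostics, not the bound, should guide run lengths).

## Known limitations

* The sampled energy uses $\alpha, \beta$ only; $\gamma$ (exterior loop) is
  reported, never sampled. Structures whose exterior-loop branching matters
  will be mis-weighted relative to the full linear model.
* No folding engine: the package never touches sequences or dot-bracket
  strings; inputs are trees, paths or the built-in parameter sets.
* Single-chain diagnostics only; no parallel tempering or multi-chain
  convergence machinery. For the enumerable sizes the exact oracles are
  strictly stronger; beyond them, users should monitor acceptance tallies
  and compare thinned-run summaries across seeds.
* Exact oracles are exponential in m by nature and capped accordingly.
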