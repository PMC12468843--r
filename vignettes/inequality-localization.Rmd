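---
title: "Localizing inequality with recursive entropy-based Hahn decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing inequality with recursive entropy-based Hahn decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqtree)
```

## The model

Global inequality summaries (a Gini coefficient, a single entropy value)
say how unequal a distribution is, not *where* the inequality sits. This
package implements a decomposition that answers the second question.

The central quantity is the **degree of uniformity** of a measurable part
$P$ of a probability distribution:

$$\frac{D_P}{c_P}, \qquad
  c_P = \sum_{i \in P} p_i, \qquad
  D_P = e^{H_P}, \qquad
  H_P = -\sum_{i \in P} \frac{p_i}{c_P}\ln\frac{p_i}{c_P},$$

with integrals replacing sums for a density $p(x)$. $D_P$ is the
exponential of the conditional Shannon entropy of the part -- the Hill
number of order one of the renormalized restriction: the size of the
uniform ("Shannon-equivalent equiprobable") distribution carrying the same
uncertainty. Dividing by the mass $c_P$ gives an intensity: effective
uniform extent per unit probability. For a discrete uniform over $K$ atoms
it is $K$; for a singleton it is $1/p_i$; its reciprocal $c_P/D_P$ measures
concentration. Two parts -- even from different distributions -- compare
through the ratio of their degrees of uniformity.

Fixing a reference degree of uniformity $r$ defines a **signed measure**

$$m_r(P) = c_P \ln\frac{D_P/c_P}{r}
         = -\sum_{i\in P} p_i \ln(p_i\, r),$$

which is additive over disjoint parts, positive exactly on parts more
uniform than the reference, and zero on parts exactly as uniform. Taking
$r$ to be the degree of uniformity of a parent part $A$ (so the threshold
probability is $c_A/D_A$), the Hahn decomposition of $m_r$ on $A$ is
*explicit and ternary*:

* $P_A = \{\,p < c_A/D_A\,\}$ -- the largest strictly positive set (every
  subset is more uniform than $A$),
* $Z_A = \{\,p = c_A/D_A\,\}$ -- the largest null set (every subset exactly
  as uniform as $A$),
* $N_A = \{\,p > c_A/D_A\,\}$ -- the largest strictly negative set.

`hahn_split()` computes this triple; `maximality_oracle()` confirms the
maximality claim by exhaustive enumeration on small discrete parts.

Recursing on $P$ and $N$ (a null part $Z$ is uniform, hence unsplittable;
it is carried down unchanged at its ordered position) yields the
**ternary localization tree** built by `build_tree()`. Because subsets of a
strictly positive set are strictly positive (and likewise for negative),
every level of the tree lists parts in strictly decreasing degree of
uniformity, and *random subsets* of two same-level parts inherit that
ordering -- the property `monotonicity_audit()` spot-checks. Conservation
ties the levels together: for any partition of $A$ into parts $A_j$,

$$\Bigl(\tfrac{D_A}{c_A}\Bigr)^{c_A} =
  \prod_j \Bigl(\tfrac{D_{A_j}}{c_{A_j}}\Bigr)^{c_{A_j}}.$$

## Worked examples

The binomial distribution $B(8, 0.4)$ decomposes to singleton leaves:

```{r binomial}
b <- fixture_binomial(8, 0.4)
tr <- build_tree(b)
tr
level_view(tr, 2)[, c("part", "mass", "dou")]
```

The tails (rare outcomes) carry high degree of uniformity -- the singleton
{8} reaches $1/p_8 \approx 1525.88$ -- while the mode {3} is the most
concentrated part. The exponential density with rate 2 splits first at
$x = 1/2$ (where $p(x) = 1/D = 2/e$), and the recursion refines toward the
origin, where concentration is highest:

```{r exponential}
e <- exponential_density(2)
tre <- build_tree(e, max_depth = 3)
round(level_breakpoints(tre, 2), 4)
round(level_breakpoints(tre, 3), 4)
```

A designed ternary split with a genuine null set:

```{r null}
d <- realize_discrete(null_design(D = 10, cZ = 0.6, eta1 = 2, eta2 = 0.5))
hahn_split(d)
```

## Tunable parameters

* `z_tol` (default `1e-9`, relative): the half-width of the null band
  around the threshold $c_A/D_A$. Exact equality $p_i = c_A/D_A$ holds only
  for designed examples, and even there floating point perturbs it, so
  membership in $Z$ is decided within a relative band. Ties resolve toward
  $Z$, which keeps designed null sets intact under rounding noise. Widening
  this tolerance merges near-threshold atoms into $Z$; at `1e-9` only
  designed equalities qualify in practice.
* `max_depth`: unlimited for discrete sources, which terminate naturally
  (singletons, uniform parts); 3 for continuous sources, where the
  recursion has no natural end and three rounds already separate the
  support into eight uniformity bands.
* `min_mass` (default 0 = off): optional stop for heavy-tailed continuous
  sources where branches of vanishing mass would otherwise be refined
  indefinitely at increased depth limits.
* Root finding (`grid_n = 1024`, `root_tol = 1e-10`): each declared
  monotone segment is scanned on a grid for sign changes of $p(x) - t$ and
  the single bracket is refined by bisection to width `root_tol`. More than
  one sign change on a declared monotone segment raises an error rather
  than guessing, since it means the declaration is wrong.
* `tail_tol = 1e-12`: an infinite tail is truncated, for scanning only,
  where its remaining mass falls below this; the resulting parts still
  extend to infinity.

## Numerical choices and degenerate inputs

Entropy is in nats throughout; there is no log-base option. The convention
$0\ln 0 = 0$ is enforced structurally: zero-probability atoms are removed
at construction (and recorded), so no entropy sum ever meets one.
Summaries of empty or zero-mass parts are errors, not `NaN`s. Continuous
parts are finite unions of open intervals -- boundary points carry no mass,
so endpoint status is not tracked, and the recursive splitter provably
stays within this class for piecewise-monotone densities. Differential
entropy may be negative (diversity below one); the degree of uniformity is
positive in every case. A uniform part splits trivially and terminates as
`"uniform"` -- distinct from `"null_set"`, which marks a Z-child: uniform
leaves appearing at the bottom of a tree are *not* null sets of their
parents. Splitting a singleton returns it as the null set of itself, which
is why singletons terminate.

Level indexing starts at the root = level 0, so "level $k$" holds the
result of $k$ split rounds. Displayed degrees of uniformity are rounded
(two decimals by default) only at print time; stored values keep full
precision.

One algebraic choice deserves a note. The mass-balance system behind
`solve_masses()` -- $c_P\ln\eta_1 + c_N\ln\eta_2 = 0$ with
$c_P + c_N = 1 - c_Z$ -- must pair $c_P$ with $-\ln\eta_2$ and $c_N$ with
$\ln\eta_1$; the opposite pairing satisfies the constraint only in the
symmetric case $\eta_1\eta_2 = 1$ (which the classic worked example,
$\eta_1 = 2$, $\eta_2 = 1/2$, happens to be). Every solver output is
validated against $\eta_1^{c_P}\eta_2^{c_N} = 1$ at `1e-10`.

## What the synthetic generators emulate

No published datasets accompany the applied examples this method targets,
so the package generates its own study material:

* `fixture_binomial()` and `fixture_exponential()` are the canonical
  discrete/continuous cases with exact pmf/closed-form entropies.
* `fixture_incidence()` emulates an age-stratified incidence histogram: 20
  five-year age bands, unimodal with a peak around 12% and geometric taper,
  plus a seeded jitter small enough never to reorder neighbouring bands.
  Defaults (20 bins, peak at band 4, decay 0.8) give a shape with a
  realistic mode height; strict unimodality without ties makes every split
  binary, as observed on real incidence curves.
* `fixture_monotone_load()` emulates a monotonically increasing load
  profile (stress fractions along a beam): strictly increasing seeded
  increments, again yielding binary splits only.
* `carryover`-style designed distributions (in the test helpers) and
  `null_design()` realizations cover the ternary case with an exact null
  band.

These generators reproduce the *structural* features that drive the
decomposition -- modality, monotonicity, ties at the threshold -- but not
sampling noise, overdispersion, or measurement error in real histograms.
Passing tests therefore demonstrate the correctness of the decomposition
machinery, not robustness of scientific conclusions drawn from noisy data;
on real data, near-ties that fall inside `z_tol` would be the main
sensitivity to check.

Problem sizes used throughout the tests and the reproduction script --
distributions of 2-21 atoms, brute-force enumeration up to 12 atoms,
trees to depth 3 on continuous supports, audits of a few hundred sampled
subset pairs -- keep every computation deterministic and fast while
exercising each code path; the enumeration oracle's cost grows as $3^n$,
which is why it is a test-support device rather than an analysis tool.

## Known limitations

* Discrete supports must be finite; truncate infinite discrete
  distributions before analysis (diversity is then that of the truncated
  object -- there is no principled default truncation).
* Continuous densities must come with correct piecewise-monotonicity
  declarations; level sets of densities with infinitely many monotone
  segments are out of scope.
* Only the order-one (Shannon) diversity is implemented; other Hill
  numbers weight richness and evenness differently and would change every
  threshold.
* The maximality oracle is exponential by design and refuses parts beyond
  20 atoms.
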