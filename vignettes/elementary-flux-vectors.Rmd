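---
title: "Elementary flux modes and elementary flux vectors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elementary flux modes and elementary flux vectors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmodes)
```

## The model

A metabolic network is described by its stoichiometric matrix
$N \in \mathbb{Q}^{m \times n}$ (net coefficients of $m$ internal metabolites
in $n$ reactions) and a set $Irr$ of irreversible reactions. At steady state
the feasible net rate vectors form the **flux cone**

$$FC = \{r \in \mathbb{R}^n \mid N r = 0,\; r_i \ge 0 \text{ for } i \in Irr\}.$$

External metabolites are represented by omission: they contribute no row of
$N$. The **elementary flux modes** (EFMs) are the nonzero, support-minimal
vectors of $FC$ — the minimal pathways and cycles. Equivalently they are the
conformally nondecomposable vectors: no EFM is a sum of other cone vectors
without sign cancellations. EFMs generate the cone conformally, and deleting
reactions shrinks the EFM set to exactly the EFMs avoiding those reactions.

Inhomogeneous linear constraints $G r \ge h$ (flux bounds, measured rates,
fixed objective values) turn the cone into a **flux polyhedron**
$FP = FC \cap \{G r \ge h\}$, where support minimality no longer
characterizes the interesting vectors. The **elementary flux vectors** (EFVs)
are defined by intersecting $FP$ with every closed orthant: each
subpolyhedron is pointed and has a unique minimal generating set (vertices
plus extreme rays of its recession cone); the union over all $2^n$ orthants
is the EFV set. Bounded EFVs are unique points; unbounded EFVs are unique up
to positive scaling. EFVs inherit the three key EFM properties: conformal
generation (every $x \in FP$ is a convex combination of bounded EFVs plus a
conic combination of unbounded EFVs, without cancellations), the subnetwork
property (knockouts filter the set), and conformal nondecomposability.

## Computation

EFV enumeration reduces to EFM enumeration by homogenization with slack
variables. The augmented cone

$$D w = \begin{pmatrix} N & 0 & 0 \\ G & -I & -h \end{pmatrix}
\begin{pmatrix} r \\ s \\ \lambda \end{pmatrix} = 0, \qquad
r_i \ge 0\ (i \in Irr),\; s \ge 0,\; \lambda \ge 0,$$

has the shape of a flux cone; its EFMs $(r, s, \lambda)$ map to the EFVs of
$FP$: $\lambda > 0$ gives the bounded EFV $r/\lambda$, $\lambda = 0$ an
unbounded EFV $r$, and an unbounded EFV with $s = 0$ and $r_i = 0$ on $Irr$
lies in the lineality space of the recession cone. `homogenize()` builds the
block matrix; `enumerate_efvs()` runs the pipeline and back-maps.

The EFM core (`enumerate_efms()`) splits every reversible reaction into
forward and backward nonnegative columns. In the resulting standard-form cone
$\{x \ge 0 \mid N' x = 0\}$ the support-minimal vectors coincide with the
extreme rays, which are enumerated by an incremental double-description pass:
starting from the unit rays of the nonnegative orthant, each equality row is
processed in turn, keeping the rays on the hyperplane and combining adjacent
positive/negative pairs. Adjacency is tested combinatorially (two rays are
adjacent iff no third ray's zero set contains the intersection of their zero
sets); an algebraic rank test would be equivalent but the combinatorial test
needs no arithmetic. Constraint order is chosen greedily by the smallest
number of positive/negative pairs; the order affects speed, never the
output. Split two-cycles (forward plus backward of one reaction) project to
zero and are dropped; reversible EFMs are recovered in a canonical
orientation (first nonzero entry positive) with a `reversible` flag.

### Exact arithmetic

There is no arbitrary-precision rational package available in this
environment, so the package carries its own small exact kernel: rationals are
numerator/denominator pairs in doubles (every integer up to $2^{53}$ is exact
in a double and multiplication is correctly rounded, so a post-hoc
$|x| \le 2^{52}$ guard certifies exactness); all elimination is
fraction-free with per-row gcd reduction. Any computation that would leave
the safe range aborts with an explicit overflow error rather than rounding.
Decimal strings in input files are interpreted as decimal fractions
(`0.1` is $1/10$, never the binary double), and `p/q` strings are accepted
everywhere. There is no floating-point mode in the enumeration core.

### Equality constraints

A user equality contributes two canonical half-rows (negated coefficients and
right-hand sides). By default `enumerate_efvs()` folds each pair into the
equality block of the augmented cone (one row appended to $N$ with the
homogenized right-hand side $-c\lambda$), which removes two slack columns per
equality from the enumeration; `fold_equalities = FALSE` forces the literal
two-slack-row treatment. Both routes provably produce the same EFV set, and
the test suite checks this on the four-row optimal-face system and on random
instances.

### Degenerate inputs

* A cone equal to $\{0\}$ yields an empty EFM set.
* An empty polyhedron (no $\lambda > 0$ augmented EFM) yields a warning; any
  recession-cone rays are still returned, which keeps knockout filtering and
  re-enumeration consistent even when a knockout empties the polyhedron.
  With no rays either, the set is empty.
* The zero EFV is computed and kept (class `"zero"`): it is needed to
  generate the polyhedron, while the analysis operations exclude it where
  only nonzero flux distributions are meaningful.

## The verification oracle

`enumerate_evs_bruteforce()` implements the orthant definition directly:
candidate vertices are basic solutions of $n$ active hyperplanes (rows of
$A = (N; -N; I_{Irr}; G)$ and coordinate hyperplanes) of full rank, candidate
rays come from rank-$(n-1)$ subsets of the homogeneous system. A candidate is
a generator of the subpolyhedron of an orthant containing it iff its active
rows plus its zero-coordinate rows reach the defining rank — a test that does
not depend on which compatible orthant is chosen, so the union over all
$2^n$ orthants is computed in one pass over the candidates.
`subpolyhedron_generators()` exposes the literal per-orthant operation. The
oracle shares no code with the double-description path beyond the arithmetic
kernel and is the standard the production path is tested against (one hundred
seeded random instances in the acceptance suite). It is exponential by
design and guarded to small $n$.

## Analysis layer

* **Rate optimization** (`optimize_rate()`): the optimum of $c^\top r$ over a
  polyhedron is unbounded iff some unbounded EFV improves it; otherwise it is
  attained at a bounded EFV, and the optimal face is spanned by all
  optimum-attaining bounded EFVs together with the unbounded EFVs orthogonal
  to $c$. Flux-variability-style per-reaction ranges are just unit
  objectives; no separate implementation exists.
* **Yield optimization** (`optimize_yield()`): yields $c^\top r / d^\top r$
  are evaluated per EFV. With a positive denominator over the polyhedron the
  per-EFV maximum is the supremum; it is attained iff a bounded EFV reaches
  it. An unbounded EFV with $d^\top u = 0$ and $c^\top u > 0$ makes the yield
  unbounded. `strict = TRUE` (default) enforces the theoretical precondition
  $d^\top v > 0$ on every nonzero bounded EFV and names a witness on failure;
  `strict = FALSE` gives the classic per-EFV comparison that simply skips
  zero-denominator vertices — useful, but if a skipped vertex has
  $c^\top v > 0$ the supremum over the polyhedron itself is infinite even
  though the per-EFV maximum is finite. Yield optima are cross-checked in the
  tests against an independent lifted linear program (the Charnes–Cooper
  substitution $y = r/(d^\top r)$, $t = 1/(d^\top r)$, solved by vertex
  enumeration on the lifted polyhedron).
* **Coupling** (`coupling()`): full coupling requires one constant exact
  ratio including sign across all nonzero EFVs; a sign conflict demotes a
  pair to partially coupled. Partial coupling is both-zero-or-both-nonzero;
  directional coupling is support implication. The definitions leave the
  asymmetric zero/nonzero case to directional coupling only; this is the
  documented set logic, applied literally.
* **Essentiality**: a reaction is essential if it occurs in every nonzero
  bounded EFV, falling back to the unbounded EFVs when no nonzero bounded EFV
  exists; blocked means zero in every EFV. A set containing only the zero EFV
  has every reaction blocked and none essential.
* **Decomposition** (`decompose()`): the target is embedded into the
  augmented split cone $(r, s, \lambda)$ and reduced by a greedy
  largest-conformal-step loop over the mode-derived generators. Each step
  zeroes at least one residual coordinate, so the loop terminates in at most
  $\dim$ steps; because the residual stays in the cone and the EFVs are its
  complete set of conformal generators, a conformal candidate always exists
  and the greedy cannot fail on a correct mode set (a failure raises an
  internal error, by design). Weights are exact; the convex weights of
  bounded EFVs sum to one automatically because the homogenization coordinate
  of the target is 1. Non-uniqueness is resolved deterministically
  (largest step, then generator order).

## Synthetic instances

`random_model()` draws sparse integer stoichiometries in $[-3, 3]$ (each
entry nonzero with probability 0.6), a reversibility fraction, and flux
bounds. Nonemptiness of the polyhedron is enforced constructively: a witness
point is first sampled as a small conic combination of the network's own
EFMs and every bound is placed to contain it, so property suites never need
rejection logic; networks with trivial cones are resampled. Sizes default to
the oracle-friendly range ($n \le 6$, a handful of rows) used by the tests.
These instances emulate the combinatorics of small reaction networks —
exact rational data, mixed reversibility, feasible bounds — and deliberately
not the biology of curated models (no mass balance realism, no
thermodynamics, no genome-scale sparsity). A green property suite therefore
establishes algorithmic correctness on the stated class of inputs, not
biological validity of any particular model.

Whole-genome or central-metabolism case studies (hundreds of thousands of
EFMs/EFVs) are outside the intended scale of this implementation: the double
description here is pure R over exact rationals with a combinatorial
adjacency test, appropriate for models up to a few dozen reactions. The
published large-scale numbers for *E. coli* central metabolism require an
externally distributed model and dedicated high-performance enumeration
tools, and are deliberately not reproduced here.

## Known limitations

* The exact kernel aborts (rather than degrades) past $2^{52}$; extremely
  ill-scaled rational inputs can hit the guard.
* `optimize_yield()` assumes maximization; minimize by negating $c$.
* The oracle is exponential and guarded at $n \le 10$ (practically useful to
  $n \approx 6$).
* SBML support is a minimal Level-3 reader (species, reactions,
  stoichiometries, reversibility, optional fbc bounds behind
  `import_bounds = TRUE`); it is read-only and ignores compartments and
  gene–protein–reaction rules. Units are treated as metadata throughout:
  rates are dimensionless rationals.

## Worked example

```{r example}
ex <- example_model("bounded")   # r1 <= 2, r2 >= -1
efvs <- enumerate_efvs(ex$network, ex$constraints)
mode_matrix(efvs)

optimize_rate(efvs, objective(ex$network, c(R2 = 1, R3 = 1)))$value  # 2
knockout(efvs, "R2")

dec <- decompose(c(2, 1, 1), efvs)
dec$weights[, c("class", "weight")]
```
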