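---
title: "Simulating DNA alignments under discrete-time Markov models on trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating DNA alignments under discrete-time Markov models on trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmsim)
```

## The model family

Most sequence simulators work in continuous time: a rate matrix $Q$ is fixed
(usually one stationary, time-reversible $Q$ for the whole tree) and each edge
of length $t$ applies $P = e^{tQ}$. `dtmsim` instead simulates *discrete-time*
Markov processes: the parameters are a root distribution $\pi$ over
$\{A,C,G,T\}$ and one arbitrary row-stochastic substitution matrix $P_e$ per
edge $e$, with no exponential structure imposed. Every edge may carry a
different matrix, so the process is nonhomogeneous by construction, and under
the strand symmetric (SSM) and general Markov (GMM) classes the base
composition need not be preserved along the tree (nonstationary data). Such
data are useful for probing how reconstruction and model-selection methods
behave outside the stationary, time-reversible comfort zone.

Branch lengths are interpreted through the log-determinant convention: an edge
of length $l_e$ (expected substitutions per site) requires

$$ l_e = -\tfrac{1}{4}\,\log \det P_e , \qquad\text{i.e.}\qquad
   \det P_e = e^{-4 l_e} \in (0,1). $$

The simulator's central task is therefore: *given a model class and a branch
length, draw a random row-stochastic matrix of that class whose determinant is
exactly $e^{-4l_e}$*.

Five model classes are supported, defined by symbolic patterns over the
alphabet order (A, C, G, T); equal labels mark entries constrained to be
equal:

```{r patterns}
getModel("k81")
```

JC69 has one free parameter per matrix, K80 two, K81 three, SSM six and GMM
twelve (after the row-sum constraint). For K80/K81 the transition cells
(A↔G, C↔T) carry the third parameter; this alphabet convention is the standard
one — nothing else in the machinery depends on it.

## Drawing a matrix with a prescribed determinant

**JC69** has a closed form: with $e = \exp(-4l/3)$, the diagonal is
$(1+3e)/4$ and every off-diagonal entry $(1-e)/4$; the eigenvalues are
$(1, e, e, e)$ so $\det P = e^3 = e^{-4l}$ identically, and the matrix is
always DLC.

**K80/K81** are sampled through their eigenvalue parameterisation. A K81
matrix with first row $(a, b, c, d)$ has eigenvalues $1$, $x = a+b-c-d$,
$y = a-b+c-d$, $z = a-b-c+d$ and $\det P = xyz$. With $D = e^{-4l}$ the
sampler draws $x \sim U(D, 1)$, $y \sim U(D/x, 1)$ and sets $z = D/(xy)$, so
the determinant constraint holds to machine precision by construction. Draws
yielding a negative entry are rejected and redrawn. Because all eigenvalues
are sampled positive, $a$ strictly dominates $b$, $c$ and $d$, so the matrix
is DLC automatically. K80 is the $b = d$ special case with double eigenvalue
$x$ and $y = D/x^2$, $x \sim U(\sqrt D, 1)$. Matrices with negative
eigenvalues (but nonnegative entries) exist in these classes and are not
produced by this sampler; restricting to the positive-eigenvalue region keeps
the DLC conversion trivial and the sampler guaranteed to terminate.

**SSM/GMM** have no usable eigenvalue parameterisation, so the sampler mixes
with the identity. A random matrix $M$ of the model's shape is drawn — GMM
rows independently flat-Dirichlet on the 3-simplex; SSM rows 1 and 2
flat-Dirichlet, rows 3 and 4 their reversals — and rejected if
$\det M \ge D$. Both shape classes are convex and contain the identity, so

$$ P(s) = (1-s)\,I + s\,M, \qquad s \in [0,1] $$

stays in class, and $f(s) = \det P(s)$ moves continuously from $f(0) = 1 > D$
to $f(1) = \det M < D$. $f$ is a quartic in $s$ whose coefficients are the
principal-minor sums of $M - I$, which is how the package evaluates it. $f$
need not be monotone, so the *first* crossing of $D$ is taken — located by
scanning $s = k/1000$ and bisecting inside the first bracketing subinterval.
Taking the first crossing biases toward more diagonally dominant matrices,
which is friendly to the DLC requirement below. The bisection stops when the
branch length $-\tfrac14 \log f(s)$ matches $l$ to $10^{-12}$; working on the
length scale (rather than on $|f - D|$) keeps the length error far below the
$10^{-9}$ contract uniformly in $l$, since a fixed determinant tolerance
inflates into a length error of order $\tfrac14\,\epsilon/D$ as $D \to 0$.

## DLC conversion and identifiability

The parameters of the general Markov model are identifiable from the joint
leaf distribution only up to row permutations. Matrices that are *diagonal
largest in column* (DLC) — each diagonal entry strictly the largest in its
column — resolve the ambiguity: a DLC parameter set generating a given leaf
distribution is unique, so simulated data can safely be used to benchmark
inference. Ties are rejected (strictness is what buys uniqueness).

If a sampled matrix is not DLC, rows may be permuted, but only by
permutations that keep the matrix inside its model class. These are computed
symbolically: a row permutation $\sigma$ is allowable when the relabelled
pattern $P[\sigma,\cdot]$ equals the original pattern up to a bijection of
parameter labels, checked by brute force over all 24 permutations. The
resulting groups are: JC69 $\{\mathrm{id}\}$; K80
$\{\mathrm{id}, (AG)(CT)\}$; K81 the Klein four-group
$\{\mathrm{id},(AC)(GT),(AG)(CT),(AT)(CG)\}$; GMM all of $S_4$. For SSM the
symbolic check returns a group of order eight: besides the Klein four-group,
the single swaps $(A\,T)$ and $(C\,G)$ — and the two 4-cycles they generate —
also preserve the strand-symmetric pattern, because "row 4 is the reversal of
row 1" is itself symmetric under exchanging those rows.

One wrinkle matters when applying these permutations: permuting rows by an
odd permutation multiplies the determinant by $-1$, which would destroy the
branch-length constraint. The DLC conversion therefore uses only the *even*
members of each group. That is no restriction for JC69/K80/K81, whose groups
are entirely even; for SSM the even subgroup is exactly the Klein four-group;
for GMM it is the alternating group $A_{4}$ (12 of the 24).

If no even group member produces a DLC matrix, the candidate is discarded and
a fresh matrix is drawn, within a total budget of 1000 trials per edge
(shared with the entry-sign and determinant rejections above), after which
the simulation aborts and asks for a re-start with a different seed. In
practice the samplers above produce a DLC matrix on the first or second
candidate; the cap exists to make failure loud rather than silent.

## The simulation procedure

1. Parse the Newick tree (`ape` does the parsing; the package validates that
   every edge has a positive, finite length and that leaf names are unique).
   Rooted or unrooted trees with nodes of any degree are accepted; an
   unrooted tree is treated as rooted at the outermost Newick node, the only
   canonical choice, and the root distribution is placed there.
2. Draw one substitution matrix per edge as above, in the canonical output
   order: terminal edges first, in leaf appearance order, then internal edges
   top-down (breadth-first) from the root, siblings in Newick order. This
   order, fixed here because the original convention for parameter output is
   not recoverable from the input, is also the order of the parameter file.
3. Draw a root sequence of $L$ i.i.d. sites from the model's root
   distribution: uniform for JC69/K80/K81 (their matrices are doubly
   stochastic, so uniform is stationary — composition stays uniform along the
   tree); $(p, \tfrac12 - p, \tfrac12 - p, p)$ with $p \sim U(0, \tfrac12)$
   for SSM; flat Dirichlet for GMM. The SSM/GMM draw is random per simulation
   (and recorded), which exercises nonstationarity; a specific distribution
   can be supplied via `rootDist=`.
4. Propagate the sequence down the tree in pre-order (children in Newick
   order), each edge substituting every site independently according to its
   matrix row. There is no rate variation across sites and there are no
   indels — the model family has neither.

RNG consumption order (matrices in canonical order, then the root sequence,
then edges in pre-order) is part of the reproducibility contract: the same
seed gives byte-identical FASTA and parameter files.

## Worked example

The bundled 5-taxon example tree, K81, 10000 sites:

```{r example}
tree <- parseNewick(
  "((species1:0.01,species2:0.2,species3:0.3):0.5,species4:0.4,species5:0.7);")
sim <- simulateAlignment(tree, "k81", L = 10000, seed = 1)
alignment(sim)
```

Every emitted matrix reproduces its edge length through the determinant:

```{r lengths}
vapply(edgeMatrices(simulationRecord(sim)), logdetBranchLength, numeric(1))
```

The same run from the shell (the `inst/scripts/dtmsim` wrapper):

```sh
Rscript inst/scripts/dtmsim tree.txt data.fa 10000 k81 --seed 1
```

writes `data.fa` (FASTA, 60-column) and `data.fa.params.txt`, a plain-text
parameter file re-parseable with `readParams()`: model, seed, tree, root
distribution, then one block per edge in canonical order with the branch
length and the matrix at 17 significant digits (full double precision).

## Validating simulated data

`empiricalJoint()` tabulates the 4×4 joint base counts of a leaf pair, and
`paralinearDistance()` evaluates the log-det (paralinear) distance

$$ d(u,v) = -\tfrac14\Bigl[\log\lvert\det \hat F\rvert
  - \tfrac12 \log\bigl(\textstyle\prod_i f_i \prod_j g_j\bigr)\Bigr], $$

with $\hat F$ the relative-frequency matrix and $f, g$ its marginals. The
absolute value guards against tiny negative determinants from sampling noise
at short alignments. The distance is additive along paths; when all marginals
are uniform (the JC69/K80/K81 stationary case) it equals the sum of the
log-det branch lengths on the path, which is how the test suite closes the
loop from simulated data back to the input tree:

```{r paralinear}
two <- simulateAlignment("(A:0.2,B:0.3);", "k81", L = 500000, seed = 606)
paralinearDistance(empiricalJoint(two, "A", "B"))   # ~ 0.5
```

For SSM/GMM the per-edge determinant contract still holds exactly, but the
paralinear leaf-pair distance is no longer the sum of edge lengths in
general — the marginal terms no longer cancel — so the tests assert only the
per-matrix contract for those models.

## What the test suite does and does not establish

The suite exercises the generator at desk scale: matrices in batches of
200 per model and length over lengths 0.01–1.0 (plus spot checks out to
length 3, where the target determinant is ~$6\times10^{-6}$), alignments of
$10^4$–$5\times10^5$ sites on 2- and 5-taxon trees. Stochastic checks
(compositions, conditional frequencies, chi-square goodness of fit on site
patterns, paralinear recovery) run under fixed seeds at 3 binomial or
delta-method standard errors. Those sizes make every stochastic bound tight
enough to catch systematic errors while keeping the full suite under a
minute; execution time grows linearly in taxa and sites, so larger problems
are a matter of patience, not of different code paths.

Synthetic data of this kind emulates the model family exactly — that is the
point of the tool — but real alignments contain features the family excludes:
indels and alignment error, rate variation across sites, context dependence,
selection. Passing tests show the simulator honours its mathematical
contract, not that the models capture any particular biological dataset.

Known limitations, deliberate:

* The GMM sampler covers the matrices reachable as identity mixtures of
  Dirichlet-row matrices after even-permutation DLC conversion — a dense,
  convenient family, with no claim of covering *every* DLC stochastic matrix
  of a given determinant, and no claim about the induced sampling law beyond
  the determinant constraint itself.
* K80/K81 matrices with negative eigenvalues are not produced.
* Zero-length branches are rejected by default: $\det P = 1$ forces the
  identity for a DLC stochastic matrix, and a silent identity edge usually
  indicates an input mistake. `--allow-zero-length` (or
  `allowZeroLength = TRUE`) opts into the identity-matrix behaviour.
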