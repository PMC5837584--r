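---
title: "Probabilistic distances between phylogenetic trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic distances between phylogenetic trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probdist)
```

## The model

Most tree metrics compare topologies and edge lengths directly. This
package instead compares trees *as probability models of sequence data*.
A rooted tree $T$ with edge lengths in expected substitutions per site,
together with a reversible Markov substitution model $\theta$, induces a
distribution $p$ on characters: assignments of one state from the
alphabet $\Omega$ ($\{0,1\}$ or $\{A,C,G,T\}$) to each of the $n$
leaves. The package computes distances between two such distributions
$p$ and $q$:

* squared Hellinger
  $d_H^2(p;q) = \tfrac12 \sum_{s\in\Omega^n} (\sqrt{p(s)} -
  \sqrt{q(s)})^2$, a metric bounded by 1;
* Kullback–Leibler $d_{KL}(p;q) = \sum_s p(s)\log(p(s)/q(s))$,
  non-negative but asymmetric;
* Jensen–Shannon
  $d_{JS}^2 = \tfrac12 d_{KL}(p;\tfrac{p+q}{2}) +
  \tfrac12 d_{KL}(q;\tfrac{p+q}{2})$, a metric bounded by
  $\sqrt{\log 2}$;
* total variation $d_{TV} = \sum_s |p(s) - q(s)| \in [0,2]$.

Because the map from (tree, model) to the induced distribution is
injective for these model families, these are genuine metrics on pairs
$(T, \theta)$, and a distance of zero means the two pairs are
statistically indistinguishable no matter how much sequence data one
collects. Two consequences distinguish them from edge-length metrics:
scaling all edges by a large factor saturates the substitution process,
so both trees converge to the same product-of-stationary distribution
and the distance falls to zero; and long pendant edges contribute less
and less information, so long-branch (Felsenstein/Farris zone) pairs
converge to a positive constant rather than diverging.

Character probabilities are computed by Felsenstein's pruning algorithm:
a postorder dynamic program passing partial likelihood vectors toward
the root, summing over root states weighted by the stationary
distribution, and averaging over the across-site rate mixture.

## Substitution models

Two model families ship with the package (the pruning and simulation
code is written for an arbitrary finite alphabet):

* `cfn_model()`: the symmetric two-state process, rate matrix
  $\begin{pmatrix}-1&1\\1&-1\end{pmatrix}$, uniform stationary
  distribution, no free parameters;
* `gtr_model()`: the general time-reversible DNA model,
  $q_{ij} = s_{ij}\pi_j$, with optional discrete-Gamma across-site rate
  heterogeneity and an invariant-site class.

Every model is normalised so that one unit of edge length is one
expected substitution per site at mixture mean rate 1, which makes edge
lengths comparable across models. Transition matrices come from the
symmetric similarity transform
$B = \mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$,
eigendecomposed once per model; per-edge assembly is then a cheap
$O(|\Omega|^3)$ product, and the decomposition guarantees numerically
symmetric detailed balance.

Tunable model parameters:

| parameter | meaning | default | why |
|---|---|---|---|
| `gamma_shape` | Gamma shape of the rate mixture | `NULL` (homogeneous) | heterogeneity is opt-in |
| `n_categories` | discrete Gamma classes | 4 | the field's convention; more classes change likelihoods only in the 3rd decimal |
| `p_invariant` | weight of the rate-0 class | 0 | "+I" used only when data demand it |

The category representative is the *bin mean* (computed in closed form
from the incomplete Gamma function), not the bin median; the choice
matters at the third decimal of likelihoods, so it is fixed and
documented. The invariant class folds into the mixture as a rate-0
class of weight $p_{inv}$, with the Gamma rates rescaled by
$1/(1-p_{inv})$ so the full mixture keeps mean rate exactly 1.

## Monte Carlo estimation

Exact computation enumerates $|\Omega|^n$ characters and is capped (by
default at 65,536 outcomes: 16 binary or 8 DNA taxa). Beyond the cap
the distances are estimated from $m$ characters simulated from each
distribution:

$$\hat d_H^2 = R_m = 1 - \frac{1}{2m}\sum_{i=1}^m\left(
\sqrt{\frac{q(s_{p,i})}{p(s_{p,i})}} +
\sqrt{\frac{p(s_{q,i})}{q(s_{q,i})}}\right),$$

which is unbiased for $d_H^2$; Kullback–Leibler is the mean of
$\log(p/q)$ over draws from $p$; each Jensen–Shannon term is estimated
from its own sample with the mixture probability obtained by
log-sum-exp; total variation uses the unbiased identity
$E_p|1 - q/p| = \sum_s|p-q|$, averaged symmetrically over both samples.
All ratios are exponentials of log-probability differences — never
quotients of probabilities — and pruning works in log space with
per-node rescaling, so 100-taxon trees evaluate without underflow.

Numerical conventions worth knowing:

* the raw estimate ($R_m$, the Jensen–Shannon square, the KL mean) can
  be negative by chance; the record keeps the raw value (so
  unbiasedness remains testable) while the reported metric is
  $\sqrt{\max(\cdot,0)}$ or $\max(\cdot,0)$;
* standard errors are plug-in sample variances of the per-draw terms,
  combined across the two independent samples;
* exact Hellinger uses the definitional half-sum-of-squares form rather
  than $1-\sum\sqrt{pq}$: identical distributions then give exactly
  zero instead of square-root-amplified cancellation noise;
* each estimator derives independent sub-stream seeds for its two
  samples from the user seed, so runs are reproducible and
  argument-order experiments are meaningful;
* a Kullback–Leibler or total-variation draw that lands on a
  zero-probability character under the opposite model (possible only
  with zero-length edges) is an error naming the character, not a
  silent infinity.

The optional control variate for the Hellinger estimator uses, under
the $p$-sample, the ratio $q/p$ whose expectation is exactly 1 (and
symmetrically $p/q$), with the regression coefficient estimated from
the sample. This is the textbook regression-adjusted construction,
chosen on its own merits; the package validates it by its
variance-reduction property (roughly a 2–3x smaller standard error on
the shipped test pairs), not against any external reference.

## Choosing the sample size

A pilot run of $m_0$ paired draws (default 1,000) produces per-draw
estimates $R_1$, whose mean $\hat\mu_0$ and variance $\hat\sigma_0^2$
are unbiased for $d_H^2$ and $\mathrm{Var}(R_1)$. To achieve absolute
error $\tau$ on $R_m$ with probability $1-\beta$, the normal
approximation gives

$$m \ge \frac{z_{\beta/2}^2\,\sigma_0^2}
{\tau^2\,(2\sqrt{\mu_0}-\tau)^2},$$

implemented as `required_m()` (ceiling, minimum 1). A relative error
target $\alpha$ translates to $\tau = \alpha\sqrt{\mu_0}$.
`auto_distance()` chains pilot, plan, and a fresh estimation run. Two
edge cases are handled explicitly: a pilot mean that is zero to
numerical precision means the trees are indistinguishable at pilot
precision, and the function returns zero with a warning rather than
dividing by zero; and $\tau \ge 2\sqrt{\mu_0}$ makes the bound's
denominator non-positive, which is an error (the tolerance is
unachievable in this approximation).

One subtlety matters when interpreting coverage: the plan controls the
absolute error $\alpha\sqrt{\mu_0} = \alpha\, d_H$ of the *squared*
estimate, which by the delta method is $\le\alpha$ *relative* error of
the distance itself exactly when $d_H \ge 1/2$. The package's coverage
experiment therefore uses a tree pair whose exact Hellinger distance
exceeds 0.5 (two 8-taxon Yule trees under the default edge-length
regime), where the nominal 80% guarantee applies to the distance scale;
for closer pairs the same plan still controls $\alpha\, d_H$ absolute
error but the distance-scale relative guarantee weakens by the factor
$1/(2 d_H)$.

For Kullback–Leibler and total variation (plain means, no square-root
transform) the same pilot machinery applies with the bound
$m \ge z^2\sigma_0^2/\tau^2$ and relative target $\tau = \alpha\mu_0$;
this is the package's extension of the Hellinger derivation and is
validated against enumeration in the tests.

## Trees with different taxon sets

Two methods compare pairs with taxon sets $A \ne B$ (they must
overlap):

* **common**: both trees are cropped to $A\cap B$ (suppressed degree-2
  nodes have their edge lengths summed, so paths among kept taxa are
  preserved) and the ordinary distance is computed. Model parameters
  are carried over unchanged — nothing is re-estimated after cropping.
* **augment**: both distributions are extended to $A\cup B$ by
  declaring the missing taxa's states uniform and independent:
  $p_{A\cup B}(s) = p(s_A)\,/\,|\Omega|^{|B\setminus A|}$. The uniform
  factor encodes maximal uncertainty about where the missing taxa
  would attach, and — unlike cropping — it *penalises* missingness:
  dimensions where one tree has structure and the other only noise push
  the distributions apart.

With $A = B$ the augmentation is algebraically the identity, and the
implementation reproduces the plain estimator stream exactly under the
same seed. The deletion experiment (`experiment_deletion()`) deletes
the same *number* of taxa from each tree but chooses the taxa
independently; deleting the same taxa from both trees would reduce to
the common-taxa comparison and lose the missingness penalty.

A finding from the package's own experiments: the mean augmented
Hellinger distance rises with the number of deleted taxa only up to a
point (roughly 30% of a 20-taxon tree, with two same-topology trees
differing in edge lengths). Past it, both augmented distributions are
dominated by their mismatched uniform dimensions and drift toward each
other, so the curve peaks and declines. At small deletion fractions —
the regime of the large-tree experiments this emulates — the trend is
cleanly monotone (e.g. 30 taxa with 2/6/10 deletions). The bundled
20-taxon test grid deliberately crosses the peak, and its
highest-deletion comparison documents the non-monotone tail.

## Synthetic data

All experiments run on synthetic trees; the generators are first-class,
tested code:

* `yule_topology()`: Yule (pure-birth) topologies realised by
  successive uniform joins of lineages — the join order induces the
  Yule topology distribution, verified by a goodness-of-fit test on the
  three labelled 3-leaf topologies;
* `sample_edge_lengths()`: i.i.d. Gamma edge lengths, default mean 0.1
  and variance 0.005 expected substitutions per site (shape 2, scale
  0.05) — a moderately informative regime where characters are neither
  constant nor saturated;
* `random_spr()`: subtree prune-and-regraft moves. No standard
  edge-length bookkeeping exists, so the package fixes one: the
  suppressed node's two edges are summed, the regraft point bisects the
  target edge, and the pruned subtree keeps its pendant length; when
  the pruned subtree's parent is the root, the sibling becomes the new
  root and its pendant length is dropped;
* `felsenstein_farris_pair()`: the classical 4-taxon long-branch
  configurations, two long pendant edges either non-sister
  (Felsenstein zone) or sister (Farris zone), all other edges at a
  configurable `short_len` (default 0.1).

Trees are kept rooted throughout; under the reversible stationary
models used, the induced character distribution is root-invariant (the
pulley principle), which the tests verify by re-rooting rather than
assume. Generated trees are binary, but the Newick reader accepts
polytomies and the pruning code handles them.

What the generators do **not** emulate: alignment and sequencing error,
model misspecification (data are always simulated under the scoring
model), non-tree-like processes, and the posterior or bootstrap tree
samples of real analyses. Passing tests therefore demonstrate
correctness of the estimators and the qualitative phenomena
(saturation, long-branch behaviour, missingness penalty, cluster
separation under multidimensional scaling) on clean synthetic input,
not robustness on real alignments.

## Distance matrices and embedding

`distance_matrix()` computes each unordered pair once — in canonical
sorted-label orientation, with a per-pair seed hashed from the master
seed and the pair's labels — and mirrors the value, so matrices are
exactly symmetric, zero-diagonal, order-independent and reproducible.
`classical_mds()` is Torgerson scaling (double-centred squared
distances, spectral embedding) via `stats::cmdscale`; Euclidean input
is reproduced exactly, and requesting more dimensions than there are
positive eigenvalues returns fewer columns with a warning. On exact
distance matrices of two clusters of trees built around two distinct
8-taxon topologies, a single-linkage cut of the 2-D embedding recovers
the clusters; which multidimensional-scaling flavour real analyses
should use is a modelling choice, and classical scaling is the one
implemented.

## Problem sizes and runtime choices

The shipped test and acceptance runs use: 4–8-taxon trees wherever an
enumeration oracle is needed (binary enumeration is capped at 16 taxa);
$m = 5000$ for estimator-vs-oracle checks; 200 replicates for the
unbiasedness and coverage experiments; 16-taxon pairs for the
edge-scaling curve; and 20-taxon trees with 50 replicate deletions for
the missing-taxa experiment. These sizes make every property
statistically decidable (3-SE margins, chi-square at $p > 0.001$)
while a full run completes in well under a minute on one core; all of
them scale up by changing arguments, not code.

## Known limitations

* Only binary and DNA alphabets ship, though nothing hard-codes
  $|\Omega|$; amino-acid or codon models would need their own
  constructors.
* The Kullback–Leibler estimator evaluates the displayed form
  $\frac1m\sum\log(p/q)$ at draws from $p$ only; no reverse-sample
  averaging is attempted.
* Sample-size planning for Kullback–Leibler and total variation uses
  the plain-mean bound, an extension beyond the squared-Hellinger
  derivation.
* The augmentation method's uniform extension is one modelling choice
  for missing taxa; it is not an inference of where the taxa belong.
* Monte Carlo distances of *near-identical* trees need very large $m$
  for a useful relative error; the pilot's zero short-circuit reports
  indistinguishability rather than pretending precision.
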