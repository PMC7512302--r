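---
title: "Stochastic complexity of spin models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic complexity of spin models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinsc)
```

## The model family

A spin model on $n$ binary variables $s_i = \pm 1$ is defined by a set $M$
of product operators $\phi_\mu(s) = \prod_{i \in \mu} s_i$, one per
interaction, with conjugate couplings $g_\mu$:

$$P(s \mid g, M) = \frac{1}{Z_M(g)} \exp\Big(\sum_{\mu \in M} g_\mu
\phi_\mu(s)\Big).$$

This is the maximum-entropy family matching the empirical averages of the
chosen operators; those averages are the sufficient statistics. `spinsc`
encodes each operator as an $n$-bit mask (bit $i-1$ set iff spin $i$
participates; spin indices are 1-based in every user-facing format), so the
algebra of operators is GF(2) linear algebra on masks. The identity
operator (empty mask) is excluded: it carries no interaction.

## Complexity, Jeffreys volume, and MDL

Asymptotically in the sample size $N$, the description length of a dataset
under model $M$ is the maximized log-likelihood minus
$\frac{|M|}{2}\log\frac{N}{2\pi} + c_M$, where

$$c_M = \log \int dg \, \sqrt{\det J(g)}, \qquad
J_{\mu\nu}(g) = \partial^2 \log Z_M / \partial g_\mu \partial g_\nu .$$

$c_M$ is the log volume of the model under Jeffreys' prior. `mdl_score()`
reports all three terms and their difference (`total`); `select_model()`
ranks candidates by `total`, breaking ties by smaller $|M|$ and then by the
lexicographic model specification. The score identity
`total = max_loglik - bic_term - complexity_term` holds exactly by
construction. The MDL expansion is asymptotic in $N$; no finite-$N$
correction is applied, and small-$N$ scores should be read accordingly.

## Gauge transformations and complexity classes

An invertible $n \times n$ binary matrix $A$ acts on operator masks (as
column vectors) by $m \mapsto A m \bmod 2$. This is a bijection of the
$2^n - 1$ operators onto themselves and leaves the likelihood geometry — and
hence $c_M$ — invariant, so its orbits partition model space into
complexity classes. Conventions fixed here:

* **Column action.** Masks are column vectors, maps act by left
  multiplication. The transpose convention yields the same orbits; one
  choice had to be fixed and documented.
* **Sign flips are not gauge maps.** $s_i \to -s_i$ changes couplings, not
  operators; the group counted by `count_gauge_maps()`
  ($N_{GT}(n) = 2^{n^2}\prod_{k=1}^n (1 - 2^{-k})$) contains exactly the
  invertible basis changes, and `enumerate_gauge_maps()` reproduces that
  count by exhaustion (1, 6, 168 for $n = 1, 2, 3$). The count is returned
  as a double and is exact up to $n = 7$, past which it exceeds the
  integers a double can represent.
* **Orbits by closure, not by exhaustion.** `orbit()` and
  `classify_models()` take the breadth-first closure under the elementary
  transvections $I + E_{ij}$, which generate the full group; this costs
  $O(\text{orbit} \times n^2)$ instead of $O(|GT|)$ and is what makes the
  $n = 4$ classification (32768 models, 46 classes) take seconds.
  Exhaustive enumeration of gauge maps is therefore capped at $n = 4$ by
  default ($2^{25}$ candidate matrices at $n = 5$ serve no purpose here).
* **Canonical representative.** A class is named by its lexicographically
  minimal member (sorted mask tuples compared elementwise). The empty model
  is a valid model and its own class. Classes could be refined further by
  the spin-permutation subgroup (the four reference models of
  `reference_class_model()` are such sub-representatives with
  multiplicities summing to 15); the package reports full gauge classes and
  leaves permutation quotients to the caller.

## Loop structure

A loop is a subset of $M$ whose masks XOR to zero, i.e. whose operator
product is identically one. Loops form an Abelian group under symmetric
difference, of size $2^\lambda$ with $\lambda = |M| - n_M$, where $n_M$ is
the GF(2) rank of the mask matrix. `loop_basis()` computes a generating set
as the null space of that matrix by Gaussian elimination, with pivots taken
in stored operator order: the generating set is not unique, and fixing the
pivot order makes the output deterministic. Each generator is a fundamental
circuit — one dependent operator plus the independent operators expressing
it — a property the closed-form dispatcher relies on (below).

The loop expansion
$Z_M(g) = 2^n \prod_\mu \cosh g_\mu \sum_{\ell \in L} \prod_{\mu \in \ell}
\tanh g_\mu$ is implemented by enumerating all $2^\lambda$ combinations of
the generators (capped at $\lambda = 20$) and is tested against brute-force
state enumeration to $10^{-10}$ relative error. Brute-force quantities
($\log Z$, Fisher matrices, exact sampling, likelihoods) all work in the
log domain (log-sum-exp), keeping couplings up to $|g| \approx 30$ finite;
state enumeration is capped at $n = 20$ for $Z$ and $n = 12$ wherever a
$2^n \times |M|$ operator matrix is materialized.

## Closed-form complexities

Three exact results are implemented:

* loopless models: $c_M = |M| \log\pi$;
* the complete model on $n$ spins (all $2^n - 1$ operators):
  $c_M = 2^{n-1}\log\pi - \log\Gamma(2^{n-1})$, via the bijection between
  its couplings and the $2^n$ state probabilities, which turns the Jeffreys
  volume into a Dirichlet integral;
* models that factorize into independent blocks: free operators contribute
  $\log\pi$ each, and every sub-complete block (a set of operators equal to
  all non-zero vectors of the $k$-dimensional span of its masks — the
  gauge-invariant signature of "complete model on $k$ spins") contributes
  the complete-model value at $k$. A 3-loop is the $k = 2$ case,
  contributing $2\log\pi$, which recovers the single-3-loop formula
  $(|M|-1)\log\pi$.

`complexity_closed()` decides applicability by decomposing the model into
matroid components: union-find over the fundamental circuits returned by
the loop basis. This decomposition is basis-independent precisely because
the generators are fundamental circuits with respect to one independent
set. If any component is not sub-complete (e.g. a single loop of length
$\ge 4$, or overlapping loops as in the fully connected pairwise model),
no closed form is claimed and the function returns `NULL` rather than an
approximation.

## Monte Carlo integration

For everything else, `complexity_mc()` estimates $\log \int dg \sqrt{\det
J(g)}$ under the change of variables $g_\mu = \operatorname{atanh}(\sin
\theta_\mu)$, $\theta_\mu$ uniform on $(-\pi/2, \pi/2)$:

* the integrand of a loopless model becomes identically 1
  ($\operatorname{sech}(\operatorname{atanh}(\sin\theta)) = \cos\theta$
  cancels the Jacobian), so the estimator is exact there and low-variance
  for weakly looped models;
* the integrand stays bounded everywhere. A plain $g = \operatorname{atanh} t$
  substitution was rejected: its tails give the estimator infinite
  variance.

Per sample, the exact Fisher matrix is assembled from the full
$2^n \times |M|$ operator table and its determinant taken by symmetric
eigendecomposition (compiled, RcppArmadillo). Eigenvalues in
$[-10^{-10}, 0]$ are clipped to zero — $\sqrt{\det}$ of a singular $J$
contributes zero volume, which is correct — and anything more negative is a
hard error, as is any non-finite integrand value.

The estimate is organized as `n_reps` independent repetitions of
`n_samples` draws; the value is the mean of per-repetition log estimates
and the standard error their standard deviation over $\sqrt{n_{reps}}$.
Repetition $r$ uses seed `seed + r - 1`, so enlarging `n_reps` extends
rather than reshuffles a run. The default budget is $10^5$ samples
$\times$ 100 repetitions; package checks that compare Monte Carlo values to
closed forms or to each other use within-3-standard-error agreement, which
is what makes reduced budgets (down to $2\times10^4 \times 30$ in the class
scan over the six $|M| = 7$ classes at $n = 4$) legitimate. All values are
in nats; `in_bits()` (and the CLI `--bits` flag) divides by $\log 2$.

## Fitting

* `fit_ml()` maximizes the exact concave log-likelihood by damped Newton
  ascent with the exact Fisher matrix as Hessian (ridge $10^{-10}$,
  backtracking line search), declaring convergence when model and empirical
  operator means agree to $10^{-8}$ in the maximum norm, and failing
  explicitly after 500 iterations. Boundary sufficient statistics
  ($|\bar\phi_\mu| = 1$, where the MLE diverges) are an explicit error
  naming the operator. For loopless models the result coincides with the
  factorized solution $\hat g_\mu = \operatorname{atanh} \bar\phi_\mu$.
* `fit_complete()` uses the complete-model closed form
  $\hat g_\mu = 2^{-n} \sum_s \phi_\mu(s) \log \hat p(s)$. Unobserved
  states make the closed form undefined, so $\hat p$ is smoothed with an
  additive per-state pseudocount, default 0.5 (Jeffreys-style); the choice
  is surfaced as an attribute of the result, and `pseudocount = 0` is
  honored when every state was observed (erroring otherwise rather than
  guessing).

## The synthetic-data generator

`make_fixture()` instantiates the named families the analysis is built
around — loopless models, single loops, sub-complete blocks, the fully
connected pairwise model, and the four reference models of the 4-spin
class with invariants $(|M|, n_M, \lambda) = (7, 3, 4)$ — draws couplings,
and samples exactly from the resulting distribution (categorical sampling
over the $2^n$ enumerated probabilities; no MCMC). Defaults: couplings of
magnitude 0.5 with random signs — moderate interactions, strong enough to
be detected at $N \sim 10^3$–$10^4$ yet far from the frozen regime where
sufficient statistics hit the boundary — and $N = 1000$ samples. Selection
checks use $N = 10^4$, where the BIC gap between a true three-operator
model and a one-operator extension makes the true model win in well over
90% of seeds.

What the generator emulates is exactly the model family itself, so passing
tests show internal consistency (sampling, fitting, scoring and complexity
agree with each other and with closed forms). What it does not emulate is
real data: samples are i.i.d. from an exponential-family distribution with
no mis-specification, no temporal correlation, and no degenerate
(constrained) couplings. Results on data violating those assumptions —
notably non-stationary or dependent samples, where effective $N$ is smaller
than nominal — are not certified by this test suite.

## Numerical choices and degenerate inputs

* All expectations are exact $2^n$ enumerations; caps at $n = 20$ ($Z$) and
  $n = 12$ (Fisher, sampling, fitting) keep memory and time bounded.
* The empty model is handled throughout: zero parameters, $c_M = 0$,
  likelihood $-Nn\log 2$.
* Monte Carlo with a single repetition reports `std_error = 0`; treat such
  an estimate as having unknown error.
* Problem sizes in the shipped tests: classification and orbit checks at
  $n \le 4$; loop-expansion identity on 200 random models with $n \le 4$;
  Monte Carlo versus closed forms at $10^5 \times 100$; the $|M| = 7$
  class scan at $2\times10^4 \times 30$ per class; selection consistency
  over 50 seeds at $N = 10^4$, $n = 3$.

## Limitations

* No analytic $c_M$ for general overlapping-loop models (none is known);
  Monte Carlo is the fallback, with cost growing as $2^n |M|^2$ per sample.
* Degenerate models (linearly constrained couplings) and mixture models
  are out of scope, as are Potts generalizations and real-valued variables.
* Classification is exhaustive only to $n = 4$; beyond that, orbits of
  individual models are still available via `orbit()` up to $n = 6$.
* Model search is not provided: scoring is over an explicit candidate
  list, since exhaustive search over all $2^{2^n - 1}$ models is infeasible
  even for moderate $n$.
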