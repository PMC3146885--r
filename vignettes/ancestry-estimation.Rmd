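---
title: "Model-based ancestry estimation with admixkit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based ancestry estimation with admixkit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

admixkit estimates individual ancestry from diploid biallelic SNP genotypes
under the admixture model. The genotype $n_{ij} \in \{0, 1, 2\}$ counts the
"type 1" allele carried by individual $i$ at marker $j$ and is modeled as

$$n_{ij} \sim \mathrm{Binomial}(2,\; p_{ij}), \qquad
  p_{ij} = \sum_{k=1}^{K} q_{ik} f_{kj},$$

where $q_{ik}$ is the fraction of individual $i$'s genome attributed to
ancestral population $k$ (rows of $Q$ lie on the probability simplex) and
$f_{kj}$ is the frequency of the counted allele in population $k$. The
log-likelihood

$$L(Q, F) = \sum_{i,j\ \mathrm{observed}}
  \bigl[\, n_{ij} \ln p_{ij} + (2 - n_{ij}) \ln (1 - p_{ij}) \,\bigr]$$

is *biconcave*: concave in $Q$ for fixed $F$ and concave in $F$ for fixed
$Q$, but not jointly concave. Missing entries are simply omitted from the
sum, which is also how cross-validation masks cells.

Two modeling assumptions matter in practice. Markers are treated as
independent given $(Q, F)$ — linkage disequilibrium is ignored, as is
standard for this model family, so dense marker panels should be LD-pruned
first. And the two alleles within an individual are drawn independently given
the ancestry proportions (no inbreeding term).

## Optimization

`admix_fit()` maximizes $L$ (or the penalized objective below) by **block
relaxation**: alternating updates of $Q$ with $F$ fixed and of $F$ with $Q$
fixed. Each block problem separates — over individuals for $Q$, over markers
for $F$ — into concave subproblems of dimension $K$, which are solved by
sequential quadratic programming: a small dense QP maximizes the second-order
Taylor expansion of the block objective subject to the original constraints
(the probability simplex for ancestry rows; the box
$[\varepsilon_f, 1-\varepsilon_f]$ for frequency columns), via a primal
active-set method. Because the quadratic model can overshoot, each accepted
step is safeguarded: if the full QP step decreases the true block objective,
the step is halved toward the current point (at most 10 times) before being
abandoned as a no-op. Every accepted step therefore increases the objective,
and the reported per-iteration trajectory is non-decreasing by construction —
a property the test suite asserts on every fit.

Convergence is declared when the objective increase between consecutive
(accelerated) sweeps falls below `tol` ($10^{-4}$ by default, an absolute
threshold on the log-likelihood scale, matching the magnitude this tool
family conventionally uses). At convergence the projected gradient on every
free ancestry row and frequency column is small; the tests check a
Karush-Kuhn-Tucker residual of at most $10^{-4}$ on instances run to a tight
tolerance.

### Quasi-Newton extrapolation

Plain block relaxation converges linearly and can crawl when populations are
weakly differentiated. `admix_fit()` accelerates it by secant extrapolation
of the block-update map $M$: with $U$ the last $q$ differences of iterates
and $V$ the matching differences of their images under $M$
(`qn_secants = 3` by default),

$$x_{\mathrm{acc}} = M(x) + V\,(U^\top U - U^\top V)^{-1} U^\top (M(x) - x).$$

The extrapolated point is projected back to the feasible set (clamp and
renormalize ancestry rows, clamp frequencies, restore fixed rows exactly) and
is **accepted only if its objective exceeds the plain step's**; otherwise the
plain step is kept, and a singular secant system simply skips acceleration
for that sweep. The safeguard makes the extrapolation's exact flavor
immaterial to correctness: monotone ascent holds either way, acceleration
only changes how fast the same fixed points are reached.

### Parallel execution contract

The per-row and per-column subproblems are independent. The `workers`
argument runs them on that many threads with disjoint writes and all
reductions performed serially in index order, so the result is **identical
for any worker count** — the tests compare `workers = 1` against
`workers = 4` for bit-equality.

### Initialization and determinism

Ancestry rows are drawn from a flat Dirichlet; frequencies start at each
marker's overall empirical frequency plus uniform $\pm 0.1$ noise (so
populations do not start identical), clamped into the frequency box. All
randomness — initialization, fold assignment, simulation — flows from
explicit integer seeds, and derived seeds (per cross-validation fold, per
simulated genotype draw) are produced by a deterministic integer hash, so
every fit, CV table, and simulated dataset is exactly reproducible.

## Numerical choices

* Frequencies are confined to $[\varepsilon_f, 1-\varepsilon_f]$ with
  $\varepsilon_f = 10^{-6}$, and every $p_{ij}$ is clamped to
  $[10^{-10}, 1-10^{-10}]$ before logs: the likelihood is undefined at
  $p \in \{0, 1\}$, and the clamp preserves optimizer progress without
  moving interior optima. Ancestry coefficients may be exactly 0.
* The QP's curvature matrix gets a ridge of $10^{-9}(1 + \max_k |H_{kk}|)$ so
  the active-set solve is strictly convex even on degenerate data.
* Ancestry coefficients the QP leaves below $10^{-10}$ are snapped to exact
  zero and the row renormalized — this is what realizes the penalty's
  "drives small coefficients to zero" in finite arithmetic — but the snapped
  candidate still passes through the same ascent safeguard.
* Grid selection ties (equal CV error) break toward the smaller $K$ or
  $\lambda$: parsimony.
* Masked-entry dosage predictions at a clamp boundary are nudged inside
  $(0, 2)$ so squared deviance residuals stay finite.

## Cross-validation

`make_folds()` partitions the observed genotype **cells** — not individuals,
not markers — into $v$ folds of sizes differing by at most one ($v = 5$ by
default). For each fold, `cv_error()` masks the fold's cells, refits the
model, predicts each masked genotype by its fitted dosage
$\hat\mu_{ij} = 2 \sum_k \hat q_{ik} \hat f_{kj}$, and scores it with the
squared binomial deviance residual

$$d^2(n, \mu) = 2\left[\, n \ln\frac{n}{\mu}
  + (2-n) \ln\frac{2-n}{2-\mu} \,\right], \qquad 0 \ln 0 \equiv 0,$$

averaging over all masked cells across folds. Minimizing this estimate over a
grid selects $K$ (`select_K()`) or the penalty strength
(`select_lambda()`).

Fold assignment is unstratified uniform; nothing balances folds within an
individual or marker, which is the literal reading of partitioning the
non-missing genotypes and is flagged here as a design choice. Each fold's fit
is re-initialized from a seed derived from the master seed and the fold's
*content* (a hash of its masked cell set) rather than its label — a
deliberate choice so that relabeling folds provably cannot change the CV
error, while reproducibility and per-fold seed independence are retained.

## Supervised analysis

When reference individuals of known ancestry are available
(`population_labels`, read from an `.ind` file with `"-"` marking unlabeled
individuals), `supervised_fit()` fixes each labeled individual's ancestry row
to its population's unit vector — bit-exactly, in the output too — and
estimates only the unlabeled rows and all frequencies. This removes the
reference rows' parameters from the problem, so fits are faster and the
frequency estimates sharper; the acceptance suite quantifies both effects on
simulated data. In combined supervised + penalized runs the fixed rows are
excluded from the penalty: their coefficients are constants, and penalizing
them would only shift the objective trace. Supervised mode is appropriate
only when reference individuals can be assigned with certainty to reasonably
homogeneous ancestral populations; no automated check of that assumption is
attempted.

## Penalized estimation

To counter the inflation of admixture estimates on small or weakly
differentiated datasets, `admix_fit(lambda = ...)` maximizes
$L(Q, F) - \mathrm{pen}(Q)$ with the approximate-$\ell_0$ penalty

$$\mathrm{pen}(Q) = \lambda \sum_{i,k}
  \frac{\ln(1 + q_{ik}/\gamma)}{\ln(1 + 1/\gamma)}.$$

The normalization makes a unit coefficient cost exactly $\lambda$; as
$\gamma \to 0$ the penalty counts nonzero coefficients, which is the sense in
which it approximates $\ell_0$ and encourages aggressive parsimony rather
than mere shrinkage. It is bounded on the simplex — unlike the Dirichlet
log-prior with concentration below 1, which is unbounded above and therefore
unusable in a maximization framework. The penalty applies to $Q$ only; the
$F$ update is identical in plain and penalized mode.

Because the penalty is concave in $q$, the penalized row objective may be
multimodal. The row QP therefore uses a **local linear approximation** of the
penalty (its gradient at the current point) added to the likelihood's
quadratic model. Linearizing a concave function majorizes it, so this is a
true minorize-maximize step for the penalized objective, and the acceptance
safeguard — checked against the *exact* penalized row objective — preserves
monotone ascent. Defaults: $\lambda = 0$ (off) and $\gamma = 0.1$ when
penalized mode is enabled without an explicit scale. $\lambda$ is best chosen
by `select_lambda()` on a grid; the package's benchmark uses
$\{0, 1, 2, 5, 10, 20, 50, 100\}$, a roughly logarithmic spacing of the
interval 0–100.

Two cautions on interpreting that grid search. First, the penalty is
normalized by $\ln(1 + 1/\gamma)$; an unnormalized convention rescales
$\lambda$ by that factor (about 2.4 at $\gamma = 0.1$), so $\lambda$ values
are not transferable across conventions. Second, held-out deviance
discriminates between $\lambda$ values only as far as the unpenalized fit
actually overfits: on the benchmark design the CV curve is typically flat to
within a few $10^{-4}$ for small-to-moderate $\lambda$ and rises sharply once
the penalty forces genuinely admixed individuals toward the simplex vertices,
and with ties broken toward parsimony the selection can land at the low end
of the flat region. Moderate penalties can nonetheless reduce both the
ancestry bias and the frequency error relative to $\lambda = 0$ — the
acceptance suite measures exactly this comparison on the benchmark
replicates.

## The simulator and what it does (not) emulate

`simulate_dataset()` reproduces the structure of the package's evaluation
benchmark: ancestral allele frequencies $p_j \sim \mathrm{Uniform}(0,1)$;
per-population frequencies from the Balding-Nichols model,
$f_{kj} \sim \mathrm{Beta}\bigl(p_j \tfrac{1-F_{ST}}{F_{ST}},
(1-p_j)\tfrac{1-F_{ST}}{F_{ST}}\bigr)$, so that $E[f_{kj}] = p_j$ and
$\mathrm{Var}[f_{kj}] = F_{ST}\, p_j (1 - p_j)$; a cohort of unadmixed
reference individuals per population plus admixed individuals whose
population-1 fraction runs over the **open** grid $i/(n_{\mathrm{adm}}+1)$ —
endpoints excluded, since fully unadmixed individuals are already present as
references; and genotypes drawn $\mathrm{Binomial}(2, QF)$ with no
missingness. The default design is two populations, $J = 10{,}000$ markers,
$F_{ST} = 0.01$ (the differentiation typical of closely related populations
within a continent), 100 references per population, 200 grid-admixed
individuals.

What the simulator does **not** emulate: linkage disequilibrium between
markers, genotyping error, missing data patterns, inbreeding, more than two
populations in the admixture grid, or ascertainment bias in marker choice.
Tests passing on these simulations therefore demonstrate correct model
fitting and calibrated behavior *under the model's own assumptions*; they do
not certify performance on real panels, where LD pruning and data cleaning
remain the user's responsibility.

Before any error statistic is computed, estimated populations are aligned to
true ones by the permutation minimizing total frequency RMSE
(`match_populations()`; the likelihood is invariant to label switching, so
some alignment rule is required — this one is deterministic and, for
$K = 2$, a binary choice). `estimate_fst()` is a Wright-style
ratio-of-averages estimator,
$\hat F_{ST} = \sum_j (f_{1j}-f_{2j})^2/2 \,\big/\, \sum_j \bar p_j(1-\bar
p_j)$ with $\bar p_j = (f_{1j}+f_{2j})/2$, clipped to $[0,1]$; it is
consistent for the Balding-Nichols $F_{ST}$ on true frequencies, and noise in
estimated frequencies inflates it — which is exactly the diagnostic the
benchmark uses. `bias_curve()` summarizes $\hat q_{i1}$ against the true
$q_{i1}$ by a 20-bin conditional mean (deterministic; a LOESS flavor with
span 0.5 is available for plotting), excluding reference individuals.

## Problem sizes used by the tests

The unit tests run on small instances (tens of individuals, hundreds of
markers) chosen to exercise every code path in seconds. The acceptance suite
and `scripts/acceptance.R` run the full benchmark design — ten replicates of
the 400-individual, 10,000-marker, $F_{ST}=.01$ cohort, fitted both
unsupervised and supervised, plus a 5-fold CV over the $\lambda$ grid on one
replicate — sizes chosen to make the replicate averages stable while keeping
a complete run in the tens of minutes on one CPU.

## Known limitations

* Independent-marker likelihood: no LD modeling.
* The admixture grid design supports exactly two populations (the benchmark's
  design); general-$K$ simulation is available without grid admixture.
* Exhaustive label matching is limited to $K \le 8$.
* The penalized objective is not concave; the optimizer guarantees monotone
  ascent to a stationary point, not a global optimum. In practice fits from
  different seeds on well-separated data agree up to label permutation, and
  the tests check this.
* Supervised mode trusts its labels; mislabeled references are not detected.
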