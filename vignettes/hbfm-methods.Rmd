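---
title: "Sparse Bayesian factor models for single-cell co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse Bayesian factor models for single-cell co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Single-cell RNA-seq count matrices are zero-inflated and overdispersed, and
co-expression methods built for bulk data transfer poorly. This package
models the raw counts directly. Let $Y_{gi}$ be the count for gene
$g = 1, \dots, G$ in cell $i = 1, \dots, N$. Conditional on cell-specific
latent factor scores, counts are Poisson:

$$Y_{gi} \sim \mathrm{Poisson}(\mu_{gi}), \qquad
\mu_{gi} = \beta_g \prod_{f=1}^{F}
  e^{-\frac{\phi_f}{2}\lvert \alpha_{gf}\rvert}\,
  \lambda_{if}^{\alpha_{gf}},$$

where $\beta_g > 0$ is the gene's average expression,
$\lambda_{if} \sim \mathrm{Lognormal}(0, \phi_f)$ is a positive factor
score unique to cell $i$, and $\alpha_{gf} \in \{-1, 0, 1\}$ is a discrete
loading that switches factor $f$ off, on, or on-inverted for gene $g$.
Throughout the package $\phi_f$ is the **variance** of
$\log \lambda_{if}$; that convention is forced by the variance identity
$\mathrm{Var}[\log \mu_{gi}] = \sum_f \phi_f \alpha_{gf}^2$ used below.
The $e^{-\phi_f/2\lvert\alpha_{gf}\rvert}$ adjustment makes
$E(Y_{gi}) = \beta_g$ regardless of the loadings, and marginally over the
factors

$$\mathrm{Var}(Y_{gi}) = \beta_g + \beta_g^2
  \Bigl(e^{\sum_f \phi_f \lvert \alpha_{gf}\rvert} - 1\Bigr) \ge \beta_g,$$

so the model is conditionally Poisson but marginally overdispersed, with
small factor scores generating excess zeros. (This multi-factor,
positive-sign form of the variance follows from the law of total variance
with lognormal moments; `marginal_moments()` is validated against a
Monte-Carlo oracle in the test suite.)

Priors: $\beta_g \sim \mathrm{Gamma}(0.001, 0.001)$;
$\phi_f \sim \mathrm{Lognormal}(h_1, h_2)$ with
$h_1 \sim \mathrm{Normal}(0, 100)$ and
$h_2 \sim \mathrm{InverseGamma}(1, 1)$;
$\lvert\alpha_{gf}\rvert \sim \mathrm{Bernoulli}(\theta_f)$ split evenly
between $+1$ and $-1$, with $\theta_f \sim \mathrm{Beta}(1, 1)$. All of
these are adjustable through `hbfm_priors()`.

## The network statistic

Marginally over the factor scores,

$$\mathrm{Cov}[\log\mu_{gi}, \log\mu_{g'i}]
   = \sum_f \phi_f \alpha_{gf}\alpha_{g'f},
\qquad
\rho_{gg'} = \frac{\sum_f \phi_f \alpha_{gf}\alpha_{g'f}}
 {\sqrt{\bigl(\sum_f \phi_f \alpha_{gf}^2\bigr)
        \bigl(\sum_f \phi_f \alpha_{g'f}^2\bigr)}}.$$

A pair sharing one factor with equal signs has $\rho = 1$; opposite signs
give $-1$; disjoint supports give $0$; and any $0/0$ case (a gene with no
active factor) is defined as exactly $0$, including that gene's diagonal,
so all-inactive genes can never form edges. At every retained MCMC sweep
the package evaluates $\rho$ at the current $(\alpha, \phi)$; the pooled
draws give the posterior mean $\hat\rho_{gg'}$, equal-tailed credible
intervals, and the approximate p-value $a^*$ — the size of the smallest
equal-tailed interval containing zero,
$a^* = 2\min(\#\{\rho<0\}, \#\{\rho>0\})/M$. An edge is declared when the
$100(1-\alpha^*)\%$ interval excludes zero (default level 0.95). No
multiple-testing correction is applied to these edges: the credible
interval is the decision rule, and $a^*$ is used only to rank pairs.
Equal-tailed intervals (rather than HPD) were chosen so the interval rule
and the $a^*$ threshold rule are exact duals of one another, which the
tests verify.

## Inference

The posterior is explored by Metropolis-within-Gibbs sweeps over
(1) $\beta_g$, conjugate Gamma; (2) $\theta_f$, conjugate Beta;
(3) each $\alpha_{gf}$ one at a time from its three-point conditional in a
fixed row-major order; (4–5) $h_1, h_2$, conjugate Normal /
Inverse-Gamma; (6) $\phi_f$ by a lognormal random-walk Metropolis step,
$\log\phi^{(c)} \sim N(\log\phi_f, \sigma^2)$; and (7) each
$\lambda_{if}$ by an independence Metropolis step whose proposal is
generalized inverse Gaussian, $\mathrm{GIG}(\kappa, b\tau, b\chi)$ with
$\kappa = \sum_g y_{gi}\alpha_{gf}$ and $\tau, \chi$ the positive- and
negative-loading coefficients in the conditional; $b = 0.9$ thickens the
proposal tails. When a factor is active for no gene, $\phi_f$ and its
$\lambda_{\cdot f}$ column are refreshed jointly from their priors — a
valid block draw since the likelihood does not involve them.

Three derivations deserve a note:

* **$\alpha$ weights.** The three-point conditional is derived directly
  from the joint (Poisson likelihood times Bernoulli prior). Besides the
  mean-sum terms, the active choices pick up the data-dependent factors
  $\lambda_{if}^{\pm y_{gi}}$ and $e^{-\phi_f/2\sum_i y_{gi}}$, which do
  not cancel across the three values. Weights are computed on the log
  scale and normalized by log-sum-exp; the tests compare the resulting
  frequencies with brute-force enumeration of the joint on a one-gene toy.
* **GIG boundary cases.** $\chi = 0$ with $\kappa > 0$ degenerates to
  $\mathrm{Gamma}(\kappa, b\tau/2)$; $\tau = 0$ with $\kappa < 0$ to
  $\mathrm{InverseGamma}(-\kappa, b\chi/2)$; $\kappa = 0$ with one of
  $\tau, \chi$ zero falls back to a Lognormal$(0,\phi_f)$ prior proposal
  with the usual Metropolis correction. These are the standard GIG limits.
  No installed sampler for the GIG exists in this stack, so the package
  implements the tangent-envelope rejection sampler of Devroye (2014),
  exact for all parameter values; it is validated against
  numerical-integration moments and CDFs.
* **Proposal scale.** The random-walk scale $\sigma$ is not part of the
  model. It defaults to 0.3 per factor and is tuned during the
  pre-retention window toward a 25–45% acceptance rate, frozen before the
  first retained sweep so the retained chain is a fixed-kernel Markov
  chain.

Gamma distributions are shape/rate and Inverse-Gamma shape/scale
throughout. All draws flow through R's RNG, so a chain is bit-for-bit
reproducible from its seed. The factor-product matrix
$C_{gi} = \mu_{gi}/\beta_g$ is maintained by rank-1 updates within a sweep
and fully recomputed at the start of every sweep, bounding numerical
drift; the test suite checks the recorded likelihood against a fresh
evaluation. Two numerical guards truncate degenerate excursions under the
diffuse priors: prior-path draws of $\phi$ are clipped to
$[10^{-6}, 10^3]$ and of $\log\lambda$ to $[-27.6, 27.6]$, and Metropolis
proposals outside $[10^{-12}, 10^{12}]$ are rejected (Metropolis on a
truncated support). These bounds are far outside any scientifically
meaningful regime and are mirrored in the forward simulator used by the
joint-distribution test.

## Warm starts, chain ranking, and choosing F

One-at-a-time $\alpha$ sampling cannot split or merge factors, so chains
can stall in local modes. Each chain is therefore warm-started by a
stochastic EM pass (`initialize_chain()`): a randomized start, 100 full
MCMC sweeps,
then 2,000 EM sweeps in which $\beta$ is set to its conditional mode
(floored at $10^{-4}$ for all-zero genes), $\alpha$ to its conditional
argmax, and $\phi$ to the 1-D maximizer of its conditional (golden-section
on $\log\phi$, bracket $[10^{-6}, 10^3]$, tolerance $10^{-8}$); $\theta,
h_1, h_2, \lambda$ remain sampled. Continuous parameters are averaged over
the last 200 EM sweeps and each $\alpha_{gf}$ takes its most frequent
value, ties broken uniformly at random.

The starting configuration deserves a note, because the local-mode
problem makes it consequential. $\beta$ starts at jittered gene means and
$\phi, \lambda$ at prior draws with $h_1 = 0, h_2 = 1$. For the loadings,
two start styles are implemented. The `"uniform"` style draws $\alpha$
iid over $\{-1, 0, 1\}$ with $P(\pm 1) = 0.1$; it explores broadly but a
noticeable fraction of EM passes collapse to all-inactive configurations
or merge gene groups. The `"cluster"` style seeds $\alpha$ from a
hierarchical clustering of the genes on the Spearman correlation of
$\log(1 + Y)$ — each cluster starts one factor column, signs taken from
the correlation with the cluster medoid — with 10% of entries
re-randomized per chain; it lands in high-likelihood modes reliably but
different chains then share the same weak incidental factors, and a
spurious association present in every kept chain survives the pooled
credible interval. `hbfm()` therefore **alternates** the two styles
across chains: cluster-seeded chains anchor the strong structure, while
uniformly-started chains provide independent exploration, so weak
incidental factors differ across chains and pooling filters them out of
the edge set. This is an initialization protocol only: it enters nothing
into the posterior, and the retained MCMC phase is identical regardless
of the start.

`hbfm()` runs 8 such chains by default and keeps the 5 with the highest
mean retained conditional log-likelihood
$\log p(Y \mid \beta, \alpha, \phi, \lambda)$ — the marginal over
$\lambda$ is intractable, so this conditional average (on the log scale)
stands in for "average marginal likelihood"; the same conditional
likelihood defines the deviance $D = -2\log p$. `hbfm_select()` fits a
grid of factor counts and picks the lowest
$\mathrm{DIC} = \bar D + \tfrac{1}{2}\mathrm{Var}(D)$ (half the posterior
deviance variance as the effective parameter count, sample variance with
$n-1$). If the grid maximum wins, the grid is extended once (default +3)
and the comparison repeated. Overshooting the true factor count is benign
and expected: extra factors give the sampler room to explore, and
selected models routinely carry more factors than the generating process.

## Simulated data

`sim_design()`/`simulate_counts()` generate the model-based benchmark
conditions: $G = 50$ genes in ten groups of five sharing identical
loading rows, $\beta_g \sim \mathrm{Gamma}(3, 0.5)$ (shape/rate, mean 6),
$\lambda_{if} \sim \mathrm{Lognormal}(0, \phi_f)$, and $\phi$ drawn from
the multiset $\{0.20, 0.35, 0.50, 0.65, 0.80\}$ — twice each for the
10-factor design, three times each for the 15-factor design. The shipped
`"sim10"` wiring (each group owns a factor, cyclically cross-loaded with
alternating signs) yields exactly 350 true edges; `"sim15"` (ten private
factors plus four shared triples and one shared pair) yields 425. Only
the group structure, $\phi$ multiset and edge counts are fixed, externally given
constraints; the exact wiring is this package's canonical choice, so
benchmark reproduction is statistical, not bit-level.

`simulate_norta()` generates the off-model benchmark: zero-inflated
negative binomial marginals coupled through a Gaussian copula (NORTA).
The latent copula correlation for benchmark-style runs defaults to the true
log-mean correlation matrix of the matching model design (a package
choice; the option is open). ZINB parameters are supplied by the user;
`synthetic_zinb_params()` provides a labelled synthetic table (means
Gamma(3, 0.5), dispersions U(0.5, 2), zero inflation U(0, 0.4)) for runs
that only need plausible single-cell-like marginals — it is not estimated
from any real dataset.

What these generators do **not** emulate: library-size differences,
batch effects, gene-length bias, pseudotime structure, or dropout that
depends on expression through anything other than the marginal ZINB.
Passing the simulation benchmarks therefore demonstrates correctness of
the inference machinery under the stated generative assumptions, not
robustness to everything real data can do.

## Validation strategy and problem sizes

The test suite checks the sampler at three levels, all chosen to run on a
single CPU in minutes:

* every conditional update against closed forms, brute-force enumeration,
  or grid-integration oracles (total variation < 0.05 for the $\phi$ and
  $\lambda$ Metropolis chains, at both $b = 0.9$ and $b = 1$);
* the full sweep against a joint-distribution (Geweke-style) test at
  $G = 4, N = 30, F = 2$: moments from successive-conditional simulation
  must match forward simulation within 4 standard errors. Because the
  $(\phi, h)$ block of the successive chain mixes slowly, several
  independent successive chains are run and the spread of their means
  supplies the standard error (a single chain's batch-means SE
  understates it). The test runs under proper, tighter priors
  ($\beta \sim \mathrm{Gamma}(2,1)$, $h_1 \sim N(0, 0.25)$,
  $h_2 \sim \mathrm{IG}(3, 2)$) because the default diffuse priors make
  forward simulation numerically degenerate; transition-kernel
  correctness does not depend on the hyperparameter values;
* end-to-end parameter recovery and benchmark reproduction on scaled-down
  analogues of the reference benchmark conditions: the 10-factor design at
  $N = 500$ with $F = 15$, 3 chains and a halved iteration schedule for
  correlation recovery (Pearson $r \ge 0.9$ against the true $\rho$), and
  DIC selection over $F \in \{10, 15, 25\}$ with 4 chains keeping 3,
  1,500 sweeps retaining 500, EM schedule 80/1000/125, for the TPR/FDR/AUC
  benchmarks at $N = 125$ and $N = 500$. These problem sizes are the
  package's regression-test choices; the full reference protocol
  (9-point grid, 8 chains keeping 5, 4,000 sweeps retaining 1,000)
  remains the default configuration of `hbfm()` and `hbfm_select()`.

## Known limitations

* Runtime grows as $O(G \cdot N \cdot F)$ per sweep; hundreds of genes
  and thousands of cells are practical, genome-wide matrices are not.
  Pre-select genes (clustering, differential expression) first.
* The conditional likelihood stands in for the marginal in chain ranking
  and DIC; both are therefore conditional-scale quantities and should be
  compared only across runs with the same data.
* Edges are defined by the credible-interval rule with no
  multiplicity adjustment; interpret edge counts accordingly.
* The discrete loading space means $\rho$ draws move in jumps; with few
  retained sweeps the equal-tailed intervals are coarse. Use the default
  retention (1,000) or more for final inference.
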