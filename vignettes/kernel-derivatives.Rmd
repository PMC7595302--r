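---
title: "Kernel derivatives and sensitivity analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel derivatives and sensitivity analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernsens)
```

## The common core: derivatives of kernel expansions

Every method in this package manipulates one object, the kernel expansion
$f(x) = \sum_{i=1}^n \alpha_i k(x, x_i) + b$. Differentiation is linear, so
every derivative of $f$ is the same contraction of $\alpha$ with the
corresponding derivative of the kernel function:
$\partial_j f(x) = (\partial_j k(x))^\top \alpha$, the gradient is
$(\nabla K)^\top\alpha$, the Hessian entry $(j,k)$ is
$(\partial_j \partial_k k(x))^\top\alpha$, and the Laplacian is the trace of
the Hessian. The bias $b$ contributes zero to every derivative. Five kernel
families carry closed-form first and second derivatives here: linear,
polynomial, RBF $e^{-\gamma\|x-y\|^2}$, hyperbolic tangent, and ARD
$\nu^2 e^{-\frac12\sum_d ((x_d-y_d)/\lambda_d)^2}$.

Two derivative conventions are fixed package-wide:

* **Derivatives are with respect to the first kernel argument.** Derivatives
  with respect to the second argument follow from symmetry (dot-product
  families) or antisymmetry (stationary families) and are never duplicated
  in code.
* **Tensor layout.** Gram-derivative tensors are indexed (evaluation point,
  anchor, feature), so contracting slice $j$ with $\alpha$ over anchors
  yields the $j$-th gradient component at each evaluation point.

**A note on the ARD family.** Published derivative tables for the ARD kernel
sometimes print $\partial k/\partial x^j = ((x^j - y^j)/\lambda_j^2)\,k$ and
a second partial $(1/\lambda_j^2 + ((x^j-y^j)/\lambda_j^2)^2)\,k$. Direct
differentiation of the kernel gives the opposite signs:
$-((x^j-y^j)/\lambda_j^2)\,k$ and
$(((x^j-y^j)^2/\lambda_j^4) - 1/\lambda_j^2)\,k$. This package follows the
calculus; the finite-difference oracle in the test suite confirms the signs
for all families, which is exactly the kind of error that battery exists to
catch.

**Higher RBF orders.** Unmixed $m$-th partials of the RBF kernel come from
the Faà di Bruno identity applied to $k = f(g)$ with $f = \exp$ and
$g = -\gamma\|x-y\|^2$. Only $g'$ and $g''$ are nonzero, so the identity
collapses to a sum over pairs $(t_1, t_2)$ with $t_1 + 2t_2 = m$ (the
coefficients are the Hermite-polynomial coefficients in disguise). Orders
$m = 1, 2$ reproduce the closed-form gradient and Hessian entries to machine
precision; $m = 3, 4$ were verified against symbolic differentiation.

**Parameterization.** The RBF scale is accepted either as $\gamma$ or as a
bandwidth $\sigma$ with $\gamma = 1/(2\sigma^2)$, and stored as $\gamma$.
This mapping matters twice: the density kernel is the normalized Gaussian
$(2\pi\sigma^2)^{-d/2} e^{-\|x-y\|^2/(2\sigma^2)}$, and the HSIC trace-form
gradient carries a $1/\sigma^2$ prefactor that is consistent with the
elementwise form only under this mapping (the two code paths are compared to
$10^{-10}$ in the tests, so any inconsistency would surface immediately).

## Sensitivity maps

The feature sensitivity $s_j = \frac1n\sum_i (\partial f(x_i)/\partial x^j)^2$
and point sensitivity $q_i = \frac1d\sum_j (\partial f(x_i)/\partial x^j)^2$
are empirical-mean estimators of the expected squared derivative. Squared
derivatives (rather than absolute values) are the package default; both
summaries share the same squared-derivative table, so
$n\sum_j s_j = d\sum_i q_i$ holds as an algebraic identity and is asserted to
$10^{-12}$. The integral definition weights each dimension by its marginal
density; the empirical estimator instead averages over joint samples at a
caller-supplied evaluation set (defaulting to the training anchors). That gap
is inherent to the empirical form and not corrected here.

## GP / kernel ridge regression

`gp_fit` solves $(K + \sigma_n^2 I)\alpha = y$ by Cholesky factorization.
Numerical policy: if the factorization fails, a jitter of
$10^{-10}\,\mathrm{tr}(K)/n$ is added and doubled up to
$10^{-6}\,\mathrm{tr}(K)/n$ before giving up; the solve is polished with up
to three iterative-refinement steps. Interpolation ($\sigma_n^2 = 0$) is
only meaningful on well-conditioned systems: random designs routinely
produce near-duplicate inputs for which no solver can interpolate
conflicting noisy targets, which is why the interpolation contract in the
tests uses an equally spaced design and a scale on which the Gram matrix is
comfortably invertible (n = 40, $\gamma = 300$ on $[0,1]$). The predictive
variance $\sigma_n^2 + k_{**} - k_*^\top(K+\sigma_n^2 I)^{-1}k_*$ is clipped
at zero against round-off.

The noise experiment (`noise_norm_experiment`) fits the $\sin(3\pi x)$
signal under additive white Gaussian noise over an SNR grid (0–50 dB,
$\mathrm{SNR} = 10\log_{10}(\sigma_y^2/\sigma_n^2)$ with $\sigma_y^2$ the
empirical clean-signal variance) and records four quadratic forms:
$\alpha^\top K\alpha$, $\alpha^\top K^\top K\alpha$,
$\alpha^\top(\nabla K)^\top(\nabla K)\alpha$ and
$\alpha^\top(\nabla^2 K)^\top(\nabla^2 K)\alpha$, the derivative matrices
stacked feature-wise so the forms are defined for any input dimension. Three
experiment-design choices, all visible in the function signature or
documented there:

* inputs are equally spaced (see above);
* "optimal regularization" in the regularized arm means
  $\sigma_n^2$ set to the injected noise variance;
* noise realizations are drawn as antithetic pairs shared across the SNR
  grid (common random numbers). The recorded norms are quadratic in the
  noise amplitude; antithetic pairing cancels the linear cross term exactly,
  so the per-SNR means are monotone in the noise level without needing
  enormous repeat counts. Default problem size: n = 100, 20 repeats, six SNR
  levels.

Hyperparameters default to the median heuristic
$\gamma = 1/(2\,\mathrm{median}^2(\text{pairwise distances}))$; there is no
marginal-likelihood optimization. Where tuning is wanted, the same k-fold
machinery used for the SVM applies.

## SVM classification

The soft-margin dual is handed to a generic interior-point QP solver
(`kernlab::ipop`) with a $10^{-8}$ diagonal regularizer for numerical
definiteness; the package's own contract is dual feasibility (box and
equality constraints within $10^{-6}$), so any QP solver is swappable. The
bias is averaged over free support vectors, falling back to the midpoint of
the KKT interval when no coefficient is strictly inside the box. The sign
mask of the decision rule is replaced by $\tanh$ with unit slope for
differentiability; the masked gradient factorizes as
$(1-\tanh^2 f)\,\partial f$, and `margin_sensitivity` reports the mask-only,
kernel-only and composite point sensitivities separately. Hyperparameter
selection is a 3-fold grid over $C \in \{0.1, 1, 10, 100\}$ and
$\gamma \in \text{median heuristic}\times\{1/4, 1, 4\}$; no class
reweighting is applied.

## Density estimation and ridges

`parzen_fit` represents the Parzen estimate as an RBF expansion with
coefficients $(2\pi\sigma^2)^{-d/2}/n$, so density derivatives reuse the
expansion machinery unchanged. The default bandwidth is the per-dimension
Silverman rule averaged to one isotropic value — adequate for the built-in
toys, and overridable wherever it is not.

The eigendecomposition-restricted density keeps $r$ components of the
*un-centered* Gram matrix $K = EDE^\top$ and uses
$\alpha = \frac1n E_r E_r^\top 1_n$. The $\frac1n$ is a deliberate
normalization choice: without it the $r = n$ case would not reduce to the
Parzen estimate (the tests verify the reduction to $10^{-10}$). For
$r < n$ the restricted density is an unnormalized smoothed approximation;
renormalize on a grid if a proper pdf is required. Component selection is
either by eigenvalue ("variance") or by information-potential contribution
$d_i (e_i^\top 1_n)^2$ ("entropy", the kernel-entropy-component ranking);
because the contributions are additive and nonnegative, the greedy top-$r$
choice is exactly optimal, which the tests confirm by exhaustive subset
search at small n.

Ridge membership: a point is scored by $\|V(x)^\top \nabla \hat p(x)\|$
where $V(x)$ holds $d - r_{\text{ridge}}$ Hessian eigenvectors. Two
ambiguities had to be settled:

* **Which eigenvectors.** The density-ridge convention projects onto the
  *trailing* (most negative) eigenvectors and additionally requires those
  eigenvalues to be negative for a point to qualify; a "largest" rule is
  kept behind a flag for the alternative top-eigenvector reading found in
  parts of the literature. The default is the trailing rule.
* **Which scale.** By default the score uses the gradient and Hessian of
  $\log \hat p$ rather than $\hat p$. The two have identical ridge sets
  (log is monotone), but the raw-density score vanishes wherever the
  density itself is small, so a percentile threshold over a sample retains
  spurious far-tail and inflection-zone points; the log-density Hessian of
  a Gaussian-like crest stays negative definite across its flanks and the
  threshold behaves. The raw-density score is available via
  `scale = "density"` and is what the finite-difference oracle test checks
  directly.

The retention threshold $\varepsilon$ defaults to the 5th percentile of
scores over the evaluation set — there is no canonical absolute threshold,
and a percentile keeps the retained set size predictable. Extracted points
are ordered by Dijkstra distance from a maximal-eccentricity endpoint of the
mutual 5-NN graph; disconnected graphs are handled per component with
component labels. The package deliberately detects ridge membership among
supplied points; it does not project points onto the ridge (no mean-shift
iteration).

## HSIC

The biased estimator $\frac{1}{n^2}\mathrm{Tr}(KHLH)$ is used throughout; no
unbiased variant. Gradients come in two code paths — the general elementwise
form $\frac{2}{n^2} A_i \partial_q k(x_i)$ with $A = HLH$, and the RBF trace
form with prefactor $-2/(\sigma^2 n^2)$ — kept deliberately separate so each
validates the other (they agree to $10^{-10}$; both match finite differences
of the HSIC value to $10^{-6}$). Translation invariance of stationary
kernels makes each gradient column sum to zero, a cheap invariant asserted
throughout.

The gradient flow applies explicit Euler updates
$X \leftarrow X \pm \eta\, \mathrm{d}X$. Bandwidths are computed once by the
median heuristic and **frozen** during the flow: refreshing them every step
changes the objective between steps and breaks monotonicity guarantees
(refreshing is available behind a flag). The default step is scale-aware,
$\eta = 0.05 \cdot \text{data scale}/\max|\nabla|$ at $t = 0$; with this
step the maximize-direction trace is non-decreasing over the 50-iteration
runs in the tests. A non-finite HSIC value aborts the flow.

## Synthetic data

The generators emulate the qualitative structure the analyses need — a
smooth 1-D signal with exactly calibrated SNR, interleaving half-moons and
concentric circles with Gaussian jitter, overlapping anisotropic Gaussian
clouds, ring/arc/blob densities, paired variables with sinusoidal, ring,
clustered or absent association, and a continuous piecewise-linear surface
$y = a(x_1)\,x_1 + x_2$ with $a = 5$ for $x_1 > 0$ and $a = 1$ otherwise on
$U([-20,20]^2)$. Parameters that the motivating figures leave unstated
(ring radius 1, arc over $[0, \pi]$, sinusoid frequency $\omega = 2$ over
$[-2, 2]$, toy noise levels) were fixed once at values giving clearly
structured data — e.g. $\omega = 2$ keeps the sinusoid's HSIC well above the
independent-pairs baseline at n = 200 — and are exposed as arguments. All
generators draw through an explicitly seeded, state-restoring RNG wrapper:
the same spec reproduces bit-identical arrays and never perturbs the
caller's RNG stream.

What passing tests on these toys do *not* show: behavior under heavy-tailed
noise, discrete or mixed-type features, high input dimension (the toys are
1-D/2-D; the derivative code itself is dimension-generic and the oracle
battery runs at d = 5), or sample sizes beyond a few thousand (all Gram
computations are dense $O(n^2)$ memory and $O(n^3)$ factorizations).

## Numerical conventions

* Finite-difference oracle: central differences with relative step
  $10^{-6}\max(1,|x_j|)$ for gradients, nested central differences with
  $10^{-4}\max(1,|x_j|)$ for Hessians. It is a test oracle, not a production
  differentiator.
* Analytic Hessians are symmetrized ($\tfrac12(H + H^\top)$) so symmetry is
  exact by construction.
* Problem sizes in the default test and verification runs were chosen to
  finish in seconds while leaving the contracts sharp: 200 random pairs per
  family at d = 5 for the gradient battery, n = 100 with 20 repeats for the
  noise experiment, n = 200/400 train/test for two-moons, n = 1000 with
  three replicates for ridge recovery, n = 150 with 50 iterations for the
  flows.

## Known limitations

* Dense linear algebra throughout; no Nyström or sparse Gram approximations.
* Mixed higher-order partials (beyond second) are not implemented; unmixed
  higher orders are RBF-only.
* The restricted (r < n) density is unnormalized; only the full-rank case is
  a proper pdf.
* `svm_fit` is binary only, without probability calibration or class
  weighting.
* HSIC has no permutation null or p-values — it is used here as a
  differentiable objective, not a test statistic.
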