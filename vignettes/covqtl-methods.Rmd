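---
title: "Bivariate covariation QTL mapping: model, calibration and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate covariation QTL mapping: model, calibration and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

In an outbred full-sib (F1) mapping population, a marker whose genotype
classes differ in the *joint* mean of two traits is evidence for a
pleiotropic locus shaping how growth is allocated between those traits — a
"covariation QTL" (covQTL). `covqtl` tests this at every marker of a dense
linkage map with a multiplicative bivariate-normal likelihood: because the
map is dense, QTLs are assumed to sit at marker positions, and no interval
mixture model is used between markers.

Let $\mathbf{y}_i = (y_{1i}, y_{2i})$ be the phenotype pair of individual
$i$, and let genotype class $j \in \{1,\dots,k\}$ at the tested marker
contain $n_j$ individuals ($k = 2$ for testcross markers segregating 1:1,
$k = 3$ for intercross markers segregating 1:2:1). Under the alternative,

$$L(\Phi \mid \mathbf{y}) = \prod_{j=1}^{k} \prod_{i \in j}
  f_j(\mathbf{y}_i), \qquad
  f_j = \mathcal{N}_2\!\left((\mu_{1j}, \mu_{2j}),\ \Sigma\right),
  \qquad
  \Sigma = \begin{pmatrix}
    \sigma_1^2 & \rho\,\sigma_1\sigma_2 \\
    \rho\,\sigma_1\sigma_2 & \sigma_2^2
  \end{pmatrix},$$

so each class has its own mean vector while all classes share one
covariance matrix whose off-diagonal carries the trait–trait correlation
$\rho$. Under the null all class means collapse to a single $(\mu_1,
\mu_2)$ with a freely re-estimated $\Sigma_0$. Both MLEs are closed form:
class (or grand) sample means, and the pooled within-class (or total)
scatter divided by $n$. The test statistic is

$$\mathrm{LR} = 2\,(\hat\ell_1 - \hat\ell_0)
  = n \log \frac{|\hat\Sigma_0|}{|\hat\Sigma_1|},$$

with $2(k-1)$ degrees of freedom. The factor 2 puts the statistic on the
conventional $\chi^2$ scale; since the same convention is applied inside
the permutation threshold, significance calls do not depend on it. The
determinant identity (the Wilks-Lambda form for Gaussian mean-shift models
with a common covariance) is not just an implementation convenience: the
package evaluates the log-likelihoods directly when fitting single markers
and uses the scatter-matrix form in the vectorised genome scan, and the
test suite requires the two routes to agree to $10^{-8}$ on a thousand
random instances.

Two consequences of the model worth keeping in mind:

* **Affine invariance.** Rescaling either trait by any non-degenerate
  affine map leaves every LR unchanged, because both determinants pick up
  the same Jacobian factor. Unit conventions (e.g. whether a stem diameter
  enters in mm or m) therefore cannot change any mapping result. The scan
  exploits this by standardising each trait once per scan, which avoids
  catastrophic cancellation in raw-moment scatter sums for traits with
  large offsets.
* **Independent $\Sigma$ per hypothesis.** $\Sigma$ is re-estimated under
  the null rather than recycled from the alternative. This is the standard
  LR construction for nested models and guarantees $\mathrm{LR} \ge 0$;
  tiny negative values from floating-point rounding (within $10^{-8}$) are
  clamped to zero, anything worse is treated as an internal error.

## Genome-wide significance by permutation

The genome-wide null distribution of $\max_m \mathrm{LR}_m$ is intractable
analytically (markers are linked and the two marker types mix $\chi^2_2$
and $\chi^2_4$ baselines), so the critical threshold is empirical:
phenotype rows are reshuffled against the genotypes and the maximum LR over
all markers is recorded per permutation. Two design choices are deliberate:

* **Rows are permuted as intact $(y_1, y_2)$ couples.** The null being
  tested is *no marker–phenotype association*, not *no trait–trait
  correlation*; permuting traits independently would destroy $\rho$ and
  test the wrong null.
* **The threshold is the smallest of the top $\lfloor \alpha \cdot
  n_{\mathrm{perm}} \rfloor$ maxima** — with 1,000 permutations at
  $\alpha = 0.05$, the 50th-largest maximum. One threshold is computed per
  trait pair, genome-wide, with both marker types pooled. Significance
  uses $\ge$, so exact ties are called.

With $n_{\mathrm{perm}} = N$ and threshold index $k = \lfloor \alpha N
\rfloor$, exchangeability gives a family-wise error of about $k/(N+1)$
(0.0497 for $N = 200$, $\alpha = 0.05$), which is what the acceptance
simulation measures. Because marker eligibility and class memberships do
not change under row permutation, the scan precomputes one index structure
and re-evaluates the whole profile per permutation from scatter identities;
a 1,000-permutation threshold on a 560-marker, 200-individual map takes a
few seconds.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `min_class_size` | 5 | Smallest genotype class fitted at a marker. A 2×2 covariance MLE from fewer points is degenerate or wildly unstable; markers failing the bound are skipped with a logged reason, not errored. |
| `alpha` | 0.05 | Genome-wide significance level of the permutation threshold. |
| `n_perm` | 1000 | Permutations per trait pair; 200 is enough for calibration studies, 1,000 for reporting. |
| `gap_cM` | 10 | Largest gap between consecutive significant markers merged into one peak region. No canonical value exists; 10 cM is of the order of a dense-map QTL support interval. |
| `degree` | 3 | Polynomial degree for trait–trait trend fits. A cubic is the lowest degree that can express the rise-plateau-decline shapes seen in allometric scatters without oscillating on ~200 points. |
| `dbh_unit` | mm | Storage unit of stem diameter before derivation of volume (converted to m, so `V` is in m³ and `SB`, after g/cm³ → kg/m³, in kg). Only the absolute scale of `V`/`SB` depends on this, never a QTL call (affine invariance). |

Missing data are handled per marker: an individual missing either trait or
the marker's genotype is excluded from that marker's test only, so each
marker uses the largest complete-case subset available to it.

Duplicate markers — identical genotype vectors across the whole population,
missing positions included — carry no independent information and are
reduced to the first in map order by `dedup_markers()`. Exact equality is
the criterion; no similarity threshold is applied.

## What the simulator emulates — and what it does not

`simulate_population()` is the test bed for every other module. It
emulates:

* an outbred full-sib F1 population (default $n = 200$) genotyped on ~20
  linkage groups totalling ~3,150 cM with ~6,440 markers, ~17% of them
  intercross — the shape of a dense RAD-derived pseudo-testcross map;
* linkage by Haldane meiosis: each parent transmits a two-state allele
  chain along a group, switching between adjacent markers with
  $r = (1 - e^{-2d/100})/2$. Haldane (no interference) was chosen over
  Kosambi as the simplest self-consistent meiosis model; nothing downstream
  depends on the map function. Testcross markers read one informative
  parent (classes `a`/`b`, 1:1), intercross markers read both (classes
  `A`/`H`/`B`, 1:2:1, heterozygote phase collapsed — the likelihood only
  uses class membership);
* planted pleiotropic QTLs specified directly as per-class mean-shift
  vectors in residual-SD units, so additive, dominant or arbitrary
  patterns are expressible; a QTL is realised at the marker nearest its
  requested position, and that marker's type is forced to match the effect
  matrix;
* residuals drawn from a bivariate normal with configurable
  $(\sigma_1, \sigma_2, \rho)$, and optional missing-data injection for
  both genotypes and phenotypes.

It does **not** emulate: segregation distortion, genotyping error,
map-order error, polygenic background beyond the planted QTLs,
block-design or spatial field effects, or non-Gaussian trait
distributions. Passing tests therefore show that the statistical machinery
is correct *under the stated model*; they cannot show robustness to model
misspecification in real field data, where residual non-normality and
distorted ratios would inflate or deflate the $\chi^2$ baselines (the
permutation threshold, being empirical, is the component most robust to
this).

## Numerical choices and degenerate inputs

* Scatter determinants $\le 0$ (a constant trait, perfect collinearity)
  make a marker ineligible — skipped in a scan, a classed error in a
  single-marker fit.
* Peak-region peaks break exact LR ties toward the first marker in map
  order; co-location keys on marker ids, not positions.
* All randomness flows through R's default generator; every simulation and
  permutation entry point takes a `seed` (or inherits the current stream
  when `seed = NULL`, which is how replicate schedules derive from one
  master seed). Fixed seed implies bit-reproducible output.
* Round-trip fidelity: writers emit numerics with 17 significant digits so
  read → write → read reproduces objects exactly.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` run a desk-scale version of a full
study: 200 individuals on 20 groups × 30 markers (tests of the generator
itself go up to 10,000 individuals for recombination-fraction checks).
Calibration studies use 200 null replicates × 200 permutations for the
family-wise error rate and 50–100 replicates per effect size for power
curves; these sizes put Monte-Carlo standard errors near 0.015 on an error
rate of 0.05, which is tight enough to detect miscalibration of practical
size while keeping a full run in minutes on one core.

## Known limitations

* Exactly two traits; trivariate and higher mapping is out of scope.
* No epistasis, no composite-interval covariates, no FDR control across
  trait pairs (each pair gets its own family-wise threshold).
* The asymptotic $\chi^2_{2(k-1)}$ null for a single fixed marker is used
  only as a diagnostic; all significance statements go through the
  permutation threshold.
* The simulator's intercross heterozygote is a single class; phase
  information, had it existed, would be ignored by the model anyway.
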