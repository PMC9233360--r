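---
title: "Moment estimation of kinship and fraternity from low-depth genotype likelihoods"
author: "glkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment estimation of kinship and fraternity from low-depth genotype likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glkin)
```

## The problem

The kinship coefficient $\varphi_{ii'}$ is the probability that two alleles
drawn at random at the same locus, one from individual $i$ and one from
$i'$, are identical by descent (IBD); the fraternity coefficient
$\psi_{ii'}$ is the genome fraction where the pair shares *both* alleles IBD
(full siblings: $\varphi = 0.25$, $\psi = 0.25$; a non-inbred individual
with itself: $2\varphi = 1$, $\psi = 1$). With accurate genotypes both are
estimated by genetic relationship matrices (GRMs) — averaged cross-products
of standardized genotype codings. With low-depth sequencing (a few reads
per site) genotypes cannot be called reliably; hard-calling the most likely
genotype biases GRMs, and discarding uncertain sites wastes most of the
data. `glkin` works directly on the per-site genotype *likelihoods* that
callers emit (`PL`/`GL` fields of a VCF) and corrects the bias that the
residual uncertainty induces.

## Moment estimators on genotype probabilities

Log-scaled likelihood triplets are rescaled per site and individual to
flat-prior genotype probabilities $(P_{AA}^{ij}, P_{Aa}^{ij}, P_{aa}^{ij})$
(`normalize_likelihoods()`). Sample genotype frequencies
$\bar P^j = (\bar P_{AA}^j, \bar P_{Aa}^j, \bar P_{aa}^j)$ are their means
over non-missing individuals.

Per variant, two codings of the genotype value $k \in \{0,1,2\}$ are built
from $\bar P^j$ alone — deliberately *without* assuming Hardy–Weinberg
proportions, which low-depth data distort:

* additive: $\tilde\alpha_k = (k - m)/\sqrt{v_A}$ with
  $m = \bar P_{Aa} + 2\bar P_{aa}$ and
  $v_A = \bar P_{Aa} + 4\bar P_{aa}\bar P_{AA} - \bar P_{Aa}^2$;
* dominance: $\tilde\delta \propto
  (\sqrt{\bar P_{aa}/\bar P_{AA}},\,
   -2\sqrt{\bar P_{aa}\bar P_{AA}}/\bar P_{Aa},\,
   \sqrt{\bar P_{AA}/\bar P_{aa}})$, normalized to unit variance.

Under the categorical law $\bar P^j$ both codings have mean 0, variance 1
and zero cross-moment, and in exact Hardy–Weinberg proportions they reduce
to the classical codings $\alpha_k = (k-2q)/\sqrt{2pq}$,
$\delta = (q/p, -1, p/q)$ — properties the test suite checks to $10^{-8}$
and $10^{-10}$. Individual scores are the probability-weighted codings
$\tilde X_A^{ij} = \sum_k \tilde\alpha_k^j P_k^{ij}$ (likewise $\tilde
X_D$), and the raw matrices are pairwise averages of score cross-products
over the variants non-missing in both individuals:
$\tilde K_{ii'} = \mathrm{mean}_j\, \tilde X_A^{ij}\tilde X_A^{i'j}$
(estimating $2\varphi$) and
$\tilde D_{ii'} = \mathrm{mean}_j\, \tilde X_D^{ij}\tilde X_D^{i'j}$
(estimating $\psi$). When external allele frequencies are supplied,
Hardy–Weinberg proportions are assumed and the codings are exactly the
classical ones; `em_allele_freq()` provides a per-variant Hardy–Weinberg EM
estimate for that mode.

Variants are pre-filtered on the mean expected minor-allele count
$\bar P_{Aa} + 2\bar P_{aa} \in [0.05, 1.95]$ (inclusive bounds; rare
variants destabilize the codings). Degenerate codings (additive variance
term or any dominance genotype frequency $\le 10^{-8}$) drop the variant
from the affected matrix only.

## Fuzziness and the bias correction

Per individual and site, *fuzziness*
$\upsilon = P_{Aa}(1-P_{Aa}) + 4P_{aa}(1-P_{aa}) - 4P_{Aa}P_{aa}$ is the
variance of the genotype value under the probability triplet: 0 exactly for
a certain genotype, at most 1. At low depth triplets are fuzzy, scores
shrink toward zero, and the raw matrices are downwardly biased by a
multiplicative factor that grows as depth falls — a property the tests
verify across mean depths $\{10\times, 5\times, 2.5\times\}$.

The correction exploits the between-variant spread of fuzziness. For a pair
$(i, i')$, the point-wise estimates $\tilde K^j_{ii'} = \tilde X_A^{ij}
\tilde X_A^{i'j}$ are regressed on
$(\upsilon^{ij}+\upsilon^{i'j},\ \upsilon^{ij}\upsilon^{i'j},\
\upsilon^{ij\,2}+\upsilon^{i'j\,2})$; the OLS intercept extrapolates the
pair's estimate to zero fuzziness, where the estimator is unbiased up to a
pair-independent scale. Design notes on this regression:

* The sum and product terms mirror the intuition that each individual
  contributes its own uncertainty and that the two interact. The
  per-individual quadratic term is included because the point-wise bias is
  convex in each individual's fuzziness under the Poisson read model: on
  the diagonal ($\upsilon^{ij} = \upsilon^{i'j}$) the product term already
  supplies the quadratic and the extra term is collinear (and dropped), but
  for off-diagonal pairs it is not, and omitting it makes off-diagonal
  intercepts extrapolate systematically high relative to the
  diagonal-anchored scale (about 15% at $2.5\times$ in our simulations),
  which propagates into over-corrected estimates.
* Degenerate designs (fewer than 3 usable variants, constant fuzziness)
  fall back to the plain mean, flagged in the diagnostics.

Calibration is two-step and uses a subset of pairs (default: the 20 highest
and 20 lowest raw off-diagonal entries, all pairs among 100 random
individuals, plus every diagonal element; regressions use a seeded
subsample of at most 20,000 variants):

1. The diagonal elements have known targets — $2\varphi_{ii} = \psi_{ii} =
   1$ in a non-inbred sample — so the mean diagonal intercept $\bar c$ is
   the intercept value corresponding to a true coefficient of 1.
2. A line through the off-diagonal pairs' (intercept, raw entry) cloud,
   evaluated at $\bar c$, gives the raw estimator's expected value for an
   off-diagonal pair with true coefficient 1: the multiplicative bias
   $\beta$ ($\beta_1$ for kinship, $\beta_2$ for fraternity). Because the
   intercepts are much noisier than the raw entries, the slope is obtained
   by regressing intercepts on raw entries and inverting (the standard
   errors-in-variables orientation); the direct regression is attenuated by
   the intercept noise and over-corrects.

The off-diagonal entries are divided by $\beta$. The diagonal is calibrated
by its own cluster (divided by the mean raw diagonal entry, the fitted
value of the diagonal regression at $\bar c$): a raw diagonal entry is a
mean of *squares* and keeps an additive noise-variance contribution that
cross-products of independently sequenced individuals average away, so a
single factor cannot calibrate both sets; treating them separately
reproduces both benchmarks (sibling $\hat\varphi \approx 0.25$ and
self-entries $\approx 1$) simultaneously, which a shared factor provably
cannot at $2.5\times$.

On noiseless data constructed to follow the bias model exactly, the whole
pipeline returns every pair's true coefficient to $10^{-6}$ and recovers a
constructed bias factor exactly — the oracle test of the calibration
algebra. The adjustment is a positive rescaling plus a constant shift, so
it never reorders pairs.

Finally, the first quartile of the off-diagonal coefficients is shifted to
zero (per matrix; diagonal untouched). This assumes most pairs are
unrelated — appropriate for the population samples the method targets — and
absorbs small additive offsets that appear with small samples or external
frequencies. The quartile is the linear-interpolation (type 7) percentile;
the shift is on by default and can be disabled.

Both matrices are corrected independently, with their own pair subsets,
regressions and $\beta$. Fraternity is intrinsically harder: dominance
scores carry less information per site, and at $2.5\times$ the adjusted
$\hat\psi$ remains noticeably attenuated even after correction — consistent
with the estimator's behaviour on real low-depth data — so `glkin` reports
it without claiming parity with kinship.

## The simulator

`sim_sib_study()` generates the validation fixtures end-to-end; every
component is seeded through named sub-streams so runs are bit-reproducible.

* **Pedigree and recombination.** Independent nuclear families (two founder
  parents, two full siblings) plus unrelated singletons are gene-dropped
  over a genetic map (default 10 chromosomes × 100 cM — a deliberately
  compact stand-in for a human autosomal map that keeps tests fast while
  leaving segment-number variance realistic enough for sibling IBD
  fractions). Crossovers per chromosome are Poisson(length/100) with
  uniform positions — the Haldane, no-interference model; interference
  would slightly reduce the variance of realized IBD fractions but not
  their means. Founder haplotypes carry unique ancestral labels, so
  realized IBD states (and hence true $\varphi$, $\psi$) are read off
  exactly, length-weighted, from label identity.
* **Variants.** Positions uniform along the map; alternate-allele
  frequencies uniform on (0.05, 0.5) by default (common variants, matching
  the estimator's default filter); founder alleles Bernoulli(q) — i.e. no
  linkage disequilibrium beyond what the pedigree itself induces.
* **Reads.** Per individual and site, three independent Poisson counts
  (reference reads, alternate reads, error reads) with rates $\rho \cdot
  d_j$, where $\rho$ depends on the true genotype and the site error rate
  $\varepsilon_j$ (heterozygotes: $(1-\varepsilon)/2 + \varepsilon/6$ per
  allele; error reads always $2\varepsilon/3$; rates sum to $d_j$ for every
  genotype). Site depths $d_j$ rescale a user template to the target mean,
  or default to Gamma(shape 2) — a right-skewed stand-in for empirical
  depth profiles; error rates are $10^{-u}$, $u \sim U(2,3)$. Likelihoods
  are the read-count multinomials under each candidate genotype with a flat
  prior; sites with no allele-bearing read are missing.

What the simulator does *not* emulate — linkage disequilibrium from real
haplotype panels, base-quality variation within a site, allele-balance and
mapping artifacts, batch effects — bounds what green tests mean: they
validate the estimator and its bias correction under the read model the
correction was derived for, not the full messiness of real pipelines.

## Numerical and interface choices

* Missing triplets are excluded from $\bar P^j$ (denominator = non-missing
  count) and from every pairwise average (pair-specific denominators), so
  each matrix entry stays an unbiased mean of its own terms.
* The VCF alternate allele is allele "a" throughout; no minor-allele
  folding. Both matrices are provably invariant to swapping the allele
  labels (tested exactly), so the choice is safe and reproducible.
* `PL` is preferred over `GL` when both are present; triplets are
  max-shifted on the log scale before exponentiation.
* Selection ties in the calibration pair subset break lexicographically by
  pair index; an all-zero `adjust_par` is rejected.
* Degeneracy tolerance for coding denominators: $10^{-8}$.
* Reported kinship is $\hat\varphi = K/2$; the matrices themselves are on
  the $2\varphi$ scale, and both scales appear in the outputs.

Problem sizes: the validation suite runs the full study design at 200
sampled individuals (20 sibling pairs), 50,000 SNPs at $2.5\times$ mean
depth, sibling IBD checks on 500 gene-dropped pairs, and smaller
configurations (tens of individuals, a few thousand SNPs) for the
structural tests — sizes chosen so the whole suite completes in a couple
of minutes on a laptop while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* Inbreeding is not modelled: the diagonal calibration assumes non-inbred
  individuals, and inbred samples would violate both it and the
  quartile-shift assumption.
* The calibration needs spread in the unadjusted estimates; a sample with
  no related pairs degrades $\beta$ towards its diagonal fallback.
* Fraternity at very low depth ($\lesssim 1\times$) is not informative;
  kinship degrades more gracefully.
* Multi-allelic sites, indels and non-diploid data are out of scope.
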