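---
title: "Mapping trait loci from deregressed breeding values: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trait loci from deregressed breeding values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winqtl)
```

## The problem

Progeny-test populations offer highly accurate estimates of a sire's
genetic merit — EBVs with reliabilities often above 0.8 — but no usable
individual phenotypes: the sire's own record is either absent or
dwarfed by the information in its offspring. Association analysis in
such panels therefore uses **deregressed EBVs (dEBVs)** as
pseudo-phenotypes. Two features of these data drive the whole design
of this package:

* the animals are strongly related (paternal half-sib families,
  selection candidates from few widely used sires), so association
  tests must model the covariance among records, and
* dEBVs have **heterogeneous precision**: a proof backed by a thousand
  daughters is far less noisy than one backed by twenty, so each
  record carries an information weight.

## Model

### Deregression

For an animal without parent information, deregression is
`debv = ebv / r²` with effective reliability `r*² = r²`. With parent
information, the package reconstructs the 2×2 mixed-model-equation
system in (parent average, individual) implied by the reported
reliabilities and the variance ratio `λ = (1 − h²)/h²`. Writing
`α = 1/(0.5 − r²_PA)` and `δ = (0.5 − r²_PA)/(1 − r²_i)`, the
individual's information content is

```
Z'Z_PA = λ(0.5α − 4) + 0.5λ √(α² + 16/δ),
Z'Z_i  = δ Z'Z_PA + 2λ(2δ − 1),
```

derived by inverting the defining relations `λ C¹¹ = 0.5 − r²_PA` and
`λ C²² = 1 − r²_i` for the coefficient matrix
`C = Z'Z + λ [4, −2; −2, 2]` (the inverse numerator-relationship block
for a parent-average/individual pair). The deregressed proof is the
individual's reconstructed right-hand side divided by `Z'Z_i`, its
effective reliability is `r*² = Z'Z_i/(Z'Z_i + λ)`, and the weight is

```
w = (1 − h²) / ((c + (1 − r*²)/r*²) h²),
```

with `c` the fraction of genetic variance not captured by markers
(default 0, configurable — nothing in the data identifies it).

A subtlety worth recording: when `r²_PA = 0` the two-equation system
still shrinks the individual proof through the parent-average
equation, and does *not* reduce to `ebv/r²`. We read `r²_PA = 0` as
"parents unknown", drop the parent-average equation, and solve the
remaining 1×1 system — which reduces *exactly* to the simple form.
`deregress_garrick()` therefore collapses to `deregress_simple()`
whenever parent information is nil, and also (with a warning) when the
system is degenerate.

### Variance components and the scan

The pseudo-phenotypes follow the weighted animal model

```
y = 1μ + u + e,   var(u) = G σ²ₐ,   var(e) = D σ²ₑ,   D = diag(1/wᵢ),
```

with `G` the VanRaden (method 1) genomic relationship matrix built
from post-QC autosomal SNPs, mean-imputing missing dosages to `2p`.
REML estimation profiles the restricted likelihood over the single
ratio `δ = σ²ₑ/σ²ₐ`: after the spectral decomposition
`D^{-1/2} G D^{-1/2} = U Λ U'`, the rotated data have diagonal
covariance `σ²ₐ(Λ + δI)`, each likelihood evaluation is O(n), and a
one-dimensional search over `log δ` (interval ±25, Brent) finds the
optimum. Degenerate cases are surfaced rather than hidden: a
non-positive-semidefinite `G` gets a 1e-6 ridge with a warning, a flat
spectrum (e.g. `G = I` with equal weights) is flagged
non-identifiable, and an optimum at the interval edge is reported as a
boundary fit.

Per-SNP allele-substitution effects are then generalized least squares
against the *fixed* fitted covariance: `X = [1, x]`,
`β̂ = (X'V̂⁻¹X)⁻¹X'V̂⁻¹y`, Wald statistic `(â/se)²` on χ²₁. A score-test
variant (`test = "score"`) evaluates the same rotated quantities
against the null residuals. The rotation `U'D^{-1/2}` is applied to
the whole dosage matrix once, which is mathematically identical to
per-SNP solves at a fraction of the cost. SNPs monomorphic among
non-missing calls — including Y markers stripped of variability by
heterozygote masking — are flagged `skipped`, not tested.

### Windows, fence, loci

Per-SNP percent variance explained is `100·2pq â²/σ²_y`. For `σ²_y`
("total trait variance") we default to the empirical variance of the
pseudo-phenotypes, since no phenotypic variance exists on the dEBV
scale; `sigma2_y = "components"` (σ̂²ₐ + σ̂²ₑ) is available. The choice
rescales all %Vp values identically and cannot change which windows
are outliers.

Windows of 1 Mb sliding 50 kb are anchored at position 0 of each
chromosome, use half-open `[start, end)` coordinates, and are
evaluated only with ≥ 10 member SNPs. Anchoring at 0 (rather than at
the first SNP) makes window boundaries reproducible across SNP subsets
and lets loci begin at 0.0 Mb. Quartiles for the Tukey fence
`Q3 + 1.5·IQR` use the linear-interpolation convention (R's default
type 7; configurable, since quartile conventions shift the fence
slightly); windows strictly above the fence are outliers, and at-fence
windows are not. Merging unions outlier windows that overlap **or
abut** — the half-open convention makes book-ended windows contiguous.
Peak positions are the midpoints of the member window(s) attaining the
maximal mean; ties are all reported, so a flat two-peak locus yields
two peaks.

## The synthetic population

`simulate_population()` emulates the data-generating process the
analysis assumes:

* **Pedigree**: paternal half-sib families; each offspring's dam is a
  distinct unobserved founder. Sire genotypes are drawn at U-shaped
  founder frequencies (Beta(0.5, 0.5) folded into MAF ≥ 0.02);
  offspring receive one sire allele by fair Mendelian sampling and one
  population allele. The real study does not publish its pedigree
  composition; the half-sib design is an assumption, chosen because it
  matches progeny-tested-sire sampling and gives the genomic
  relationship matrix a clean block structure (0.25 expected within
  families) to validate against.
* **Trait**: a handful of QTL, each a member SNP of the panel sized to
  a stated fraction of phenotypic variance, plus a genomic polygenic
  term — small normal effects on *every* other SNP — plus
  environmental noise. Building the polygenic term from the markers
  (rather than drawing family effects from the pedigree) makes `G`
  the exact covariance of the polygenic values, so REML recovery of
  `h²` is a sharp test rather than one attenuated by
  pedigree-versus-realized-relationship noise.
* **EBVs**: BLUP-consistent shrunken predictions
  `EBV = r² TBV + ε`, `var(ε) = r²(1 − r²) var(TBV)`, giving
  `cor(EBV, TBV)² = r²` and — crucially — `debv = EBV/r²` with
  residual variance `(1 − r²)/r² · var(TBV)`, exactly the form the
  deregression weights encode. Reliabilities are uniform on
  (0.26, 0.96), i.e. accuracies of about 0.51–0.98, matching the
  progeny-test setting. At `h² = 0` a shrinkage evaluation would
  return all-zero EBVs; the generator then emits unit-scale
  prediction-error noise so downstream fits remain defined.
* **Assay artifacts**: per-SNP quality U(0.7, 1) with a configurable
  fraction downgraded to U(0, 0.7); genotypes missing at random; X/Y
  markers with hemizygous (0/2) male dosages corrupted to heterozygous
  at a stated error rate; monomorphic Y markers; a tail of
  mitochondrial and unmapped SNPs for the QC chain to remove.

One global seed drives a hierarchical per-stage stream
(map/founders/genotypes/trait/EBV/quality/missingness/sex), so stages
re-run reproducibly.

What the generator deliberately does **not** emulate: population-level
linkage disequilibrium (no coalescent founder haplotypes), maternal
genetic effects, multi-breed structure, or selection across
generations. The most consequential absence is LD: in real data,
markers flanking a causal variant carry association signal, whereas
here only the causal SNP itself does. Passing recovery tests therefore
demonstrate the machinery (model, scan, smoothing, fence, merge) under
a *harder* single-marker-signal regime, but say nothing about LD-driven
resolution, which is data-specific.

## Numerical and design notes

* MAF and call-rate are computed **after** sex-heterozygote masking;
  the order is observable (an X SNP whose calls are mostly
  heterozygous errors flips from kept to removed) and tested.
* Threshold readings follow the filter definitions literally: sample
  accuracy and call rate strict (`>`), GenTrain, MAF and SNP call rate
  inclusive (`≥`); the MAF/call-rate clause removes a SNP failing
  *either* condition.
* Sample call rate is computed on the pre-SNP-filter marker set, since
  sample filters precede marker filters in the chain.
* Reliabilities of exactly 1 would make deregression weights infinite
  and are capped at `1 − 1e-6` with a warning.
* `fit_animal_model(..., fixed = c(sigma2_a =, sigma2_e =))` builds
  the model object at fixed components; this is how the GLS scan is
  unit-tested against brute-force `solve()` oracles at 1e-10.
* Windows carrying no scored SNP yield `NA` means and never become
  outliers; fewer than 4 window means leave the fence undefined and
  the locus list empty, recorded in the scan summary.

## Problem sizes for validation

The validation suite chooses problem sizes by a priori power analysis,
run before the checks were frozen:

* *REML recovery*: n = 1000 bulls in 50 families, 5000 SNPs,
  `h² = 0.5`, 20 replicates — the between-family information at this
  size puts the REML standard error near 0.04, so ĥ² lands in
  [0.4, 0.6] in ≳95% of replicates.
* *Type-I error*: a purely polygenic trait (no QTL) scanned at 5000
  markers, n = 500; with the polygenic variance spread over thousands
  of markers, per-SNP noncentralities are negligible and the scan's
  rejection rate at 0.05 is nominal.
* *Single-QTL recovery*: n = 861 (the default study size) in 43
  families, one QTL at 5% of phenotypic variance, 2700 SNPs over
  3 × 15 Mb. Without LD a window's QTL signal is the causal SNP's %Vp
  diluted by window occupancy (~45 SNPs here), while the Tukey fence
  sits ~2.7 window-SDs above the background mean; this density leaves
  a several-SD detection margin, placing the single-covering-locus
  rate near 90%, which the validation suite asserts at the 80% level
  over 25 replicates. Because merged loci are pairwise disjoint, "the
  QTL is covered by exactly one locus" is the event measured.
* *Smoothing gain*: for iid per-SNP values averaged in disjoint
  k-windows the SNR ratio has closed form √k; measured at k = 25 over
  10⁴ values.

## Limitations

* The weight-to-residual mapping (`D = diag(1/w)`) is the conventional
  reading of weighted two-step association on dEBVs; alternative
  codings (e.g. weights inside the relationship structure) exist.
* The X chromosome is carried through QC but the scan applies no
  dosage-compensation model; Y markers are usually monomorphic after
  masking and skipped.
* The Tukey fence is a descriptive outlier rule, not an error-rate
  control: a fraction of windows near 0.5–1% exceeds it under a pure
  polygenic background, so candidate loci always require functional
  or replication support.
* Deregression assumes the reliabilities are exact; mis-stated
  reliabilities propagate directly into the weights.
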