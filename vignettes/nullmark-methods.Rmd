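---
title: "Methods: dominant null-allele markers from phenotype calls to population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant null-allele markers from phenotype calls to population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullmark)
```

## The problem

Gene-deletion polymorphisms such as the GSTM1 and GSTT1 "null" variants are
typed by multiplex PCR as a band that is either present or absent. The assay
is *dominant*: a present band can come from a +/+ homozygote or a +/-
heterozygote, and only the null/null class is directly observable. A cohort
is therefore a binary loci × samples matrix (`GenotypeCohort`), and published
reference data reduce to per-population pairs of sample size and null
*genotype* frequency (`ReferencePanel`).

`nullmark` turns such data into allele frequencies, between-population
tests, genetic distances, and low-dimensional summaries of population
structure, with a simulator that makes every stage testable end to end.

## Allele frequencies under Hardy–Weinberg equilibrium

Under random mating the genotype classes follow
\(p^2 + 2pq + q^2 = 1\). The null phenotype is the \(q^2\) class, so

\[ \hat q = \sqrt{\hat f_{\mathrm{null}}}, \qquad \hat p = 1 - \hat q , \]

where \(\hat f_{\mathrm{null}} = n_{\mathrm{null}}/n\) is kept at full
precision. This is the standard estimator for dominant null markers, and it
is the *only* available one: no heterozygote information exists, so no
maximum-likelihood co-dominant estimator applies, and **HWE itself cannot be
tested from the phenotypes** — the positive class collapses two genotypes,
leaving zero degrees of freedom. The package therefore performs no HWE test
and states the assumption instead.

Two presentation details matter for reproducing published tables:

* computation is full precision throughout; rounding happens only in the
  `*_txt` columns of `genotypeSummary()` and friends, *half away from zero*
  (`roundHalfUp()`), 4 decimals for frequencies and 2 for percentages;
* rounding the full-precision value, not the printed frequency, is what
  reproduces published allele-frequency strings (e.g.
  \(\sqrt{98/300} = 0.57155 \rightarrow 0.5715\), whereas
  \(\sqrt{0.3267} = 0.57158\) would round to 0.5716 — a one-ulp trap
  whenever a rounded \(f_{\mathrm{null}}\) is re-used as input).

### Uncertainty

The paper-style point estimate is complemented by a delta-method standard
error,

\[ \mathrm{se}(\hat q) = \frac{\sqrt{f(1-f)/n}}{2\sqrt{f}} , \]

with a Wald interval truncated to \([0,1]\), and by a seeded percentile
bootstrap (default \(B = 2000\)) that resamples the \(n\) phenotype calls.
At the boundaries \(f \in \{0, 1\}\) the delta method degenerates; the
package falls back to a Clopper–Pearson interval on \(f\), square-root
transformed. The \(\sqrt{\cdot}\) transform makes \(\hat q\) slightly
biased at small \(n\); `recoveryExperiment()` reports that bias rather than
hiding it.

## Between-population comparisons

Panel rows store \((n, f_{\mathrm{null}})\); `reconstructCounts()` rebuilds
integer counts (default: rounding \(n f\) half away from zero; a
fractional-count option exists for the Pearson statistic but is refused for
Fisher's exact test, which is defined on integer tables). Every result
carries a provenance flag so reconstructed-count p-values are visibly
approximate.

`pearsonChi2()` is the uncorrected Pearson statistic on the 2×2 table
(Yates' correction \(\max(0, |O-E| - 0.5)\) behind a flag, default off: for
the tables in scope the corrected and uncorrected statistics bracket most
historically printed values, and the uncorrected form is the reproducible
convention this package standardises on). `fisherExact()` sums
hypergeometric point probabilities not exceeding the observed one (relative
tie tolerance \(10^{-7}\)); the "double one-sided" convention is available
by flag. `comparePanel()` auto-selects Fisher when the smallest expected
cell is below 5, skips panel rows lacking \(n\) or the locus frequency with
a logged notice, and applies no multiple-testing correction by default (a
`bonferroni`/`BH` column is available but off, matching common practice for
descriptive baseline comparisons).

## Nei's identity and standard distance

For one biallelic locus with profiles \((p_a, q_a)\), \((p_b, q_b)\):

\[ I = \frac{p_a p_b + q_a q_b}
          {\sqrt{(p_a^2 + q_a^2)(p_b^2 + q_b^2)}}, \qquad D = -\ln I . \]

Distances are computed on **HWE-derived allele frequencies**
(\(q = \sqrt{f_{\mathrm{null}}}\)), not on genotype frequencies: that is the
convention under which the package reproduces the verifiable published
anchor (cohort vs Portugal at GSTM1, \(D = 0.0003\) at 4 decimals; the
genotype-frequency convention gives 0.0004 and is rejected). \(I = 0\) —
hence \(D = \infty\) — occurs only for opposite fixations; infinities are
represented explicitly, excluded from locus averages with a warning, and
never clamped. Missing panel cells are first-class `NA`s: a pair's average
distance is taken over its shared loci, and the loci used are recorded.

## Ordination and clustering

`classicalMds()` delegates to the Torgerson procedure (double-centre
\(B = -\tfrac12 J D^2 J\), eigendecompose, scale eigenvectors by
\(\sqrt{\lambda}\)). The retained dimension is capped at the number of
eigenvalues positive beyond a relative tolerance of \(10^{-9}\); negative
eigenvalues (non-Euclidean input, common for averaged \(-\ln I\) matrices)
are reported as diagnostics, never used for coordinates. Axis signs are
arbitrary in theory, so each axis is oriented to give the focal (first)
population a non-negative coordinate — plots become reproducible. A
stress-like Frobenius residual between input and reconstructed distances is
attached.

`upgma()` is the classical unweighted pair-group agglomeration:
size-weighted average linkage, merging the pair with the smallest distance;
among exact ties, the pair first in cluster-creation order, so output is
deterministic. Merge heights are stored as *half* the between-cluster
distance, making the tree ultrametric with leaf-to-leaf path length equal to
the join distance, and the Newick branch lengths are height differences (two
leaves at distance \(d\) serialize as `(A:d/2,B:d/2);`).

## The synthetic cohort generator

`admixtureSpec()` describes a one-generation admixture of up to a few
ancestral sources — the tri-hybrid Amerindian/European/African setting that
shaped urban Latin American cohorts — with stated weights. The default
model is panmictic: after one generation of random mating the null allele
frequency is \(q_{\mathrm{mix}} = \sum_s w_s q_s\) and each individual is
null with probability \(q_{\mathrm{mix}}^2\) (HWE at the mixed frequency),
matching the assumption the estimator itself makes. A Wahlund alternative
(`model = "wahlund"`) instead draws each individual's source and uses that
source's \(q_s^2\), producing the classical homozygote excess
\(\sum_s w_s q_s^2 \ge q_{\mathrm{mix}}^2\); it exists so analyses can
demonstrate the estimator's sensitivity to hidden structure. Loci are
simulated independently (the two GST loci are analysed independently in
practice even though both map to 1p13.3; no linkage or drift is modelled).
The seed is part of the spec and is recorded in the cohort's metadata.

What the generator does *not* emulate: genotyping failure/missingness,
related individuals, linkage between loci, multi-generation drift or
selection. Passing tests on simulated cohorts therefore validate the
estimator and pipeline under their stated assumptions, not the wet-lab
process producing real call tables.

## Problem sizes and numerical choices

The shipped test suite exercises: exhaustive Fisher enumeration on all 2×2
tables with total ≤ 30; 1000 random tables against the textbook Pearson
formula (10⁻¹⁰ agreement); 100 random matrices for UPGMA ultrametricity;
5-point Euclidean matrices recovered by MDS to 10⁻⁸; and parameter-recovery
experiments of 1000 replicates at \(n = 1000\) for \(q \in \{0.30, 0.57,
0.62\}\), where the delta-method 95% intervals achieve empirical coverage
within [0.93, 0.97]. These sizes were chosen to make each property's
sampling noise negligible relative to its tolerance while keeping a full
run under a minute per property on one core.

Tie-breaks and degenerate inputs are handled explicitly: UPGMA ties merge
the lexicographically-first pair; an empty call file with a header yields an
empty cohort whose errors surface downstream where a frequency is actually
requested; zero contingency marginals are an error advising Fisher's test;
a 1×1 distance selection is a legal zero matrix.

## Worked example

```{r example, eval = FALSE}
cohort <- simulateCohort(admixtureSpec(
  loci = c("GSTM1", "GSTT1"),
  ancestralQ = list(amerindian = c(0.0, 0.05),
                    european   = c(0.63, 0.45),
                    african    = c(0.48, 0.62)),
  weights = c(amerindian = 0.25, european = 0.55, african = 0.20),
  n = 300, seed = 11))
genotypeSummary(cohort)
lf <- phenotypeFrequencies(cohort, "GSTT1", ci = "delta")
comparePanel(lf, table3Panel(), "GSTT1")
```

## Known limitations

* Everything downstream of \(\hat q\) inherits the HWE assumption, which is
  untestable here; the Wahlund simulator quantifies the consequences when
  it fails.
* Reconstructed counts from rounded published frequencies make the panel
  p-values approximate at the margin (the provenance flag marks them); no
  reconstruction can recover the original study's exact tables.
* Nei's \(D\) from two biallelic loci is a coarse summary; the package
  deliberately implements no \(F_{ST}\), chord distance, or multi-allelic
  generalisations.
* Classical MDS on non-Euclidean \(D\) matrices is a projection of a
  partially negative spectrum; inspect `eigenvalues()` before interpreting
  axes.
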